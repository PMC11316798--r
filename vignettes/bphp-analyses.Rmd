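---
title: "Models and methods: oligomerization, photokinetics and conformational analysis of a phytochrome kinase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bphptools)
```

Bacterial phytochromes (BphPs) are dimeric photoreceptors that interconvert
between a red-absorbing dark state (Pr) and a far-red-absorbing activated
state (Pfr), and many couple this photocycle to a histidine-kinase output.
`bphptools` implements the four quantitative analyses such a system calls
for — size-exclusion chromatography (SEC) deconvolution of a dimer/tetramer
equilibrium, global analysis of Pfr→Pr thermal reversion, saturation
kinetics of autophosphorylation and phosphotransfer, and rigid-body
descriptors of the Pr/Pfr conformational change — together with seeded
generators that make every stage testable without instrument data. This
vignette describes the models, their assumptions, the tunable parameters,
and the numerical choices; it states no result that the package's test suite
or `scripts/acceptance.R` does not itself compute.

## 1. SEC deconvolution and the dimer–tetramer isotherm

### Peak model

A chromatographic peak subject to Gaussian band broadening and first-order
column tailing is the exponentially modified Gaussian (EMG): the
distribution of a Gaussian elution volume (center $\mu$ mL, width $\sigma$
mL) plus an exponential delay (rate $\lambda$ mL$^{-1}$), scaled by the peak
area $A$ (absorbance·mL):

$$
f(V_e) = \tfrac{1}{2} A \lambda\,
  e^{\frac{\lambda}{2}(2\mu + \lambda\sigma^2 - 2V_e)}\,
  \operatorname{erfc}\!\Big(\frac{\mu + \lambda\sigma^2 - V_e}{\sqrt2\,\sigma}\Big).
$$

A chromatogram is modeled as a tetramer EMG plus a dimer EMG plus a linear
baseline $b + cV_e$ — ten parameters, fit by bounded Levenberg–Marquardt
least squares (`fitEMGMixture()`). The component with the smaller $\mu$ is
labelled tetramer, because the larger hydrodynamic species elutes first.

**Numerical stability.** The printed form overflows for $V_e \ll \mu$
(the exponential argument grows without bound while erfc underflows). The
implementation evaluates the algebraically identical
$\tfrac12 A\lambda\, e^{-(V_e-\mu)^2/2\sigma^2}\,\mathrm{erfcx}(z)$ for
$z \ge 0$ and the direct form (whose exponent is then provably negative) for
$z < 0$. The scaled complement erfcx itself is computed by an asymptotic
continued-fraction expansion above $z = 25$, where naive
$e^{z^2}\mathrm{erfc}(z)$ evaluation underflows.

**Gaussian limit.** The exponential stage shifts the peak mean by exactly
$1/\lambda$, so as $\lambda\sigma \to \infty$ the EMG converges to
$N(\mu + 1/\lambda, \sigma)$, with residual error of order
$(\lambda\sigma)^{-2}$. Comparing against a Gaussian centered at $\mu$
itself leaves a first-order error of $\approx 3/(\lambda\sigma)$ at
$\mu \pm 3\sigma$ — about 6% at $\lambda\sigma = 50$ — which is why the test
suite checks convergence against the mean-shifted Gaussian.

**Initialization.** When no starting model is given: $\mu$ seeds at the two
highest local maxima of a lightly smoothed trace; $\sigma$ from the
half-width at 60% height; $\lambda = 2/\sigma$; areas by trapezoid sums split
at the inter-peak minimum; baseline from a line through the outer 5% of
points. Convergence is declared at relative parameter change below $10^{-8}$
or 500 iterations, and non-convergence is reported in the returned object,
never silently. Standard errors come from the Jacobian-based covariance
scaled by the residual variance.

### Mole fraction and the association model

The tetramer mole fraction is taken as the area fraction
$\bar{Y} = A_T/(A_T + A_D)$, assuming equal extinction per subunit at the
detection wavelength (protein absorbance at 280 nm scales with subunit
count); the baseline is excluded. Whether a reported titration used
amplitude ratios or extinction-corrected areas is generally ambiguous, so
reports flag this assumption explicitly.

For the self-association 2 D $\rightleftharpoons$ T with
$K_2 = [T]/[D]^2$, the *subunit* is the intact dimer (a tetramer holds two),
because only that reading makes the closed form follow from the mass balance
$C_{tot} = [D] + 2K_2[D]^2$ and $\bar{Y} = 2[T]/C_{tot}$:

$$
\bar{Y} = \frac{2\big(4K_2C_{tot} + 1 - \sqrt{1 + 8K_2C_{tot}}\big)}{8K_2C_{tot}}
        = \frac{4x}{1 + 4x + \sqrt{1+8x}}, \quad x = K_2C_{tot}.
$$

The second, conjugate form is what `yfracEquilibrium()` evaluates: it is
free of the subtractive cancellation that destroys the printed form below
$x \approx 10^{-6}$, continuous at $C_{tot}=0$, and agrees with a brute-force
mass-balance root-finder to $10^{-10}$ over eight decades of $x$ (a test and
an acceptance-script check). Its exact inverse is
$K_2C_{tot} = \bar{Y}/(2(1-\bar{Y})^2)$ (`invertYfrac()`). Mass
concentrations convert to molar with a configurable subunit molar mass,
default 165 kDa (a dimer of two 745-residue chains).

`fitAssociationConstant()` fits $K_2$ by least squares in $\bar{Y}$; with a
single titration point it reduces to the exact closed-form inversion. SEC
titrations of a slowly re-equilibrating oligomer need not represent the
equilibrium populations during elution, so the fitted constant is exposed as
a *descriptive trendline* and every report labels it as such.

## 2. Global biexponential thermal reversion

Dark reversion of the activated state is modeled per wavelength as

$$\mathrm{Abs}(\lambda, t) = A_1(\lambda)e^{-k_1 t} + A_2(\lambda)e^{-k_2 t} + \mathrm{Abs}_0(\lambda),$$

with the two rate constants *shared across all wavelengths* in the fit
window (default 650–785 nm, configurable). Given $(k_1,k_2)$, the
amplitudes and baselines are linear and have a closed-form least-squares
solution, so `fitGlobalBiexponential()` uses variable projection: a
two-dimensional outer optimization over $(\log k_1, \log k_2)$ with the
linear parameters projected out. This is far better conditioned than a
joint fit of $3W + 2$ parameters and, at the optimum, identical to it (a
property the suite verifies against an independent joint fit on a small
noiseless instance, where the RSS minimum is a point).

Because biexponential objectives are multimodal, the outer search starts
from a log-spaced grid over rate pairs spanning $10^{-5}$–$1$ s$^{-1}$
before Nelder–Mead plus quasi-Newton refinement. Rates are ordered
$k_1 > k_2$ by relabeling. Two degeneracies collapse the fit to a single
exponential, with a warning and `degenerate = TRUE`: rates closer than
$10^{-6}$ relative, and a second component whose RSS improvement over the
single-exponential fit is below $10^{-8}$ of the data's total variance (the
variance-referenced threshold keeps the decision meaningful when both
residuals are at floating-point noise). Rate standard errors come from the
full Jacobian over rates *and* all per-wavelength linear parameters.

`differenceSpectrum()` computes state-A-minus-state-B difference spectra on
a common grid and reports the peak, trough and the spectral change ratio,
defined here as $|\Delta A|$ at the difference maximum divided by
$|\Delta A|$ at the minimum (the quantity is commonly reported without a
formal definition; the package records this convention in its reports). An
identically zero difference has no defined ratio and is signalled.

## 3. Saturation kinetics of the kinase reactions

Phosphorylation time courses follow
$S(t) = \Delta S\,(1 - e^{-kt}) + S_0$ (or a sum of two such terms,
$k > k_2$ by relabeling), with the rate constant(s) shared globally across
replicate traces while $\Delta S$ and $S_0$ float per trace
(`fitSaturation()`). The same variable-projection structure applies: a 1-D
(or 2-D) outer search over log rates with per-trace linear solves inside.
For phosphotransfer experiments, where the donor kinase is pre-loaded and
mixed with the acceptor at $t=0$, `constrainBaseline = TRUE` fixes each
$S_0$ to that trace's measured $t=0$ signal and removes it from the free
parameters. A negative $\Delta S$ describes the donor losing label; on
paired donor/acceptor traces generated with conserved total label the
fitted amplitudes mirror each other, a property the suite checks.

Rate units are the reciprocal of whatever time unit the input uses; the
package never assumes seconds and echoes units from input metadata.
(Published apparent rate constants for such reactions are occasionally
inconsistent with the stated completion time of the reaction, which is
exactly why unit handling is left to metadata.) Residuals are treated as
homoscedastic by default — densitometry noise is dominated by film/plate
response rather than counting statistics — and standard errors come from
the Jacobian-based covariance.

## 4. Conformational descriptors between photostate models

`readStructure()` parses PDB and mmCIF (first model, blank/'A' alternate
locations), keeping deposited author numbering untouched. All comparisons
pair atoms by (chain, residue number, atom name) intersection and are built
on one primitive: Kabsch superposition (`superpose()`), the SVD solution of
the least-squares rotation with a determinant correction that excludes
reflections. Rotation angles are extracted as
$\arccos((\mathrm{tr}\,R - 1)/2)$ with the argument clamped to $[-1,1]$;
the axis sign convention is a nonnegative z-component (ties resolved toward
y, then x).

* **Domain rotation** (`domainRotation()`): both states are aligned on a
  common frame (for a phytochrome, the bilin-binding GAF domain), and the
  rotation mapping the measured domain (e.g. PHY) between states is
  extracted. This is the natural formalization of "superpose on GAF,
  measure how far PHY rotated".
* **Ring flip** (`planeFlipAngle()`): after the same frame alignment, a
  least-squares plane is fit to the ordered chromophore ring atoms in each
  state; normals are oriented by the right-hand rule over the stated atom
  order, so a genuine flip of the bilin D ring reads as an angle beyond
  90°, not its supplement.
* **Atom-pair distances** (`pairDistance()`), e.g. the hairpin-proximity
  pair that contracts on photoactivation, are reported per state.
* **Helix scissoring** (`helixScissorAngle()`): each helix axis is the
  dominant principal component of its Cα set, sign-fixed N→C, and the acute
  inter-axis angle is reported per state so Pr/Pfr deltas can be tabulated.
  This principal-axis proxy deliberately avoids secondary-structure
  assignment.

Default selections for the *P. syringae* BphP1 comparisons (GAF/PHY
windows, the Gly177–Ile483 Cα pair, the biliverdin D-ring atom names from
the BLA chemical-component entry) ship as an editable YAML config
(`inst/extdata/psbphp1_domains.yaml`); the domain windows there are
approximate and meant to be overridden with deposited boundaries when exact
ones matter. Deposited accessions are not bundled — fetching them requires
network access — so the structural test surface runs on generator-built
fixtures; accession-based measurements are one `compare-structures` call
once files are local. Protomer choice matters at the ±degree level:
compute both protomers and report both rather than averaging.

## 5. What the generators emulate — and what they do not

Every generator is a pure function of a `GeneratorSpec` (seed, noise model,
grid, truth): the same spec yields byte-identical output, the caller's RNG
stream is never disturbed, and the ground truth is embedded in the returned
object so recovery tests never re-type true values.

* `makeChromatogram()`: two-EMG-plus-baseline traces on an 8–24 mL grid at
  0.02 mL steps, matching an analytical SEC column; default peaks put the
  tetramer 1.6 mL ahead of the dimer with realistic widths and tails.
* `makeEquilibriumSeries()`: area fractions follow the isotherm exactly and
  total area scales with load. The default $K_2 = 2\times10^6$
  M$^{-1}$ was chosen once as the mid-range of the closed-form single-point
  inversions of a reported two-point titration (0.52 at 0.117 mg/mL and
  0.84 at 1.17 mg/mL with the 165 kDa subunit mass give $1.6$ and
  $2.3\times10^6$ M$^{-1}$); the default concentration decade spans those
  two loads.
* `makeReversionSeries()`: 28 wavelengths over 650–785 nm, 200 times over
  two hours, $k_1 = 3\times10^{-3}$, $k_2 = 3\times10^{-4}$ s$^{-1}$, and
  opposite-signed Gaussian bands (far-red loss, red gain) with decay
  amplitudes of order 0.1 absorbance, so the reference noise of
  $10^{-3}$ is about 1% of signal.
* `makeKineticsTrace()`: saturating traces (default $k = 4.7\times10^{-3}$
  s$^{-1}$, the hour-scale loading regime) in replicate, or paired
  donor/acceptor traces with conserved total label.
* `makeRotatedPair()`: a two-domain Cα scaffold of ideal helices plus a
  planar five-atom ring; state B rotates the mobile domain about a stated
  hinge and flips the ring in place. Defaults (35° rotation, 161° flip) are
  the magnitudes of the photocycle motions the descriptors were built to
  measure.

What passing these tests shows is that the estimators recover known truth
under the stated noise at desk scale. What they cannot show: real SEC peaks
deviate from EMG shape under column overloading or slow re-equilibration
during elution; real reversion data carry baseline drift and stray-light
structure the model omits; real densitometry noise is neither exactly
multiplicative nor independent; and cryo-EM coordinate error is spatially
correlated, unlike the isotropic jitter option. Conclusions about real data
inherit those caveats.

## 6. Problem sizes, tolerances, reproducibility

The test suite and the acceptance script run the study-scale problems
directly — 801-point chromatograms, the 28 × 200 reversion matrix,
triplicate 25-point kinetics traces, 20-chromatogram recovery batches —
because all fits are seconds-scale. Key numeric tolerances: isotherm vs
oracle $10^{-10}$; EMG area vs amplitude $10^{-6}$ relative; noiseless
parameter recovery $10^{-4}$ relative or better; angle recovery from exact
transforms $10^{-6}$ degrees. Pipeline runs (`runPipeline()`) write a JSON
report plus a manifest with the config echo, package version and input
checksums; identical inputs give byte-identical reports, and every
defaulted parameter is logged.

## 7. Known limitations

No higher oligomers beyond tetramer; no reaction-chromatography transport
modeling; no quantum-yield or action-spectrum analysis; no gel image
quantification (densitometry happens upstream); no secondary-structure
assignment beyond the principal-axis helix proxy; and no map-space (EM
volume) analysis. The association constant from SEC titrations is reported
as a trendline, not a certified equilibrium constant, for the reasons in
section 1.
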