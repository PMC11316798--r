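# bphptools

Quantitative analyses for dimeric bacterial phytochrome (BphP)
photoreceptors with histidine-kinase output modules — the class of
photosensors that interconvert between a red-absorbing dark state (Pr) and a
far-red-absorbing activated state (Pfr) and couple that photocycle to a
two-component phosphorelay. The package is aimed at groups characterizing
such photoreceptors by size-exclusion chromatography (SEC), UV-vis
kinetics, radiolabel phosphotransfer assays, and photostate coordinate
models.

Four analysis stages, plus seeded synthetic-data generators that make every
stage testable without instrument data:

1. **SEC oligomerization.** Chromatograms are deconvolved into tetramer and
   dimer peaks, each an exponentially modified Gaussian (EMG)

   *f*(V<sub>e</sub>) = ½·A·λ·exp(½λ(2μ + λσ² − 2V<sub>e</sub>))·erfc((μ + λσ² − V<sub>e</sub>)/(√2·σ)),

   on a linear baseline (`fitEMGMixture`). Area fractions feed the
   closed-form dimer⇌tetramer isotherm (2 D ⇌ T, K₂ = [T]/[D]²):

   Ȳ = 2(4K₂C<sub>tot</sub> + 1 − √(1 + 8K₂C<sub>tot</sub>)) / (8K₂C<sub>tot</sub>),

   evaluated in a cancellation-free equivalent form
   (`yfracEquilibrium`, `invertYfrac`, `fitAssociationConstant`).
2. **Thermal reversion.** Pfr→Pr decay matrices are fit globally to
   Abs(λ,t) = A₁(λ)e<sup>−k₁t</sup> + A₂(λ)e<sup>−k₂t</sup> + Abs₀(λ) with
   rates shared across wavelengths, by variable projection
   (`fitGlobalBiexponential`); plus difference-spectrum utilities
   (`differenceSpectrum`).
3. **Kinase kinetics.** Autophosphorylation and phosphotransfer traces
   follow S(t) = ΔS(1 − e<sup>−kt</sup>) + S₀ (one or two components) with
   a globally shared rate and optional time-zero baseline constraint
   (`fitSaturation`).
4. **Conformational comparison.** PDB/mmCIF models of the two photostates
   are compared by Kabsch superposition and derived descriptors: domain
   rotation in a common alignment frame, chromophore ring-flip angle,
   atom-pair distances, helix scissor angles (`readStructure`, `superpose`,
   `domainRotation`, `planeFlipAngle`, `pairDistance`,
   `helixScissorAngle`, `compareStructures`).

`runPipeline()` orchestrates the stages from schema-checked configurations
and writes JSON reports with reproducibility manifests; a thin CLI wrapper
lives at `inst/scripts/bphp-pipeline.R`.

## Worked example

Deconvolve a synthetic chromatogram whose truth is known, then fit the
association trendline to a two-point titration:

```r
library(bphptools)

sp  <- generatorSpec(seed = 7, noise = list(type = "relpeak", frac = 0.005))
ch  <- makeChromatogram(sp)      # truth: areas 0.6/0.4, peaks at 10.2/11.8 mL
fit <- fitEMGMixture(ch)
fit
#> EMGMixtureFit: converged = TRUE, 10 iterations, residual RMS 0.00405
#> EMGMixture (tetramer + dimer + linear baseline)
#>   tetramer: EMGComponent: area 0.5999, mu 10.201 mL, sigma 0.220 mL, lambda 4.019 /mL
#>   dimer:    EMGComponent: area 0.3992, mu 11.801 mL, sigma 0.261 mL, lambda 3.540 /mL
#>   baseline: b = 0.005935, c = 0.0001506 per mL
#>   tetramer mole fraction: 0.600 (SE 0.001)
```

All ten generating parameters are recovered at 0.5% peak-height noise, and
the tetramer area fraction (0.600) matches the generator's truth (0.6)
within its standard error.

A titration reporting tetramer mole fractions 0.52 at 0.117 mg/mL and 0.84
at 1.17 mg/mL (165 kDa subunit) gives a descriptive association trendline:

```r
conc <- mgPerMlToMolar(c(0.117, 1.17))     # 7.09e-07 7.09e-06 M
fitAssociationConstant(conc, c(0.52, 0.84))$k2
#> [1] 1711471
```

i.e. K₂ ≈ 1.7×10⁶ M⁻¹ — a trendline, since SEC titration points need not
represent equilibrium during elution. Global reversion analysis of a
synthetic decay matrix (1% noise) recovers its shared rates:

```r
rev <- makeReversionSeries(generatorSpec(seed = 9,
                                         noise = list(type = "gaussian", sd = 1e-3)))
fitGlobalBiexponential(rev)
#> ReversionFit: k1 = 0.003007 /s (SE 1.8e-05), k2 = 0.0003033 /s (SE 3e-06)
#>   28 wavelengths in 650-785 nm, residual RMS 0.000983
```

(generating rates: 3×10⁻³ and 3×10⁻⁴ s⁻¹).

## Documentation

The methods vignette (`vignettes/bphp-analyses.Rmd`) describes the models,
their assumptions, parameter defaults and units, the numerical choices
(overflow-free EMG evaluation, variable projection, degeneracy handling),
what the synthetic generators do and do not emulate, and known limitations.
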