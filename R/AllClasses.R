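#' @import methods
NULL

# ---------------------------------------------------------------------------
# SEC / oligomerization containers
# ---------------------------------------------------------------------------

#' Chromatogram: a single SEC elution trace
#'
#' Holds an elution-volume/absorbance series from size-exclusion
#' chromatography, the raw input of the dimer/tetramer deconvolution.
#'
#' @slot volume numeric, elution volume in mL, strictly increasing.
#' @slot absorbance numeric, same length as `volume`, finite.
#' @slot wavelength numeric(1), nominal detection wavelength in nm (metadata).
#' @slot label character(1), free-text sample label.
#' @export
setClass("Chromatogram",
  representation(volume = "numeric", absorbance = "numeric",
                 wavelength = "numeric", label = "character"),
  prototype(wavelength = 280, label = ""))

setValidity("Chromatogram", function(object) {
  v <- object@volume; a <- object@absorbance
  if (length(v) != length(a)) return("volume and absorbance lengths differ")
  if (length(v) < 10) return("need at least 10 points")
  if (!all(is.finite(v)) || !all(is.finite(a)))
    return("volume and absorbance must be finite")
  if (any(diff(v) <= 0)) return("volume must be strictly increasing")
  TRUE
})

#' Construct a Chromatogram
#'
#' @param volume elution volumes (mL), strictly increasing.
#' @param absorbance absorbance values, same length.
#' @param wavelength nominal detection wavelength (nm).
#' @param label free-text label.
#' @return a [Chromatogram-class] object.
#' @examples
#' v <- seq(8, 24, by = 0.1)
#' Chromatogram(v, exp(-(v - 12)^2))
#' @export
Chromatogram <- function(volume, absorbance, wavelength = 280, label = "") {
  new("Chromatogram", volume = as.numeric(volume),
      absorbance = as.numeric(absorbance),
      wavelength = as.numeric(wavelength)[1], label = as.character(label)[1])
}

#' Exponentially modified Gaussian peak component
#'
#' One chromatographic peak: a Gaussian (center `mu`, width `sigma`) convolved
#' with a one-sided exponential of rate `lam`, scaled so that the total peak
#' area equals `amp`.
#'
#' @slot amp numeric(1), peak area (absorbance * mL), >= 0.
#' @slot lam numeric(1), exponential tailing rate (1/mL), > 0.
#' @slot mu numeric(1), Gaussian center (mL).
#' @slot sigma numeric(1), Gaussian width (mL), > 0.
#' @export
setClass("EMGComponent",
  representation(amp = "numeric", lam = "numeric", mu = "numeric",
                 sigma = "numeric"))

setValidity("EMGComponent", function(object) {
  if (!all(is.finite(c(object@amp, object@lam, object@mu, object@sigma))))
    return("parameters must be finite")
  if (object@amp < 0) return("amp must be >= 0")
  if (object@lam <= 0) return("lam must be > 0")
  if (object@sigma <= 0) return("sigma must be > 0")
  TRUE
})

#' @rdname EMGComponent-class
#' @param amp,lam,mu,sigma peak area, tailing rate (1/mL), center (mL), width (mL).
#' @return an `EMGComponent`.
#' @export
EMGComponent <- function(amp, lam, mu, sigma) {
  new("EMGComponent", amp = amp, lam = lam, mu = mu, sigma = sigma)
}

#' Two-component EMG chromatogram model
#'
#' The SEC deconvolution model: a tetramer peak plus a dimer peak (each an
#' [EMGComponent-class]) on a linear baseline `b + c * volume`. Tetramers are
#' the larger species and elute first, so `tetramer@mu < dimer@mu` is
#' enforced.
#'
#' @slot tetramer,dimer [EMGComponent-class] peaks.
#' @slot b numeric(1), baseline intercept (absorbance).
#' @slot c numeric(1), baseline slope (absorbance/mL).
#' @export
setClass("EMGMixture",
  representation(tetramer = "EMGComponent", dimer = "EMGComponent",
                 b = "numeric", c = "numeric"),
  prototype(b = 0, c = 0))

setValidity("EMGMixture", function(object) {
  if (!is.finite(object@b) || !is.finite(object@c))
    return("baseline parameters must be finite")
  if (object@tetramer@mu >= object@dimer@mu)
    return("tetramer must elute before dimer (tetramer@mu < dimer@mu)")
  TRUE
})

#' @rdname EMGMixture-class
#' @param tetramer,dimer `EMGComponent` objects (tetramer elutes first).
#' @param b,c baseline intercept and slope.
#' @return an `EMGMixture`.
#' @export
EMGMixture <- function(tetramer, dimer, b = 0, c = 0) {
  new("EMGMixture", tetramer = tetramer, dimer = dimer, b = b, c = c)
}

#' Result of fitting an EMG mixture to a chromatogram
#'
#' @slot model the fitted [EMGMixture-class].
#' @slot residualRMS numeric(1), root-mean-square residual (absorbance).
#' @slot covariance parameter covariance matrix, rows/cols named
#'   `ampT, lamT, muT, sigmaT, ampD, lamD, muD, sigmaD, b, c`.
#' @slot converged logical(1).
#' @slot nIter integer(1), optimizer iterations.
#' @export
setClass("EMGMixtureFit",
  representation(model = "EMGMixture", residualRMS = "numeric",
                 covariance = "matrix", converged = "logical",
                 nIter = "integer"))

setValidity("EMGMixtureFit", function(object) {
  if (object@residualRMS < 0) return("residualRMS must be >= 0")
  if (nrow(object@covariance) != ncol(object@covariance))
    return("covariance must be square")
  TRUE
})

#' Dimer-tetramer association state
#'
#' One point on the 2 dimer <-> 1 tetramer isotherm: equilibrium constant,
#' total subunit (dimer) concentration, and the tetramer mole fraction.
#'
#' @slot k2 numeric(1), association constant (1/M), > 0.
#' @slot cTot numeric(1), total subunit concentration (M, dimer units), >= 0.
#' @slot yFrac numeric(1), tetramer mole fraction in [0, 1).
#' @export
setClass("AssociationState",
  representation(k2 = "numeric", cTot = "numeric", yFrac = "numeric"))

setValidity("AssociationState", function(object) {
  if (object@k2 <= 0) return("k2 must be > 0")
  if (object@cTot < 0) return("cTot must be >= 0")
  if (object@yFrac < 0 || object@yFrac >= 1) return("yFrac must be in [0, 1)")
  if (object@cTot == 0 && object@yFrac != 0)
    return("yFrac must be 0 at zero concentration")
  TRUE
})

#' @rdname AssociationState-class
#' @param k2 association constant (1/M).
#' @param cTot total subunit concentration (M).
#' @return an `AssociationState` with `yFrac` computed from the isotherm.
#' @export
AssociationState <- function(k2, cTot) {
  new("AssociationState", k2 = k2, cTot = cTot,
      yFrac = yfracEquilibrium(k2, cTot))
}

# ---------------------------------------------------------------------------
# Photokinetics containers
# ---------------------------------------------------------------------------

#' Time-resolved multi-wavelength absorbance series
#'
#' @slot wavelengths numeric, nm, strictly increasing (>= 2 values).
#' @slot times numeric, s, strictly increasing, t0 >= 0 (>= 3 values).
#' @slot absorbance numeric matrix, wavelengths x times, finite.
#' @export
setClass("SpectralSeries",
  representation(wavelengths = "numeric", times = "numeric",
                 absorbance = "matrix"))

setValidity("SpectralSeries", function(object) {
  if (length(object@wavelengths) < 2) return("need >= 2 wavelengths")
  if (length(object@times) < 3) return("need >= 3 time points")
  if (any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (object@times[1] < 0 || any(diff(object@times) <= 0))
    return("times must be strictly increasing with t0 >= 0")
  if (!identical(dim(object@absorbance),
                 c(length(object@wavelengths), length(object@times))))
    return("absorbance must be wavelengths x times")
  if (!all(is.finite(object@absorbance))) return("absorbance must be finite")
  TRUE
})

#' @rdname SpectralSeries-class
#' @param wavelengths,times axis vectors (nm, s).
#' @param absorbance matrix, wavelengths in rows, times in columns.
#' @return a `SpectralSeries`.
#' @export
SpectralSeries <- function(wavelengths, times, absorbance) {
  absorbance <- as.matrix(absorbance)
  dimnames(absorbance) <- NULL
  new("SpectralSeries", wavelengths = as.numeric(wavelengths),
      times = as.numeric(times), absorbance = absorbance)
}

#' Global biexponential thermal-reversion fit
#'
#' Rates `k1 > k2` are shared across all wavelengths in the fit window;
#' amplitudes and baselines float per wavelength. A degenerate fit (the data
#' support only one exponential) is flagged and carries `k2 = NA`.
#'
#' @slot k1,k2 numeric(1), rate constants (1/s); `k1 > k2` unless degenerate.
#' @slot amp1,amp2,abs0 numeric, per-wavelength amplitudes and baseline.
#' @slot wavelengths numeric, wavelengths inside the fit window.
#' @slot fitWindow numeric(2), nm range used.
#' @slot residualRMS numeric(1).
#' @slot kSE numeric(2), standard errors of (k1, k2).
#' @slot degenerate logical(1), TRUE when collapsed to a single exponential.
#' @export
setClass("ReversionFit",
  representation(k1 = "numeric", k2 = "numeric", amp1 = "numeric",
                 amp2 = "numeric", abs0 = "numeric", wavelengths = "numeric",
                 fitWindow = "numeric", residualRMS = "numeric",
                 kSE = "numeric", degenerate = "logical"))

setValidity("ReversionFit", function(object) {
  nw <- length(object@wavelengths)
  if (length(object@amp1) != nw || length(object@abs0) != nw)
    return("per-wavelength arrays must match wavelengths")
  if (!object@degenerate) {
    if (length(object@amp2) != nw)
      return("per-wavelength arrays must match wavelengths")
    if (!(object@k1 > object@k2 && object@k2 > 0))
      return("need k1 > k2 > 0")
  } else if (object@k1 <= 0) return("k1 must be > 0")
  TRUE
})

#' Difference spectrum between two photostates
#'
#' @slot wavelengths numeric, nm.
#' @slot deltaAbs numeric, absorbance of state A minus state B.
#' @slot peakWavelength,troughWavelength numeric(1), nm of the maximum and
#'   minimum of the difference inside the analysis window.
#' @slot changeRatio numeric(1), |dA at peak| / |dA at trough|.
#' @export
setClass("DifferenceSpectrum",
  representation(wavelengths = "numeric", deltaAbs = "numeric",
                 peakWavelength = "numeric", troughWavelength = "numeric",
                 changeRatio = "numeric"))

setValidity("DifferenceSpectrum", function(object) {
  rng <- range(object@wavelengths)
  if (object@peakWavelength < rng[1] || object@peakWavelength > rng[2] ||
      object@troughWavelength < rng[1] || object@troughWavelength > rng[2])
    return("peak/trough must lie inside the wavelength range")
  TRUE
})

# ---------------------------------------------------------------------------
# Kinase kinetics containers
# ---------------------------------------------------------------------------

#' A densitometry kinetics trace
#'
#' @slot times numeric, s, increasing, t0 >= 0 (>= 4 points).
#' @slot signal numeric, densitometry counts (arbitrary units), >= 0.
#' @slot replicateId character(1).
#' @slot species character(1), e.g. "donor" (kinase) or "acceptor"
#'   (response regulator).
#' @export
setClass("KineticsTrace",
  representation(times = "numeric", signal = "numeric",
                 replicateId = "character", species = "character"),
  prototype(replicateId = "r1", species = ""))

setValidity("KineticsTrace", function(object) {
  if (length(object@times) != length(object@signal))
    return("times and signal lengths differ")
  if (length(object@times) < 4) return("need >= 4 points")
  if (object@times[1] < 0 || any(diff(object@times) <= 0))
    return("times must be increasing with t0 >= 0")
  if (!all(is.finite(object@signal)) || any(object@signal < 0))
    return("signal must be finite and >= 0")
  TRUE
})

#' @rdname KineticsTrace-class
#' @param times,signal time (s) and signal (counts) vectors.
#' @param replicateId,species labels.
#' @return a `KineticsTrace`.
#' @export
KineticsTrace <- function(times, signal, replicateId = "r1", species = "") {
  new("KineticsTrace", times = as.numeric(times), signal = as.numeric(signal),
      replicateId = as.character(replicateId)[1],
      species = as.character(species)[1])
}

#' Saturating-exponential fit with a globally shared rate
#'
#' @slot k numeric(1), shared rate constant (1/s), > 0.
#' @slot k2 numeric(1), second-component rate (NA for one component;
#'   `k > k2 > 0` otherwise).
#' @slot nComponents integer(1), 1 or 2.
#' @slot deltaS,deltaS2,s0 numeric, per-replicate amplitudes and baselines.
#' @slot replicateIds character, per-replicate labels.
#' @slot kSE numeric, standard error(s) of the shared rate(s).
#' @slot residualRMS numeric(1).
#' @slot baselineConstrained logical(1).
#' @slot converged logical(1).
#' @export
setClass("SaturationFit",
  representation(k = "numeric", k2 = "numeric", nComponents = "integer",
                 deltaS = "numeric", deltaS2 = "numeric", s0 = "numeric",
                 replicateIds = "character", kSE = "numeric",
                 residualRMS = "numeric", baselineConstrained = "logical",
                 converged = "logical"))

setValidity("SaturationFit", function(object) {
  if (object@k <= 0) return("k must be > 0")
  if (object@nComponents == 2L &&
      !(is.finite(object@k2) && object@k > object@k2 && object@k2 > 0))
    return("two-component fit needs k > k2 > 0")
  TRUE
})

# ---------------------------------------------------------------------------
# Structural comparison containers
# ---------------------------------------------------------------------------

#' An atomic coordinate model
#'
#' A flat atom table parsed from PDB or mmCIF (first model, highest-priority
#' alternate locations only).
#'
#' @slot id character(1), model label (e.g. a PDB accession).
#' @slot atoms data.frame with columns `chain, resno, resid, elety, elesy,
#'   x, y, z, o, alt, type`.
#' @export
setClass("StructureModel",
  representation(id = "character", atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  at <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(at)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (!all(is.finite(at$x)) || !all(is.finite(at$y)) || !all(is.finite(at$z)))
    return("coordinates must be finite")
  key <- paste(at$chain, at$resno, at$elety,
               if ("alt" %in% names(at)) at$alt else "")
  if (anyDuplicated(key)) return("(chain, resno, atom, altloc) must be unique")
  TRUE
})

#' Atom selection
#'
#' @slot chain character(1) or NA for any chain.
#' @slot residueRange numeric(2), inclusive range in deposited numbering
#'   (author numbering, no renumbering); `c(-Inf, Inf)` for all.
#' @slot atomNames character, atom-name filter (default Calpha only);
#'   `NA` for all atoms.
#' @slot ligand character(1), residue-name selector for heteroatoms
#'   (e.g. the biliverdin component), or NA.
#' @export
setClass("Selection",
  representation(chain = "character", residueRange = "numeric",
                 atomNames = "character", ligand = "character"),
  prototype(chain = NA_character_, residueRange = c(-Inf, Inf),
            atomNames = "CA", ligand = NA_character_))

setValidity("Selection", function(object) {
  if (length(object@residueRange) != 2 ||
      object@residueRange[1] > object@residueRange[2])
    return("residueRange must be c(start, end) with start <= end")
  TRUE
})

#' @rdname Selection-class
#' @param chain chain identifier (NA: any).
#' @param residueRange inclusive `c(start, end)` residue range.
#' @param atomNames atom-name filter; default `"CA"`, `NA` keeps all.
#' @param ligand heteroatom residue-name selector (overrides residue range).
#' @return a `Selection`.
#' @export
Selection <- function(chain = NA, residueRange = c(-Inf, Inf),
                      atomNames = "CA", ligand = NA) {
  new("Selection", chain = as.character(chain)[1],
      residueRange = as.numeric(residueRange),
      atomNames = as.character(atomNames), ligand = as.character(ligand)[1])
}

#' Rigid-body superposition result
#'
#' @slot rotation 3x3 proper rotation matrix (det = +1).
#' @slot translation numeric(3), Angstrom.
#' @slot rmsd numeric(1), minimized RMSD (Angstrom).
#' @slot nAtoms integer(1), number of paired atoms.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nAtoms = "integer"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!identical(dim(R), c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-10)
    return("rotation must be orthogonal")
  if (abs(det(R) - 1) > 1e-10) return("rotation must be proper (det = +1)")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

# ---------------------------------------------------------------------------
# Synthetic-data generator spec
# ---------------------------------------------------------------------------

#' Specification for a seeded synthetic-data generator
#'
#' @slot seed integer(1); a fixed seed makes generator output byte-identical.
#' @slot noise list with `$type` in `"none"`, `"gaussian"` (`$sd`, absolute),
#'   `"relpeak"` (`$frac` of the clean peak maximum), `"multiplicative"`
#'   (`$frac` of each clean value).
#' @slot grid list `(start, stop, count)` defining the sampling axis.
#' @slot truth stage-specific true parameter list (or an [EMGMixture-class]).
#' @export
setClass("GeneratorSpec",
  representation(seed = "integer", noise = "list", grid = "list",
                 truth = "ANY"))

setValidity("GeneratorSpec", function(object) {
  if (!object@noise$type %in% c("none", "gaussian", "relpeak", "multiplicative"))
    return("unknown noise type")
  par <- switch(object@noise$type, none = 0,
                gaussian = object@noise$sd, object@noise$frac)
  if (is.null(par) || par < 0) return("noise parameter must be >= 0")
  TRUE
})

#' @rdname GeneratorSpec-class
#' @param seed integer seed.
#' @param noise noise model list (see slots).
#' @param grid sampling-axis list `(start, stop, count)` or NULL for the
#'   generator's default.
#' @param truth true parameter set or NULL for the generator's default.
#' @return a `GeneratorSpec`.
#' @export
generatorSpec <- function(seed = 1L, noise = list(type = "none"),
                          grid = NULL, truth = NULL) {
  new("GeneratorSpec", seed = as.integer(seed), noise = noise,
      grid = if (is.null(grid)) list() else grid, truth = truth)
}

# Synthetic subclasses carry the generator's ground truth so recovery tests
# never re-enter true parameters by hand.

#' @rdname GeneratorSpec-class
#' @export
setClass("SyntheticChromatogram", contains = "Chromatogram",
         representation(truth = "list"))

#' @rdname GeneratorSpec-class
#' @export
setClass("SyntheticSpectralSeries", contains = "SpectralSeries",
         representation(truth = "list"))

#' @rdname GeneratorSpec-class
#' @export
setClass("SyntheticKineticsTrace", contains = "KineticsTrace",
         representation(truth = "list"))

#' Ground truth of a synthetic object
#'
#' @param object a synthetic container produced by a `make*` generator.
#' @return the embedded true parameter list.
#' @export
setGeneric("generatorTruth", function(object) standardGeneric("generatorTruth"))

#' @rdname generatorTruth
#' @export
setMethod("generatorTruth", "SyntheticChromatogram", function(object) object@truth)
#' @rdname generatorTruth
#' @export
setMethod("generatorTruth", "SyntheticSpectralSeries", function(object) object@truth)
#' @rdname generatorTruth
#' @export
setMethod("generatorTruth", "SyntheticKineticsTrace", function(object) object@truth)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "Chromatogram", function(object) {
  cat(sprintf("Chromatogram \"%s\": %d points, %.2f-%.2f mL, %g nm\n",
              object@label, length(object@volume), min(object@volume),
              max(object@volume), object@wavelength))
})

setMethod("show", "EMGComponent", function(object) {
  cat(sprintf("EMGComponent: area %.4g, mu %.3f mL, sigma %.3f mL, lambda %.3f /mL\n",
              object@amp, object@mu, object@sigma, object@lam))
})

setMethod("show", "EMGMixture", function(object) {
  cat("EMGMixture (tetramer + dimer + linear baseline)\n")
  cat("  tetramer: "); show(object@tetramer)
  cat("  dimer:    "); show(object@dimer)
  cat(sprintf("  baseline: b = %.4g, c = %.4g per mL\n", object@b, object@c))
})

setMethod("show", "EMGMixtureFit", function(object) {
  cat(sprintf("EMGMixtureFit: converged = %s, %d iterations, residual RMS %.3g\n",
              object@converged, object@nIter, object@residualRMS))
  show(object@model)
  tf <- tetramerFraction(object)
  cat(sprintf("  tetramer mole fraction: %.3f (SE %.3f)\n", tf$yFrac, tf$se))
})

setMethod("show", "AssociationState", function(object) {
  cat(sprintf("AssociationState: K2 = %.3g /M, Ctot = %.3g M, Y = %.4f\n",
              object@k2, object@cTot, object@yFrac))
})

setMethod("show", "SpectralSeries", function(object) {
  cat(sprintf("SpectralSeries: %d wavelengths (%g-%g nm) x %d times (%g-%g s)\n",
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths), length(object@times),
              min(object@times), max(object@times)))
})

setMethod("show", "ReversionFit", function(object) {
  if (object@degenerate) {
    cat(sprintf("ReversionFit (degenerate, single exponential): k = %.4g /s (SE %.2g)\n",
                object@k1, object@kSE[1]))
  } else {
    cat(sprintf("ReversionFit: k1 = %.4g /s (SE %.2g), k2 = %.4g /s (SE %.2g)\n",
                object@k1, object@kSE[1], object@k2, object@kSE[2]))
  }
  cat(sprintf("  %d wavelengths in %g-%g nm, residual RMS %.3g\n",
              length(object@wavelengths), object@fitWindow[1],
              object@fitWindow[2], object@residualRMS))
})

setMethod("show", "DifferenceSpectrum", function(object) {
  cat(sprintf("DifferenceSpectrum: peak %g nm, trough %g nm, change ratio %.3f\n",
              object@peakWavelength, object@troughWavelength,
              object@changeRatio))
})

setMethod("show", "KineticsTrace", function(object) {
  cat(sprintf("KineticsTrace %s%s: %d points, t = %g-%g s\n",
              object@replicateId,
              if (nzchar(object@species)) paste0(" (", object@species, ")") else "",
              length(object@times), min(object@times), max(object@times)))
})

setMethod("show", "SaturationFit", function(object) {
  cat(sprintf("SaturationFit (%d component%s): k = %.4g /s (SE %.2g)\n",
              object@nComponents, if (object@nComponents > 1) "s" else "",
              object@k, object@kSE[1]))
  if (object@nComponents == 2L)
    cat(sprintf("  k2 = %.4g /s (SE %.2g)\n", object@k2, object@kSE[2]))
  cat(sprintf("  %d replicate(s), baseline %s, residual RMS %.3g\n",
              length(object@replicateIds),
              if (object@baselineConstrained) "constrained to t=0" else "free",
              object@residualRMS))
})

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel \"%s\": %d atoms, chains %s\n", object@id,
              nrow(object@atoms),
              paste(sort(unique(object@atoms$chain)), collapse = ", ")))
})

setMethod("show", "SuperpositionResult", function(object) {
  ra <- rotationAngle(object@rotation)
  cat(sprintf("SuperpositionResult: %d atoms, rmsd %.4f A, rotation %.2f deg\n",
              object@nAtoms, object@rmsd, ra$angle))
})
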