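# Deterministic, seeded generators producing inputs with the statistical
# structure each analysis stage assumes. Every generator is a pure function
# of its GeneratorSpec (same spec => byte-identical output) and embeds its
# ground truth in the returned object.

apply_noise <- function(clean, noise, seed) {
  with_seed(seed, switch(noise$type,
    none = clean,
    gaussian = clean + stats::rnorm(length(clean), 0, noise$sd),
    relpeak = clean + stats::rnorm(length(clean), 0,
                                   noise$frac * max(abs(clean))),
    multiplicative = clean * (1 + stats::rnorm(length(clean), 0, noise$frac)),
    stop("unknown noise type: ", noise$type)))
}

grid_axis <- function(grid, default) {
  g <- utils::modifyList(default, grid)
  seq(g$start, g$stop, length.out = g$count)
}

default_sec_truth <- function() {
  # Analytical-SEC-like conditions: ~165 kDa dimer and ~330 kDa tetramer on a
  # 24 mL column; tetramers elute ~1.6 mL earlier with slightly sharper tailing.
  EMGMixture(
    tetramer = EMGComponent(amp = 0.6, lam = 4.0, mu = 10.2, sigma = 0.22),
    dimer = EMGComponent(amp = 0.4, lam = 3.5, mu = 11.8, sigma = 0.26),
    b = 0.005, c = 2e-4)
}

#' Generate a synthetic SEC chromatogram
#'
#' Evaluates a true [EMGMixture-class] on the elution grid and adds the
#' requested noise. Defaults mirror an analytical SEC run: 8-24 mL at
#' 0.02 mL steps.
#'
#' @param spec a [GeneratorSpec-class]; `truth` may be an `EMGMixture`
#'   (default: a realistic two-peak dimer/tetramer mixture).
#' @return a `SyntheticChromatogram` (a [Chromatogram-class] carrying
#'   `generatorTruth()`).
#' @export
makeChromatogram <- function(spec = generatorSpec()) {
  stopifnot(is(spec, "GeneratorSpec"))
  validObject(spec)
  v <- grid_axis(spec@grid, list(start = 8, stop = 24, count = 801))
  if (length(v) < 20) stop("grid too coarse: need at least 20 points")
  truth <- spec@truth %||% default_sec_truth()
  stopifnot(is(truth, "EMGMixture"))
  clean <- mixtureValue(truth, v)
  a <- apply_noise(clean, spec@noise, spec@seed)
  new("SyntheticChromatogram", volume = v, absorbance = a,
      wavelength = 280, label = sprintf("synthetic seed %d", spec@seed),
      truth = list(model = truth, clean = clean,
                   areaFractionTetramer =
                     truth@tetramer@amp / (truth@tetramer@amp + truth@dimer@amp)))
}

#' Generate an equilibrium titration of chromatograms
#'
#' For each total concentration the component area fractions follow the
#' dimer/tetramer isotherm `yfracEquilibrium(k2, C)` and the total peak area
#' is proportional to the loaded concentration.
#'
#' @param k2 association constant (1/M). The default 2e6 is a realistic
#'   mid-range value for a tetramerization detectable across a tenfold
#'   micromolar titration.
#' @param concentrations total subunit concentrations (M, dimer units);
#'   default 8 log-spaced points spanning 7.1e-7 to 7.1e-6 M (0.117 to
#'   1.17 mg/mL of a 165 kDa dimer).
#' @param template a [GeneratorSpec-class] supplying seed, grid and noise;
#'   chromatogram i uses seed `template@seed + i`.
#' @param areaScale total peak area per molar concentration
#'   (absorbance * mL / M).
#' @return list of `SyntheticChromatogram`; each truth records `k2`, `cTot`
#'   and the generating `yFrac`.
#' @export
makeEquilibriumSeries <- function(k2 = 2e6,
                                  concentrations = logspace(7.0909e-7,
                                                            7.0909e-6, 8),
                                  template = generatorSpec(),
                                  areaScale = 2e5) {
  stopifnot(k2 > 0, all(concentrations > 0))
  base <- template@truth %||% default_sec_truth()
  lapply(seq_along(concentrations), function(i) {
    C <- concentrations[i]
    y <- yfracEquilibrium(k2, C)
    A <- areaScale * C
    truth <- EMGMixture(
      tetramer = EMGComponent(y * A, base@tetramer@lam, base@tetramer@mu,
                              base@tetramer@sigma),
      dimer = EMGComponent((1 - y) * A, base@dimer@lam, base@dimer@mu,
                           base@dimer@sigma),
      b = base@b, c = base@c)
    sp <- generatorSpec(seed = template@seed + i, noise = template@noise,
                        grid = template@grid, truth = truth)
    out <- makeChromatogram(sp)
    out@truth$k2 <- k2
    out@truth$cTot <- C
    out@truth$yFrac <- y
    out
  })
}

#' Generate a synthetic thermal-reversion series
#'
#' Per-wavelength biexponential decays with shared rates. Default amplitude
#' shapes are two Gaussian spectral bands of opposite sign (loss of the
#' far-red-absorbing state, gain of the red-absorbing state) on the
#' 650-785 nm window, sampled at 200 times over two hours.
#'
#' @param spec a [GeneratorSpec-class]; `truth` may override `k1`, `k2` (1/s)
#'   and the per-wavelength `amp1`, `amp2`, `abs0` functions or vectors.
#' @return a `SyntheticSpectralSeries`.
#' @export
makeReversionSeries <- function(spec = generatorSpec()) {
  stopifnot(is(spec, "GeneratorSpec"))
  validObject(spec)
  wl <- grid_axis(spec@grid, list(start = 650, stop = 785, count = 28))
  tdef <- (spec@truth %||% list())$times %||% seq(0, 7200, length.out = 200)
  if (any(diff(tdef) <= 0)) stop("time grid must be increasing")
  gauss <- function(x, m, s) exp(-(x - m)^2 / (2 * s^2))
  truth <- utils::modifyList(
    list(k1 = 3e-3, k2 = 3e-4,
         amp1 = 0.100 * gauss(wl, 690, 18) - 0.070 * gauss(wl, 752, 20),
         amp2 = 0.080 * gauss(wl, 690, 18) - 0.050 * gauss(wl, 752, 20),
         abs0 = 0.150 * gauss(wl, 700, 30) + 0.02),
    spec@truth %||% list())
  stopifnot(truth$k1 > truth$k2, truth$k2 > 0)
  clean <- sapply(tdef, function(tt)
    reversionModel(truth$k1, truth$k2, truth$amp1, truth$amp2, truth$abs0, tt))
  a <- matrix(apply_noise(as.numeric(clean), spec@noise, spec@seed),
              nrow = length(wl))
  truth$times <- tdef
  truth$wavelengths <- wl
  new("SyntheticSpectralSeries", wavelengths = wl, times = tdef,
      absorbance = a, truth = truth)
}

#' Generate synthetic saturation-kinetics traces
#'
#' Replicated saturating-exponential traces with a shared true rate, or
#' paired donor/acceptor traces with conserved total label (phosphotransfer).
#'
#' @param spec a [GeneratorSpec-class]. `truth` fields: `k` (1/s, default
#'   4.7e-3), `deltaS` (default 100), `s0` (default 5), `replicates`
#'   (default 3), `paired` (logical; donor/acceptor mode), and for two
#'   components `k2`, `deltaS2`. Default time grid: 25 points over 0-7200 s.
#' @return list of `SyntheticKineticsTrace` (length `replicates`, or
#'   2 x replicates in paired mode).
#' @export
makeKineticsTrace <- function(spec = generatorSpec()) {
  stopifnot(is(spec, "GeneratorSpec"))
  validObject(spec)
  t <- grid_axis(spec@grid, list(start = 0, stop = 7200, count = 25))
  truth <- utils::modifyList(
    list(k = 4.7e-3, deltaS = 100, s0 = 5, replicates = 3L,
         paired = FALSE, k2 = NULL, deltaS2 = NULL),
    spec@truth %||% list())
  out <- list()
  for (r in seq_len(truth$replicates)) {
    clean <- saturationModel(truth$deltaS, truth$k, truth$s0, t)
    if (!is.null(truth$k2))
      clean <- clean + truth$deltaS2 * (1 - exp(-truth$k2 * t))
    if (truth$paired) {
      # donor starts loaded and loses label; acceptor gains it; sum conserved
      donor <- truth$s0 + truth$deltaS -
        truth$deltaS * (1 - exp(-truth$k * t))
      acceptor <- truth$s0 + truth$deltaS * (1 - exp(-truth$k * t))
      dn <- apply_noise(donor, spec@noise, spec@seed + 2L * r)
      an <- apply_noise(acceptor, spec@noise, spec@seed + 2L * r + 1L)
      out[[length(out) + 1]] <- new("SyntheticKineticsTrace", times = t,
        signal = pmax(dn, 0), replicateId = sprintf("r%d", r),
        species = "donor", truth = truth)
      out[[length(out) + 1]] <- new("SyntheticKineticsTrace", times = t,
        signal = pmax(an, 0), replicateId = sprintf("r%d", r),
        species = "acceptor", truth = truth)
    } else {
      s <- apply_noise(clean, spec@noise, spec@seed + r)
      out[[length(out) + 1]] <- new("SyntheticKineticsTrace", times = t,
        signal = pmax(s, 0), replicateId = sprintf("r%d", r),
        species = "", truth = truth)
    }
  }
  out
}

# Rotate points about an axis through a pivot (Rodrigues).
rotate_about_axis <- function(xyz, angle_deg, axis, pivot) {
  th <- angle_deg * pi / 180
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, "+")
}

ideal_helix <- function(n, start = c(0, 0, 0), axis = c(0, 0, 1),
                        radius = 2.3, rise = 1.5, turn = 100) {
  # Calpha trace of an ideal alpha-helix along `axis`
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- pracma::cross(a, ref); u <- u / sqrt(sum(u^2))
  w <- pracma::cross(a, u)
  i <- seq_len(n) - 1
  ang <- i * turn * pi / 180
  t(vapply(seq_len(n), function(j)
    start + radius * cos(ang[j]) * u + radius * sin(ang[j]) * w +
      i[j] * rise * a, numeric(3)))
}

#' Generate a pair of structures related by a known domain rotation
#'
#' Builds a two-domain Calpha scaffold (two ideal helices per domain), an
#' optional planar five-atom ring, and a second state in which the mobile
#' domain is rotated by a stated angle about a stated hinge axis and the
#' ring is flipped about an in-plane axis. Ground truth is returned
#' alongside the two [StructureModel-class] objects; both are writable as
#' PDB fixtures via [writeStructurePdb()].
#'
#' @param spec a [GeneratorSpec-class]. `truth` fields: `angle` (degrees in
#'   `[0, 180]`, default 35 -- the scale of a photocycle domain rotation),
#'   `axis` (default `c(0, 1, 0)`), `pivot` (default `c(0, 0, 58)`),
#'   `ringFlip` (degrees, default 161 -- the scale of a chromophore D-ring
#'   flip), `noiseSd` (coordinate jitter, default 0).
#' @return list with `stateA`, `stateB` ([StructureModel-class]) and `truth`.
#'   The fixed domain is chain A residues 1-76 (two crossed helices), the
#'   mobile domain residues 101-176, the ring is `RNG` residue 301 with
#'   atoms `C1..C5`.
#' @export
makeRotatedPair <- function(spec = generatorSpec()) {
  stopifnot(is(spec, "GeneratorSpec"))
  validObject(spec)
  truth <- utils::modifyList(
    list(angle = 35, axis = c(0, 1, 0), pivot = c(0, 0, 58),
         ringFlip = 161, noiseSd = 0),
    spec@truth %||% list())
  if (truth$angle < 0 || truth$angle > 180)
    stop("rotation angle must be inside [0, 180] degrees")
  # fixed domain: two crossed helices so its Kabsch frame is well conditioned
  f1 <- ideal_helix(38, start = c(0, 0, 0), axis = c(0, 0, 1))
  f2 <- ideal_helix(38, start = c(9, 0, 54),
                    axis = c(sin(0.3), 0, -cos(0.3)))
  # mobile domain: two helices above the hinge point
  m1 <- ideal_helix(38, start = c(0, 6, 60), axis = c(0, 0, 1))
  m2 <- ideal_helix(38, start = c(8, 6, 114), axis = c(0.2, 0.1, -0.975))
  ring <- {
    ang <- 2 * pi * (0:4) / 5
    cbind(1.2 * cos(ang), 1.2 * sin(ang), 0) +
      matrix(c(4, 2, 20), 5, 3, byrow = TRUE)
  }
  ca <- rbind(f1, f2, m1, m2)
  resno <- c(1:38, 39:76, 101:138, 139:176)
  atoms_of <- function(ca, ring) {
    rbind(
      data.frame(chain = "A", resno = resno, resid = "ALA", elety = "CA",
                 elesy = "C", x = ca[, 1], y = ca[, 2], z = ca[, 3], o = 1,
                 alt = "", type = "ATOM", stringsAsFactors = FALSE),
      data.frame(chain = "A", resno = 301, resid = "RNG",
                 elety = paste0("C", 1:5), elesy = "C", x = ring[, 1],
                 y = ring[, 2], z = ring[, 3], o = 1, alt = "",
                 type = "HETATM", stringsAsFactors = FALSE))
  }
  mobile_rows <- resno >= 101
  caB <- ca
  caB[mobile_rows, ] <- rotate_about_axis(ca[mobile_rows, , drop = FALSE],
                                          truth$angle, truth$axis,
                                          truth$pivot)
  ringB <- rotate_about_axis(ring, truth$ringFlip, c(1, 0, 0),
                             colMeans(ring))
  atomsA <- atoms_of(ca, ring)
  atomsB <- atoms_of(caB, ringB)
  if (truth$noiseSd > 0) {
    jitter <- function(at, seed) {
      with_seed(seed, {
        n <- nrow(at)
        at$x <- at$x + stats::rnorm(n, 0, truth$noiseSd)
        at$y <- at$y + stats::rnorm(n, 0, truth$noiseSd)
        at$z <- at$z + stats::rnorm(n, 0, truth$noiseSd)
      })
      at
    }
    atomsA <- jitter(atomsA, spec@seed)
    atomsB <- jitter(atomsB, spec@seed + 1L)
  }
  list(stateA = StructureModel(atomsA, id = "synthetic_state_a"),
       stateB = StructureModel(atomsB, id = "synthetic_state_b"),
       truth = truth,
       fixedSel = Selection(chain = "A", residueRange = c(1, 76)),
       mobileSel = Selection(chain = "A", residueRange = c(101, 176)),
       ringSel = Selection(chain = "A", atomNames = paste0("C", 1:5),
                           ligand = "RNG"))
}
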