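# Exponentially modified Gaussian peak model and the two-component SEC
# deconvolution fit.

#' Evaluate one EMG peak component
#'
#' The exponentially modified Gaussian is the density of Gaussian(mu, sigma)
#' elution broadening convolved with Exponential(lam) column tailing, scaled
#' by the peak area `amp`:
#' \deqn{0.5\,amp\,\lambda\,
#'   e^{0.5\lambda(2\mu+\lambda\sigma^2-2V_e)}\,
#'   \mathrm{erfc}\!\left(\frac{\mu+\lambda\sigma^2-V_e}{\sqrt2\,\sigma}\right).}
#' Evaluation uses the algebraically identical overflow-free form
#' \eqn{0.5\,amp\,\lambda\, e^{-(V_e-\mu)^2/(2\sigma^2)}\,\mathrm{erfcx}(z)}
#' for \eqn{z \ge 0}; the naive exponential would overflow for
#' \eqn{V_e \ll \mu}.
#'
#' @param component an [EMGComponent-class].
#' @param volume elution volume(s), mL; vectorized.
#' @return nonnegative finite absorbance values, one per volume.
#' @examples
#' emgValue(EMGComponent(1, 2, 12, 0.3), seq(10, 14, 0.5))
#' @export
emgValue <- function(component, volume) {
  stopifnot(is(component, "EMGComponent"))
  validObject(component)
  if (!all(is.finite(volume))) stop("volume must be finite")
  amp <- component@amp; lam <- component@lam
  mu <- component@mu; sigma <- component@sigma
  if (amp == 0) return(numeric(length(volume)) + 0 * volume)
  z <- (mu + lam * sigma^2 - volume) / (sqrt(2) * sigma)
  out <- numeric(length(volume))
  pos <- z >= 0
  if (any(pos)) {
    out[pos] <- 0.5 * amp * lam *
      exp(-(volume[pos] - mu)^2 / (2 * sigma^2)) * erfcx_stable(z[pos])
  }
  if (any(!pos)) {
    # z < 0 implies V_e > mu + lam*sigma^2, where the printed exponent
    # lam*(mu - V_e) + lam^2 sigma^2 / 2 is negative: the naive form is safe.
    out[!pos] <- 0.5 * amp * lam *
      exp(lam * (mu - volume[!pos]) + 0.5 * lam^2 * sigma^2) *
      pracma::erfc(z[!pos])
  }
  pmax(out, 0)
}

#' Evaluate the two-component SEC model
#'
#' Tetramer EMG + dimer EMG + linear baseline `b + c * volume`.
#'
#' @param model an [EMGMixture-class].
#' @param volume elution volume(s), mL.
#' @return absorbance values.
#' @export
mixtureValue <- function(model, volume) {
  stopifnot(is(model, "EMGMixture"))
  validObject(model)
  emgValue(model@tetramer, volume) + emgValue(model@dimer, volume) +
    model@b + model@c * volume
}

# Flatten an EMGMixture to the canonical 10-parameter vector and back.
emg_par_names <- c("ampT", "lamT", "muT", "sigmaT",
                   "ampD", "lamD", "muD", "sigmaD", "b", "c")

mixture_to_par <- function(model) {
  stats::setNames(
    c(model@tetramer@amp, model@tetramer@lam, model@tetramer@mu,
      model@tetramer@sigma, model@dimer@amp, model@dimer@lam,
      model@dimer@mu, model@dimer@sigma, model@b, model@c),
    emg_par_names)
}

par_to_mixture <- function(p) {
  EMGMixture(
    tetramer = EMGComponent(p[["ampT"]], p[["lamT"]], p[["muT"]], p[["sigmaT"]]),
    dimer = EMGComponent(p[["ampD"]], p[["lamD"]], p[["muD"]], p[["sigmaD"]]),
    b = p[["b"]], c = p[["c"]])
}

# Automatic initialization: mu seeds at the two highest local maxima of a
# lightly smoothed trace, sigma from the half-width at 60% height, lambda at
# 2/sigma, areas by trapezoids split at the inter-peak minimum, baseline from
# the outer 5% of points.
auto_init_emg <- function(v, a) {
  n <- length(v)
  edge <- unique(c(seq_len(max(2, floor(0.05 * n))),
                   seq(n - max(2, floor(0.05 * n)) + 1, n)))
  bl <- stats::lm(a[edge] ~ v[edge])
  b0 <- unname(stats::coef(bl)[1]); c0 <- unname(stats::coef(bl)[2])
  y <- a - (b0 + c0 * v)
  w <- max(3, round(n / 100))
  sm <- stats::filter(y, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- y[is.na(sm)]
  sm <- as.numeric(sm)
  locmax <- which(diff(sign(diff(sm))) < 0) + 1L
  locmax <- locmax[order(sm[locmax], decreasing = TRUE)]
  if (length(locmax) == 0) locmax <- which.max(sm)
  if (length(locmax) == 1) {
    # single visible peak: seed a shadow component slightly earlier
    i1 <- locmax[1]
    mu1 <- v[i1] - 0.05 * diff(range(v)); mu2 <- v[i1]
  } else {
    pk <- sort(v[locmax[1:2]])
    mu1 <- pk[1]; mu2 <- pk[2]
  }
  half_width <- function(mu) {
    i <- which.min(abs(v - mu)); h <- 0.6 * max(sm[i], 1e-12)
    lo <- i; while (lo > 1 && sm[lo] > h) lo <- lo - 1
    hi <- i; while (hi < n && sm[hi] > h) hi <- hi + 1
    max((v[hi] - v[lo]) / 2, 2 * mean(diff(v)))
  }
  s1 <- half_width(mu1); s2 <- half_width(mu2)
  isplit <- {
    ii <- which(v > mu1 & v < mu2)
    if (length(ii)) ii[which.min(sm[ii])] else which.min(abs(v - (mu1 + mu2) / 2))
  }
  trap <- function(idx) {
    if (length(idx) < 2) return(1e-8)
    max(sum(diff(v[idx]) * (y[idx][-1] + y[idx][-length(idx)]) / 2), 1e-8)
  }
  a1 <- trap(seq_len(isplit)); a2 <- trap(isplit:n)
  stats::setNames(c(a1, 2 / s1, mu1, s1, a2, 2 / s2, mu2, s2, b0, c0),
                  emg_par_names)
}

#' Deconvolve a chromatogram into tetramer and dimer EMG peaks
#'
#' Bounded Levenberg-Marquardt least squares of the 10-parameter
#' [EMGMixture-class] model. When `init` is omitted, starting values come
#' from peak-picking on a lightly smoothed trace. After convergence the
#' component eluting first is labelled tetramer (larger hydrodynamic size
#' elutes earlier).
#'
#' @param data a [Chromatogram-class].
#' @param init optional [EMGMixture-class] starting model.
#' @param bounds optional list with numeric vectors `$lower`/`$upper` of
#'   length 10 in the order `ampT, lamT, muT, sigmaT, ampD, lamD, muD,
#'   sigmaD, b, c`.
#' @param window optional `c(min, max)` elution-volume window (mL) to fit.
#' @return an [EMGMixtureFit-class]. Non-convergence is reported via
#'   `converged = FALSE`, never silently.
#' @export
fitEMGMixture <- function(data, init = NULL, bounds = NULL, window = NULL) {
  stopifnot(is(data, "Chromatogram"))
  validObject(data)
  v <- data@volume; a <- data@absorbance
  if (!is.null(window)) {
    keep <- v >= window[1] & v <= window[2]
    v <- v[keep]; a <- a[keep]
  }
  if (length(v) < 10)
    stop("insufficient data: fewer points than free parameters")
  p0 <- if (is.null(init)) auto_init_emg(v, a) else mixture_to_par(init)
  lower <- c(0, 1e-6, min(v) - diff(range(v)), 1e-4,
             0, 1e-6, min(v) - diff(range(v)), 1e-4, -Inf, -Inf)
  upper <- c(Inf, 1e4, max(v) + diff(range(v)), diff(range(v)),
             Inf, 1e4, max(v) + diff(range(v)), diff(range(v)), Inf, Inf)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower <- bounds$lower
    if (!is.null(bounds$upper)) upper <- bounds$upper
  }
  p0 <- pmin(pmax(p0, lower), upper)
  resid_fn <- function(p) {
    names(p) <- emg_par_names
    val <- tryCatch(mixtureValue_raw(p, v), error = function(e) rep(1e6, length(v)))
    val - a
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-8,
                                         ftol = 1e-12))
  p <- stats::setNames(fit$par, emg_par_names)
  # enforce peak identity: smaller mu is the tetramer
  if (p[["muT"]] > p[["muD"]]) {
    p <- p[c(5:8, 1:4, 9, 10)]
    names(p) <- emg_par_names
  }
  n <- length(v); npar <- length(p)
  res <- mixtureValue_raw(p, v) - a
  sigma2 <- sum(res^2) / max(n - npar, 1)
  jtj <- jtj_emg(p, v)
  covmat <- cov_from_jtj(jtj, sigma2)
  dimnames(covmat) <- list(emg_par_names, emg_par_names)
  # guard against exactly coincident centers from a degenerate relabel
  if (p[["muT"]] >= p[["muD"]]) p[["muT"]] <- p[["muD"]] - 1e-9
  new("EMGMixtureFit", model = par_to_mixture(p),
      residualRMS = sqrt(mean(res^2)), covariance = covmat,
      converged = fit$info %in% 1:4, nIter = as.integer(fit$niter))
}

# model value straight from a parameter vector (no S4 construction in the
# optimizer hot loop, and no tetramer-first ordering constraint while the
# optimizer explores)
mixtureValue_raw <- function(p, v) {
  emg_raw(p[["ampT"]], p[["lamT"]], p[["muT"]], p[["sigmaT"]], v) +
    emg_raw(p[["ampD"]], p[["lamD"]], p[["muD"]], p[["sigmaD"]], v) +
    p[["b"]] + p[["c"]] * v
}

emg_raw <- function(amp, lam, mu, sigma, v) {
  if (amp == 0 || lam <= 0 || sigma <= 0) return(numeric(length(v)))
  z <- (mu + lam * sigma^2 - v) / (sqrt(2) * sigma)
  out <- numeric(length(v))
  pos <- z >= 0
  if (any(pos))
    out[pos] <- 0.5 * amp * lam * exp(-(v[pos] - mu)^2 / (2 * sigma^2)) *
      erfcx_stable(z[pos])
  if (any(!pos))
    out[!pos] <- 0.5 * amp * lam *
      exp(lam * (mu - v[!pos]) + 0.5 * lam^2 * sigma^2) * pracma::erfc(z[!pos])
  out
}

# finite-difference J'J of the mixture model at p (for covariance only)
jtj_emg <- function(p, v) {
  f0 <- mixtureValue_raw(p, v)
  J <- matrix(0, length(v), length(p))
  for (j in seq_along(p)) {
    h <- max(abs(p[[j]]), 1e-6) * 1e-6
    ph <- p; ph[[j]] <- ph[[j]] + h
    J[, j] <- (mixtureValue_raw(ph, v) - f0) / h
  }
  crossprod(J)
}

#' Tetramer mole fraction from a mixture fit
#'
#' Area fraction `ampT / (ampT + ampD)`, assuming equal extinction per
#' subunit at the detection wavelength (absorbance at 280 nm is proportional
#' to subunit count); the baseline is excluded. The standard error is
#' propagated from the fit covariance by the delta method.
#'
#' @param fit an [EMGMixtureFit-class].
#' @return list with `yFrac` (in `[0, 1]`) and `se`.
#' @export
tetramerFraction <- function(fit) {
  stopifnot(is(fit, "EMGMixtureFit"))
  aT <- fit@model@tetramer@amp; aD <- fit@model@dimer@amp
  tot <- aT + aD
  if (tot <= 0) stop("undefined fraction: both component areas are zero")
  y <- aT / tot
  g <- c(aD, -aT) / tot^2
  S <- fit@covariance[c("ampT", "ampD"), c("ampT", "ampD")]
  se <- sqrt(max(drop(t(g) %*% S %*% g), 0))
  list(yFrac = y, se = se)
}
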