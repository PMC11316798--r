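# Autophosphorylation / phosphotransfer kinetics: saturating exponentials
# with a globally shared rate constant across replicate traces.

#' Saturating-exponential kinetics model
#'
#' `S(t) = deltaS * (1 - exp(-k t)) + s0`: monotone from `s0` at t = 0 to
#' `s0 + deltaS` at saturation. A negative `deltaS` describes a donor losing
#' label during phosphotransfer.
#'
#' @param deltaS amplitude (counts), sign-free.
#' @param k rate constant (1/s), > 0.
#' @param s0 baseline signal at t = 0 (counts).
#' @param t time(s), s; vectorized.
#' @return signal values.
#' @export
saturationModel <- function(deltaS, k, s0, t) {
  if (!is.finite(k) || k <= 0) stop("k must be > 0")
  deltaS * (1 - exp(-k * t)) + s0
}

# Per-trace linear solve given shared rate(s). Returns list(rss, coefs),
# coefs a matrix with rows deltaS[, deltaS2][, s0].
sat_project <- function(rates, traces, constrain) {
  rss <- 0
  coefs <- lapply(traces, function(tr) {
    t <- tr@times; s <- tr@signal
    basis <- vapply(rates, function(k) 1 - exp(-k * t), numeric(length(t)))
    if (constrain) {
      s0 <- s[t == 0][1]
      b <- qr.coef(qr(basis), s - s0)
      fitted <- basis %*% b + s0
      rss <<- rss + sum((s - fitted)^2)
      c(b, s0)
    } else {
      X <- cbind(basis, 1)
      b <- qr.coef(qr(X), s)
      rss <<- rss + sum((s - X %*% b)^2)
      b
    }
  })
  list(rss = rss, coefs = do.call(cbind, coefs))
}

#' Fit saturation kinetics with a globally shared rate
#'
#' One (or two) rate constants are shared across all traces; amplitudes and
#' baselines float per trace, except that `constrainBaseline = TRUE` fixes
#' each baseline to that trace's measured t = 0 signal and removes it from
#' the free-parameter set (the phosphotransfer protocol). The problem is
#' separable: rates are optimized on a log grid plus local refinement, with
#' the linear parameters solved conditionally by least squares.
#'
#' @param traces a [KineticsTrace-class] or list of them (replicates).
#' @param nComponents 1 or 2 saturating components; with two, `k > k2` by
#'   relabeling.
#' @param constrainBaseline fix per-trace baselines at the t = 0 signal.
#' @param rateRange search range for the rate grid (1/s).
#' @return a [SaturationFit-class]; the rate SE comes from the full
#'   Jacobian-based covariance with homoscedastic residual variance.
#' @export
fitSaturation <- function(traces, nComponents = 1,
                          constrainBaseline = FALSE,
                          rateRange = c(1e-5, 1)) {
  if (is(traces, "KineticsTrace")) traces <- list(traces)
  stopifnot(length(traces) >= 1, all(vapply(traces, is, TRUE, "KineticsTrace")))
  lapply(traces, validObject)
  nComponents <- as.integer(nComponents)
  stopifnot(nComponents %in% 1:2)
  if (constrainBaseline &&
      !all(vapply(traces, function(tr) any(tr@times == 0), TRUE)))
    stop("baseline constraint requires a t = 0 observation in every trace")
  if (all(vapply(traces, function(tr) stats::var(tr@signal) == 0, TRUE)))
    stop("no information: all traces are flat")
  if (nComponents == 2L &&
      any(vapply(traces, function(tr) length(tr@times), 1L) < 8))
    warning("two components with < 8 points per trace: over-parameterized")

  grid <- logspace(rateRange[1], rateRange[2], 40)
  if (nComponents == 1L) {
    rssg <- vapply(grid, function(k) sat_project(k, traces, constrainBaseline)$rss,
                   numeric(1))
    o <- stats::optimize(function(lk)
      sat_project(exp(lk), traces, constrainBaseline)$rss,
      interval = log(grid[which.min(rssg)]) + c(-1.5, 1.5), tol = 1e-14)
    ks <- exp(o$minimum)
  } else {
    pairs <- which(outer(grid, grid, ">"), arr.ind = TRUE)
    rssg <- apply(pairs, 1, function(ij)
      sat_project(grid[ij], traces, constrainBaseline)$rss)
    best <- grid[pairs[which.min(rssg), ]]
    o <- stats::optim(log(best), function(lk)
      sat_project(exp(lk), traces, constrainBaseline)$rss,
      method = "Nelder-Mead", control = list(reltol = 1e-14, maxit = 2000))
    ks <- sort(exp(o$par), decreasing = TRUE)
  }
  pr <- sat_project(ks, traces, constrainBaseline)
  n_obs <- sum(vapply(traces, function(tr) length(tr@times), 1L))
  npar <- nComponents +
    length(traces) * (nComponents + if (constrainBaseline) 0L else 1L)
  sigma2 <- pr$rss / max(n_obs - npar, 1)
  se <- sat_rate_se(ks, pr$coefs, traces, constrainBaseline, sigma2)

  ids <- vapply(traces, function(tr) tr@replicateId, "")
  if (nComponents == 1L) {
    new("SaturationFit", k = ks, k2 = NA_real_, nComponents = 1L,
        deltaS = unname(pr$coefs[1, ]), deltaS2 = numeric(length(traces)),
        s0 = unname(pr$coefs[2, ]), replicateIds = ids,
        kSE = se, residualRMS = sqrt(pr$rss / n_obs),
        baselineConstrained = constrainBaseline, converged = TRUE)
  } else {
    new("SaturationFit", k = ks[1], k2 = ks[2], nComponents = 2L,
        deltaS = unname(pr$coefs[1, ]), deltaS2 = unname(pr$coefs[2, ]),
        s0 = unname(pr$coefs[3, ]), replicateIds = ids,
        kSE = se, residualRMS = sqrt(pr$rss / n_obs),
        baselineConstrained = constrainBaseline, converged = TRUE)
  }
}

sat_rate_se <- function(rates, coefs, traces, constrain, sigma2) {
  nr <- length(rates)
  nlin <- nr + if (constrain) 0L else 1L
  npar <- nr + nlin * length(traces)
  rows <- sum(vapply(traces, function(tr) length(tr@times), 1L))
  J <- matrix(0, rows, npar)
  at <- 0
  for (w in seq_along(traces)) {
    t <- traces[[w]]@times
    idx <- at + seq_along(t); at <- at + length(t)
    for (r in seq_len(nr))
      J[idx, r] <- coefs[r, w] * t * exp(-rates[r] * t)
    basis <- vapply(rates, function(k) 1 - exp(-k * t), numeric(length(t)))
    X <- if (constrain) basis else cbind(basis, 1)
    J[idx, nr + (w - 1L) * nlin + seq_len(nlin)] <- X
  }
  covk <- cov_from_jtj(crossprod(J), sigma2)
  sqrt(pmax(diag(covk)[seq_len(nr)], 0))
}
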