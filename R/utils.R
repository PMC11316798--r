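# Internal numerical helpers shared across modules.

#' Scaled complementary error function, stable for large arguments
#'
#' erfcx(z) = exp(z^2) * erfc(z). `pracma::erfcx` evaluates the product
#' naively and underflows to NaN for z > ~26.5; above a cutoff we switch to
#' the asymptotic expansion erfcx(z) ~ (z*sqrt(pi))^-1 * sum (-1)^n (2n-1)!! /
#' (2 z^2)^n, whose truncation error at the cutoff is far below 1e-14
#' relative.
#'
#' @param z numeric vector, must be >= 0 (negative arguments are handled by
#'   the callers via the unscaled branch).
#' @return erfcx(z), same length as `z`.
#' @keywords internal
#' @noRd
erfcx_stable <- function(z) {
  stopifnot(all(z >= 0))
  out <- numeric(length(z))
  small <- z <= 25
  if (any(small)) out[small] <- pracma::erfcx(z[small])
  if (any(!small)) {
    zz <- z[!small]
    u <- 1 / (2 * zz^2)
    s <- 1 - u + 3 * u^2 - 15 * u^3 + 105 * u^4 - 945 * u^5
    out[!small] <- s / (zz * sqrt(pi))
  }
  out
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream (generators must be pure functions of their spec).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Robust covariance from a (possibly near-singular) JtJ matrix.
cov_from_jtj <- function(jtj, sigma2) {
  inv <- tryCatch(chol2inv(chol(jtj)), error = function(e) {
    s <- svd(jtj)
    pos <- s$d > max(s$d) * 1e-12
    s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  })
  sigma2 * inv
}

# log-spaced grid
logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

clamp1 <- function(x) pmin(1, pmax(-1, x))

`%||%` <- function(a, b) if (is.null(a)) b else a
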