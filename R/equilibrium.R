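# Closed-form dimer <-> tetramer association isotherm and the descriptive
# K2 trendline fit.
#
# Model: 2 D <-> T with K2 = [T]/[D]^2. "Subunit" is the intact dimer, so the
# mass balance is Ctot = [D] + 2[T] and the tetramer mole fraction is
# Ybar = 2[T]/Ctot. Eliminating [D] gives the closed form
#   Ybar = 2(4x + 1 - sqrt(1 + 8x)) / (8x),  x = K2 * Ctot,
# evaluated here in the cancellation-free equivalent form
#   Ybar = 4x / (1 + 4x + sqrt(1 + 8x)).

#' Tetramer mole fraction at equilibrium
#'
#' @param k2 association constant (1/M), > 0.
#' @param cTot total subunit concentration (M, dimer units), >= 0; vectorized.
#' @return mole fraction of subunits assembled into tetramers, in `[0, 1)`,
#'   continuous at `cTot = 0` with limit 0 and strictly increasing in `cTot`.
#' @examples
#' yfracEquilibrium(1e6, 1e-6)  # K2*Ctot = 1 -> 0.5
#' @export
yfracEquilibrium <- function(k2, cTot) {
  if (any(!is.finite(k2)) || any(k2 <= 0)) stop("k2 must be > 0")
  if (any(!is.finite(cTot)) || any(cTot < 0)) stop("cTot must be >= 0")
  x <- k2 * cTot
  4 * x / (1 + 4 * x + sqrt(1 + 8 * x))
}

#' Invert the tetramer isotherm
#'
#' Returns the dimensionless product `K2 * Ctot` that yields a given tetramer
#' mole fraction: `Ybar / (2 (1 - Ybar)^2)`.
#'
#' @param yFrac mole fraction(s) strictly inside (0, 1).
#' @return `K2 * Ctot` product(s); `yfracEquilibrium` applied to the result
#'   reproduces `yFrac`.
#' @examples
#' invertYfrac(0.5)   # 1
#' invertYfrac(0.84)  # 16.40625
#' @export
invertYfrac <- function(yFrac) {
  if (any(!is.finite(yFrac)) || any(yFrac <= 0) || any(yFrac >= 1))
    stop("yFrac must be strictly inside (0, 1)")
  yFrac / (2 * (1 - yFrac)^2)
}

#' Fit the association constant to a titration of tetramer fractions
#'
#' Least-squares K2 minimizing `sum((Y_obs - yfracEquilibrium(K2, C))^2)`.
#' With a single point this is the exact closed form
#' `invertYfrac(Y) / C`. The titration points of a SEC experiment need not
#' represent a system at equilibrium during elution, so the fitted K2 is a
#' descriptive trendline; reports label it as such.
#'
#' @param cTot concentrations (M, dimer units).
#' @param yFrac observed tetramer mole fractions, same length.
#' @return list with `k2` (1/M), `se`, `residualRMS`, and `trendline = TRUE`
#'   (a reminder that the constant describes a trend, not a certified
#'   equilibrium measurement).
#' @export
fitAssociationConstant <- function(cTot, yFrac) {
  stopifnot(length(cTot) == length(yFrac), length(cTot) >= 1)
  ok <- yFrac > 0 & yFrac < 1
  if (!any(ok)) stop("no information: all fractions at the [0, 1] bounds")
  cTot <- cTot[ok]; yFrac <- yFrac[ok]
  single <- invertYfrac(yFrac) / cTot
  if (length(cTot) == 1) {
    return(list(k2 = single, se = NA_real_, residualRMS = 0,
                trendline = TRUE))
  }
  ssr <- function(logk) sum((yFrac - yfracEquilibrium(exp(logk), cTot))^2)
  opt <- stats::optimize(ssr, interval = log(range(single)) + c(-3, 3),
                         tol = 1e-12)
  k2 <- exp(opt$minimum)
  res <- yFrac - yfracEquilibrium(k2, cTot)
  sigma2 <- sum(res^2) / max(length(cTot) - 1, 1)
  h <- k2 * 1e-6
  J <- (yfracEquilibrium(k2 + h, cTot) - yfracEquilibrium(k2 - h, cTot)) / (2 * h)
  se <- sqrt(sigma2 / sum(J^2))
  list(k2 = k2, se = se, residualRMS = sqrt(mean(res^2)), trendline = TRUE)
}

#' Convert a mass concentration to molar subunit concentration
#'
#' The association model counts intact dimers as subunits; the default molar
#' mass is the 165 kDa dimer (2 x 745-residue chains).
#'
#' @param mg_per_ml mass concentration (mg/mL).
#' @param molarMassKDa subunit (dimer) molar mass in kDa.
#' @return molar concentration (M).
#' @export
mgPerMlToMolar <- function(mg_per_ml, molarMassKDa = 165) {
  mg_per_ml / (molarMassKDa * 1000)
}
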