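test_that("biexponential model obeys its boundary identities", {
  expect_equal(reversionModel(0.01, 0.001, 0.2, 0.1, 0.05, 0), 0.35)
  expect_equal(reversionModel(0.01, 0.001, 1, 0, 0, log(2) / 0.01), 0.5)
  # amp2 = 0 reduces exactly to a single exponential
  t <- seq(0, 500, 25)
  expect_equal(reversionModel(0.01, 0.5, 2, 0, 0.1, t),
               2 * exp(-0.01 * t) + 0.1)
  expect_error(reversionModel(-1, 0.1, 1, 1, 0, 0), "rate")
})

test_that("global rates are recovered exactly from noiseless data", {
  s <- makeReversionSeries(generatorSpec(seed = 5))
  fit <- fitGlobalBiexponential(s)
  truth <- generatorTruth(s)
  expect_false(fit@degenerate)
  expect_equal(fit@k1, truth$k1, tolerance = 1e-6)
  expect_equal(fit@k2, truth$k2, tolerance = 1e-6)
  expect_equal(fit@amp1, truth$amp1, tolerance = 1e-4)
  expect_equal(fit@abs0, truth$abs0, tolerance = 1e-6)
})

test_that("global rates survive 1% absorbance noise within 2%", {
  s <- makeReversionSeries(generatorSpec(seed = 9,
                                         noise = list(type = "gaussian",
                                                      sd = 1e-3)))
  fit <- fitGlobalBiexponential(s)
  truth <- generatorTruth(s)
  expect_lt(abs(fit@k1 - truth$k1) / truth$k1, 0.02)
  expect_lt(abs(fit@k2 - truth$k2) / truth$k2, 0.02)
  expect_true(all(fit@kSE > 0))
})

test_that("a series with no second component collapses to one exponential", {
  s <- makeReversionSeries(generatorSpec(seed = 5,
                                         truth = list(amp2 = rep(0, 28))))
  expect_warning(fit <- fitGlobalBiexponential(s), "degenerate")
  expect_true(fit@degenerate)
  expect_equal(fit@k1, generatorTruth(s)$k1, tolerance = 0.01)
  expect_true(is.na(fit@k2))
})

test_that("variable projection matches a full joint nonlinear fit", {
  # small instance: 3 wavelengths x 20 times, rates by joint optimization of
  # all 11 parameters as the independent route
  wl <- c(660, 700, 740)
  t <- seq(0, 4000, length.out = 20)
  truth <- list(k1 = 2e-3, k2 = 4e-4,
                amp1 = c(0.08, 0.12, -0.05), amp2 = c(0.05, 0.04, -0.03),
                abs0 = c(0.05, 0.1, 0.08), times = t)
  # noiseless: the RSS minimum is a point, so two independently converged
  # optimizers must coincide (with noise the minimum is too flat for a
  # 1e-6 comparison between optimizers)
  s <- makeReversionSeries(generatorSpec(
    seed = 21, grid = list(start = 660, stop = 740, count = 3),
    truth = truth))
  fit <- fitGlobalBiexponential(s, window = c(650, 750))
  joint_obj <- function(p) {
    k <- exp(p[1:2])
    B <- matrix(p[-(1:2)], nrow = 3)
    pred <- sapply(t, function(tt)
      B[, 1] * exp(-k[1] * tt) + B[, 2] * exp(-k[2] * tt) + B[, 3])
    sum((s@absorbance - pred)^2)
  }
  p0 <- c(log(c(truth$k1, truth$k2)) + 0.2,
          truth$amp1 * 1.1, truth$amp2 * 0.9, truth$abs0 + 0.01)
  joint <- optim(p0, joint_obj, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
  polished <- nlminb(joint$par, joint_obj,
                     control = list(rel.tol = 1e-15, x.tol = 1e-14,
                                    eval.max = 10000, iter.max = 10000))
  kj <- sort(exp(polished$par[1:2]), decreasing = TRUE)
  expect_equal(fit@k1, kj[1], tolerance = 1e-6)
  expect_equal(fit@k2, kj[2], tolerance = 1e-6)
})

test_that("fitted rates do not depend on wavelength labelling", {
  s <- makeReversionSeries(generatorSpec(seed = 9,
                                         noise = list(type = "gaussian",
                                                      sd = 1e-3)))
  fit1 <- fitGlobalBiexponential(s)
  set.seed(42)
  perm <- sample(length(s@wavelengths))
  s2 <- SpectralSeries(s@wavelengths, s@times,
                       s@absorbance[perm, , drop = FALSE])
  fit2 <- fitGlobalBiexponential(s2)
  expect_equal(fit1@k1, fit2@k1, tolerance = 1e-12)
  expect_equal(fit1@k2, fit2@k2, tolerance = 1e-12)
})

test_that("rate standard errors shrink like one over sqrt(time points)", {
  se_at <- function(n) {
    s <- makeReversionSeries(generatorSpec(
      seed = 31, noise = list(type = "gaussian", sd = 1e-3),
      truth = list(times = seq(0, 7200, length.out = n))))
    fitGlobalBiexponential(s)@kSE
  }
  r <- se_at(50) / se_at(200)   # expect ~ sqrt(200/50) = 2
  expect_true(all(r > 2 / 1.5 & r < 2 * 1.5))
})

test_that("difference spectra locate bands and the change ratio", {
  wl <- seq(550, 850, by = 1)
  base <- 0.2 * exp(-(wl - 700)^2 / (2 * 40^2))
  a <- base + 0.10 * exp(-(wl - 700)^2 / (2 * 15^2))
  b <- base + 0.05 * exp(-(wl - 755)^2 / (2 * 15^2))
  ds <- differenceSpectrum(wl, a, b)
  expect_equal(ds@peakWavelength, 700)
  expect_equal(ds@troughWavelength, 755)
  # band overlap at 55 nm separation perturbs the ratio by ~0.2%
  expect_equal(ds@changeRatio, 2.0, tolerance = 5e-3)
  # sign flip swaps peak and trough and inverts the ratio
  ds2 <- differenceSpectrum(wl, b, a)
  expect_equal(ds2@peakWavelength, 755)
  expect_equal(ds2@troughWavelength, 700)
  expect_equal(ds2@changeRatio, 0.5, tolerance = 5e-3)
  expect_equal(ds2@changeRatio, 1 / ds@changeRatio, tolerance = 1e-12)
  expect_error(differenceSpectrum(wl, a, a), "undefined")
  expect_error(differenceSpectrum(wl, a, b[-1]), "identical")
})
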