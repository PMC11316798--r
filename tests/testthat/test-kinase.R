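test_that("saturation model obeys its boundary identities", {
  expect_equal(saturationModel(100, 0.1, 5, 0), 5)
  expect_equal(saturationModel(100, 0.1, 5, log(2) / 0.1), 55.0)
  # donor losing label: S(inf) = s0 + deltaS
  expect_equal(saturationModel(-40, 0.05, 50, 1e6), 10.0)
  expect_error(saturationModel(1, -0.1, 0, 1), "k must be")
})

test_that("global rate is recovered exactly from noiseless replicates", {
  traces <- makeKineticsTrace(generatorSpec(seed = 2))
  fit <- fitSaturation(traces)
  expect_equal(fit@k, traces[[1]]@truth$k, tolerance = 1e-6)
  expect_equal(fit@deltaS, rep(100, 3), tolerance = 1e-6)
  expect_equal(fit@s0, rep(5, 3), tolerance = 1e-6)
})

test_that("global rate survives 3% multiplicative noise within 5%", {
  traces <- makeKineticsTrace(generatorSpec(
    seed = 4, noise = list(type = "multiplicative", frac = 0.03)))
  fit <- fitSaturation(traces)
  truth <- traces[[1]]@truth
  expect_lt(abs(fit@k - truth$k) / truth$k, 0.05)
  expect_gt(fit@kSE[1], 0)
})

test_that("the baseline constraint pins s0 to the t = 0 signal exactly", {
  traces <- makeKineticsTrace(generatorSpec(seed = 2, truth = list(s0 = 0)))
  fit <- fitSaturation(traces, constrainBaseline = TRUE)
  expect_identical(fit@s0, rep(0, 3))
  expect_true(fit@baselineConstrained)
  # shifted traces: constrained s0 equals each trace's measured first point
  traces2 <- makeKineticsTrace(generatorSpec(
    seed = 8, noise = list(type = "multiplicative", frac = 0.02)))
  fit2 <- fitSaturation(traces2, constrainBaseline = TRUE)
  expect_identical(fit2@s0,
                   vapply(traces2, function(tr) tr@signal[tr@times == 0][1],
                          numeric(1)))
})

test_that("constraining an already-consistent baseline barely moves k", {
  traces <- makeKineticsTrace(generatorSpec(seed = 2))  # noiseless
  k_free <- fitSaturation(traces)@k
  k_con <- fitSaturation(traces, constrainBaseline = TRUE)@k
  expect_lt(abs(k_con - k_free) / k_free, 1e-3)
})

test_that("rescaling time rescales the rate reciprocally", {
  traces <- makeKineticsTrace(generatorSpec(
    seed = 6, noise = list(type = "multiplicative", frac = 0.02)))
  fit1 <- fitSaturation(traces)
  a <- 60  # seconds -> minutes
  scaled <- lapply(traces, function(tr)
    KineticsTrace(tr@times / a, tr@signal, tr@replicateId))
  fit2 <- fitSaturation(scaled)
  expect_equal(fit2@k, fit1@k * a, tolerance = 1e-6)
})

test_that("paired donor/acceptor traces conserve and mirror the amplitude", {
  traces <- makeKineticsTrace(generatorSpec(
    seed = 10, noise = list(type = "multiplicative", frac = 0.02),
    truth = list(paired = TRUE, deltaS = 80, s0 = 10)))
  donors <- Filter(function(tr) tr@species == "donor", traces)
  acceptors <- Filter(function(tr) tr@species == "acceptor", traces)
  fd <- fitSaturation(donors)
  fa <- fitSaturation(acceptors)
  # donor amplitude is negative, acceptor positive, equal magnitude within
  # a few percent at 2% noise
  expect_true(all(fd@deltaS < 0))
  expect_true(all(fa@deltaS > 0))
  expect_equal(mean(abs(fd@deltaS)), mean(fa@deltaS), tolerance = 0.05)
})

test_that("two-component fits order the rates and warn when starved", {
  truth <- list(k = 2e-2, k2 = 1e-3, deltaS = 60, deltaS2 = 40, s0 = 5,
                replicates = 2L)
  traces <- makeKineticsTrace(generatorSpec(
    seed = 12, grid = list(start = 0, stop = 4000, count = 40),
    truth = truth))
  fit <- fitSaturation(traces, nComponents = 2)
  expect_gt(fit@k, fit@k2)
  expect_equal(fit@k, truth$k, tolerance = 1e-4)
  expect_equal(fit@k2, truth$k2, tolerance = 1e-4)
  short <- makeKineticsTrace(generatorSpec(
    seed = 12, grid = list(start = 0, stop = 4000, count = 6), truth = truth))
  expect_warning(fitSaturation(short, nComponents = 2),
                 "over-parameterized")
})

test_that("degenerate inputs are refused with clear signals", {
  flat <- KineticsTrace(c(0, 10, 20, 30), rep(7, 4))
  expect_error(fitSaturation(flat), "no information")
  no_zero <- KineticsTrace(c(5, 10, 20, 30), c(1, 2, 3, 4))
  expect_error(fitSaturation(no_zero, constrainBaseline = TRUE), "t = 0")
})
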