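test_that("generators are pure functions of their spec", {
  sp <- generatorSpec(seed = 7, noise = list(type = "relpeak", frac = 0.005))
  expect_identical(makeChromatogram(sp)@absorbance,
                   makeChromatogram(sp)@absorbance)
  sp2 <- generatorSpec(seed = 9, noise = list(type = "gaussian", sd = 1e-3))
  expect_identical(makeReversionSeries(sp2)@absorbance,
                   makeReversionSeries(sp2)@absorbance)
  sp3 <- generatorSpec(seed = 2, noise = list(type = "multiplicative",
                                              frac = 0.03))
  expect_identical(lapply(makeKineticsTrace(sp3), function(x) x@signal),
                   lapply(makeKineticsTrace(sp3), function(x) x@signal))
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(makeChromatogram(sp)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noise-free output equals the model exactly and embeds truth", {
  ch <- makeChromatogram(generatorSpec(seed = 7))
  truth <- generatorTruth(ch)
  expect_identical(ch@absorbance, mixtureValue(truth$model, ch@volume))
  expect_equal(range(ch@volume), c(8, 24))
  s <- makeReversionSeries(generatorSpec(seed = 5))
  tr <- generatorTruth(s)
  expect_equal(s@absorbance[, 1],
               tr$amp1 + tr$amp2 + tr$abs0)   # t = 0 slice
  expect_equal(s@absorbance[3, ],
               reversionModel(tr$k1, tr$k2, tr$amp1[3], tr$amp2[3],
                              tr$abs0[3], s@times))
  kt <- makeKineticsTrace(generatorSpec(seed = 2))[[1]]
  expect_equal(kt@signal,
               saturationModel(kt@truth$deltaS, kt@truth$k, kt@truth$s0,
                               kt@times))
})

test_that("equilibrium series follows the isotherm by construction", {
  k2 <- 2e6
  # one chromatogram exactly at K2*C = 1: equal areas
  s1 <- makeEquilibriumSeries(k2 = k2, concentrations = 1 / k2,
                              template = generatorSpec(seed = 1))[[1]]
  truth <- generatorTruth(s1)
  expect_equal(truth$yFrac, 0.5)
  expect_equal(truth$model@tetramer@amp, truth$model@dimer@amp)
  # dilute limit: tetramer area fraction below 1%
  lo <- makeEquilibriumSeries(k2 = k2, concentrations = 1e-9,
                              template = generatorSpec(seed = 1))[[1]]
  expect_lt(generatorTruth(lo)$yFrac, 0.01)
  # total area proportional to concentration
  pairc <- makeEquilibriumSeries(k2 = k2, concentrations = c(1e-6, 2e-6),
                                 template = generatorSpec(seed = 1))
  area <- vapply(pairc, function(ch) {
    m <- generatorTruth(ch)$model; m@tetramer@amp + m@dimer@amp
  }, numeric(1))
  expect_equal(area[2] / area[1], 2)
})

test_that("paired phosphotransfer traces conserve total label", {
  traces <- makeKineticsTrace(generatorSpec(seed = 2,
                                            truth = list(paired = TRUE)))
  expect_length(traces, 6)
  donor <- traces[[1]]; acceptor <- traces[[2]]
  expect_equal(donor@signal + acceptor@signal,
               rep(donor@signal[1] + acceptor@signal[1],
                   length(donor@times)))
})

test_that("rotated-pair generator honors its stated transform", {
  pair0 <- makeRotatedPair(generatorSpec(seed = 1,
                                         truth = list(angle = 0,
                                                      ringFlip = 0)))
  expect_equal(pair0$stateA@atoms[, c("x", "y", "z")],
               pair0$stateB@atoms[, c("x", "y", "z")])
  expect_error(makeRotatedPair(generatorSpec(seed = 1,
                                             truth = list(angle = 200))),
               "0, 180")
  # fixed domain untouched, mobile domain moved
  pair <- makeRotatedPair(generatorSpec(seed = 1))
  fixed <- pair$stateA@atoms$resno <= 76 & pair$stateA@atoms$type == "ATOM"
  expect_equal(pair$stateA@atoms$x[fixed], pair$stateB@atoms$x[fixed])
  mobile <- pair$stateA@atoms$resno >= 101 & pair$stateA@atoms$type == "ATOM"
  expect_gt(max(abs(pair$stateA@atoms$x[mobile] -
                    pair$stateB@atoms$x[mobile])), 1)
})

test_that("a too-coarse grid is refused", {
  expect_error(makeChromatogram(generatorSpec(
    seed = 1, grid = list(count = 10))), "too coarse")
})
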