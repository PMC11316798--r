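test_that("minimal PDB and mmCIF fixtures parse identically", {
  p_pdb <- write_mini_pdb(tempfile(fileext = ".pdb"))
  p_cif <- write_mini_cif(tempfile(fileext = ".cif"))
  a <- readStructure(p_pdb)
  b <- readStructure(p_cif)
  expect_equal(nrow(a@atoms), 3)
  expect_equal(unique(a@atoms$chain), "A")
  expect_equal(a@atoms[, c("x", "y", "z")], b@atoms[, c("x", "y", "z")])
  expect_equal(a@atoms$elety, b@atoms$elety)
  expect_error(readStructure(tempfile()), "not found")
})

test_that("only highest-priority alternate locations are retained", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       0.500   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), p)
  s <- readStructure(p)
  expect_equal(nrow(s@atoms), 2)
  kept <- s@atoms[s@atoms$resno == 1, ]
  expect_equal(kept$x, 0)  # the altloc-A conformer, not B
})

test_that("Kabsch superposition recovers a constructed rotation", {
  set.seed(1)
  P <- matrix(rnorm(30, sd = 5), 10, 3)
  R30 <- rotmat_axis(30, c(0, 0, 1))
  Q <- P %*% t(R30) + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  sup <- superpose(P, Q)
  expect_lt(sup@rmsd, 1e-8)
  ra <- rotationAngle(sup@rotation)
  expect_equal(ra$angle, 30, tolerance = 1e-6 / 30)
  expect_equal(abs(ra$axis[3]), 1, tolerance = 1e-9)
  # identity case
  sup0 <- superpose(P, P)
  expect_equal(sup0@rotation, diag(3), tolerance = 1e-10)
  expect_lt(sup0@rmsd, 1e-12)
})

test_that("reflections are excluded: mirror images give det +1 and rmsd > 0", {
  set.seed(2)
  P <- matrix(rnorm(30, sd = 5), 10, 3)
  M <- P %*% diag(c(-1, 1, 1))
  sup <- superpose(P, M)
  expect_equal(det(sup@rotation), 1, tolerance = 1e-10)
  expect_gt(sup@rmsd, 0.1)
})

test_that("superposition rmsd beats a brute-force rotation search", {
  set.seed(3)
  P <- matrix(rnorm(30, sd = 5), 10, 3)
  Q <- P %*% t(rotmat_axis(73, c(1, 2, 3))) + 0.3 * matrix(rnorm(30), 10, 3)
  best <- superpose(P, Q)@rmsd
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  set.seed(4)
  brute <- vapply(1:1000, function(i) {
    ax <- rnorm(3); ang <- runif(1, 0, 180)
    sqrt(mean(rowSums((Pc %*% t(rotmat_axis(ang, ax)) - Qc)^2)))
  }, numeric(1))
  expect_true(all(best <= brute + 1e-12))
})

test_that("degenerate superposition inputs are refused", {
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("rotation angle and axis follow their conventions", {
  r0 <- rotationAngle(diag(3))
  expect_equal(r0$angle, 0)
  r180 <- rotationAngle(diag(c(-1, -1, 1)))
  expect_equal(r180$angle, 180)
  expect_equal(r180$axis, c(0, 0, 1))
  # composition about a common axis adds angles (quaternion oracle)
  ax <- c(1, 1, 2) / sqrt(6)
  R <- rotmat_axis(25, ax) %*% rotmat_axis(20, ax)
  q <- quat_mult(quat_from_axis(25, ax), quat_from_axis(20, ax))
  expect_equal(rotationAngle(R)$angle, 45, tolerance = 1e-9)
  expect_equal(rotationAngle(R)$angle, quat_angle_deg(q), tolerance = 1e-9)
  expect_error(rotationAngle(matrix(1:9 / 10, 3, 3)), "rotation matrix")
})

test_that("domain rotation recovers the generator's hinge angle", {
  pair <- makeRotatedPair(generatorSpec(seed = 1))
  dr <- domainRotation(pair$stateA, pair$stateB, pair$fixedSel,
                       pair$mobileSel)
  expect_equal(dr$angle, pair$truth$angle, tolerance = 0.1 / 35)
  expect_equal(dr$nMeasure, 76L)
  # same state on both sides: no rotation
  dr0 <- domainRotation(pair$stateA, pair$stateA, pair$fixedSel,
                        pair$mobileSel)
  expect_lt(dr0$angle, 1e-6)
  bad <- Selection(chain = "Z", residueRange = c(1, 10))
  expect_error(domainRotation(pair$stateA, pair$stateB, bad, pair$mobileSel),
               "no common atoms")
})

test_that("ring plane flips are measured against oriented normals", {
  pair0 <- makeRotatedPair(generatorSpec(seed = 1,
                                         truth = list(ringFlip = 0,
                                                      angle = 0)))
  expect_lt(planeFlipAngle(pair0$stateA, pair0$stateB, pair0$ringSel,
                           pair0$fixedSel), 1e-6)
  pair90 <- makeRotatedPair(generatorSpec(seed = 1,
                                          truth = list(ringFlip = 90)))
  expect_equal(planeFlipAngle(pair90$stateA, pair90$stateB, pair90$ringSel,
                              pair90$fixedSel), 90, tolerance = 1e-6)
  # a genuine flip exceeds 90 degrees
  pair161 <- makeRotatedPair(generatorSpec(seed = 1,
                                           truth = list(ringFlip = 161)))
  expect_equal(planeFlipAngle(pair161$stateA, pair161$stateB,
                              pair161$ringSel, pair161$fixedSel),
               161, tolerance = 0.2 / 161)
})

test_that("pair distances resolve atom specs in both syntaxes", {
  at <- data.frame(chain = "A", resno = 1:3, resid = "GLY",
                   elety = "CA", x = c(0, 3, 1), y = c(0, 4, 1),
                   z = c(0, 0, 1), stringsAsFactors = FALSE)
  s <- StructureModel(at, id = "fixture")
  expect_equal(pairDistance(s, "A:1:CA", "A:2:CA"), 5.0)
  expect_equal(pairDistance(s, "A:1:CA", "A:1:CA"), 0)
  expect_equal(pairDistance(s, list(chain = "A", resno = 1, elety = "CA"),
                            "A:2:CA"), 5.0)
  expect_error(pairDistance(s, "A:1:CA", "B:9:CA"), "atom not found: B:9:CA")
})

test_that("helix scissor angles match constructed geometries", {
  mk <- function(axisB, seed = 6) {
    h1 <- bphptools:::ideal_helix(20, start = c(0, 0, 0), axis = c(0, 0, 1))
    h2 <- bphptools:::ideal_helix(20, start = c(10, 0, 0), axis = axisB)
    at <- data.frame(chain = "A", resno = 1:40, resid = "ALA", elety = "CA",
                     x = c(h1[, 1], h2[, 1]), y = c(h1[, 2], h2[, 2]),
                     z = c(h1[, 3], h2[, 3]), stringsAsFactors = FALSE)
    StructureModel(at, id = "helices")
  }
  selA <- Selection(chain = "A", residueRange = c(1, 20))
  selB <- Selection(chain = "A", residueRange = c(21, 40))
  th <- 40 * pi / 180
  expect_lt(helixScissorAngle(mk(c(0, 0, 1)), selA, selB), 0.5)
  expect_equal(helixScissorAngle(mk(c(sin(th), 0, cos(th))), selA, selB), 40,
               tolerance = 1 / 40)
  expect_equal(helixScissorAngle(mk(c(1, 0, 0)), selA, selB), 90,
               tolerance = 1 / 90)
})

test_that("all metrics are invariant under a common rigid transform", {
  pair <- makeRotatedPair(generatorSpec(seed = 1))
  rigid <- random_rigid(17)
  a2 <- apply_rigid(pair$stateA, rigid)
  b2 <- apply_rigid(pair$stateB, rigid)
  dr1 <- domainRotation(pair$stateA, pair$stateB, pair$fixedSel,
                        pair$mobileSel)$angle
  dr2 <- domainRotation(a2, b2, pair$fixedSel, pair$mobileSel)$angle
  expect_equal(dr1, dr2, tolerance = 1e-6 / dr1)
  f1 <- planeFlipAngle(pair$stateA, pair$stateB, pair$ringSel, pair$fixedSel)
  f2 <- planeFlipAngle(a2, b2, pair$ringSel, pair$fixedSel)
  expect_equal(f1, f2, tolerance = 1e-6)
  expect_equal(pairDistance(pair$stateA, "A:1:CA", "A:110:CA"),
               pairDistance(a2, "A:1:CA", "A:110:CA"), tolerance = 1e-9)
})

test_that("comparison reports name every selection", {
  pair <- makeRotatedPair(generatorSpec(seed = 1))
  rep <- compareStructures(
    pair$stateA, pair$stateB, pair$fixedSel, pair$mobileSel,
    ringSel = pair$ringSel,
    distancePairs = list(list(a = "A:1:CA", b = "A:110:CA")),
    helixSels = list(Selection(chain = "A", residueRange = c(1, 38)),
                     Selection(chain = "A", residueRange = c(39, 76))))
  expect_true(all(nzchar(rep$selection)))
  expect_setequal(
    rep$name,
    c("domain_rotation", "ring_flip",
      "pair_distance_synthetic_state_a", "pair_distance_synthetic_state_b",
      "helix_scissor_synthetic_state_a", "helix_scissor_synthetic_state_b"))
  expect_equal(rep$value[rep$name == "domain_rotation"], 35, tolerance = 1e-3)
})
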