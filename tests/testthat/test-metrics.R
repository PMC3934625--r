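# Volumes whose support mask covers every voxel, for closed-form checks.
denseVolume <- function(values, d = c(3, 3, 3)) {
  imageVolume(array(values, d), c(1, 1, 1))
}

test_that("maximum geometric error matches hand-computed maxima", {
  a <- landmarkSet(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_identical(maxGeometricError(a, a), 0)
  shifted <- landmarkSet(landmarkPoints(a) +
                           matrix(c(3, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(maxGeometricError(a, shifted), 3)
  b <- landmarkSet(rbind(c(0, 0, 1), c(10, 4, 0)))
  expect_equal(maxGeometricError(a, b), 4)  # max(1, 4) by direct arithmetic
  expect_error(maxGeometricError(a, landmarkSet(matrix(0, 3, 3))),
               "cardinality")
  expect_error(maxGeometricError(a, landmarkSet(landmarkPoints(b),
                                                c("X1", "X2"))),
               "labels")
})

test_that("MGE is permutation-invariant and grows when a point moves away", {
  set.seed(5)
  pts <- matrix(rnorm(24, sd = 10), 8, 3)
  rec <- pts + matrix(rnorm(24, sd = 0.5), 8, 3)
  base <- maxGeometricError(landmarkSet(pts), landmarkSet(rec))
  for (i in 1:5) {
    perm <- sample(8)
    lab <- paste0("M", perm)
    expect_equal(maxGeometricError(landmarkSet(pts[perm, ], lab),
                                   landmarkSet(rec[perm, ], lab)), base)
  }
  worst <- which.max(sqrt(rowSums((pts - rec)^2)))
  sep <- (rec[worst, ] - pts[worst, ])
  rec2 <- rec; rec2[worst, ] <- rec[worst, ] + sep  # move further out
  expect_gt(maxGeometricError(landmarkSet(pts), landmarkSet(rec2)), base)
})

test_that("NMI attains its bounds at identity and independence", {
  p <- smallPhantomPair()$t1
  expect_equal(normalizedMutualInformation(p, p), 2, tolerance = 1e-12)
  set.seed(8)
  u1 <- denseVolume(runif(27000, 50, 150), c(30, 30, 30))
  u2 <- denseVolume(runif(27000, 50, 150), c(30, 30, 30))
  expect_equal(normalizedMutualInformation(u1, u2, bins = 8), 1,
               tolerance = 0.02)
  pairNmi <- normalizedMutualInformation(p, smallPhantomPair()$t2)
  expect_gte(pairNmi, 1); expect_lte(pairNmi, 2)
  flat <- denseVolume(rep(7, 27))
  expect_error(normalizedMutualInformation(flat, flat), "degenerate")
})

test_that("NRMS matches closed forms and a hand-computed grid", {
  f <- denseVolume(100 + 1:27)
  expect_identical(normalizedRMS(f, f), 0)
  g <- denseVolume(100 + 1:27 + 5)
  expect_equal(normalizedRMS(f, g), 5 / 26, tolerance = 1e-12)
  # hand-computed: diffs cycle (0, 1, -2) so mean square is 5/3, range 26
  d <- rep(c(0, 1, -2), 9)
  h <- denseVolume(100 + 1:27 + d)
  expect_equal(normalizedRMS(f, h), sqrt(5 / 3) / 26, tolerance = 1e-12)
  expect_error(normalizedRMS(denseVolume(rep(9, 27)), f), "constant")
})

test_that("edge overlap is 1 at identity, symmetric, and 0 for disjoint shells", {
  p <- smallPhantomPair()$t1
  expect_equal(edgeOverlap(p, p), 1)
  q <- smallPhantomPair()$t2
  expect_equal(edgeOverlap(p, q), edgeOverlap(q, p), tolerance = 1e-12)
  # thin-shell phantom shifted far beyond the dilation tolerance
  sphere <- function(cx) {
    d <- c(40, 40, 40)
    g <- expand.grid(1:40, 1:40, 1:40)
    r <- sqrt((g[[1]] - cx)^2 + (g[[2]] - 20)^2 + (g[[3]] - 20)^2)
    imageVolume(array(as.numeric(r >= 6 & r <= 8) * 100 + 10, d),
                c(1, 1, 1))
  }
  expect_lt(edgeOverlap(sphere(12), sphere(30)), 0.05)
})

test_that("metric evaluation follows the landmark protocol end to end", {
  pair <- smallPhantomPair()
  truth <- sampleMisalignment(6, 3, seed = 21, center = volumeCenter(pair$t1))
  # monomodal pair so the ideal case drives every metric to its optimum
  moving <- resampleVolume(pair$t1, truth, "linear")
  lmRef <- placeLandmarks(pair$t1, 10, seed = 2)
  lmMis <- transformLandmarks(lmRef, invertTransform(truth))
  cfg <- pipelineConfig("rigid", "RSGD", "linear")
  perfect <- new("RegistrationResult", transform = invertTransform(truth),
                 metricValue = 1, iterations = 1L, converged = TRUE,
                 diagnostics = list())
  rec <- evaluateRegistration(pair$t1, moving, perfect, lmRef, lmMis, cfg,
                              "toy")
  expect_lt(rec$mge_mm, 1e-9)
  expect_gt(rec$nmi, 1.4)
  expect_lt(rec$nrms, 0.15)
  expect_gt(rec$eo, 0.6)
  expect_true(rec$mge_mm >= 0 && rec$eo >= 0 && rec$eo <= 1 &&
                rec$nrms >= 0)
  # identity "registration" leaves the full 5 mm misalignment in place
  shift5 <- rigidTransform(translation = c(5, 0, 0))
  lmMis5 <- transformLandmarks(lmRef, invertTransform(shift5))
  idres <- new("RegistrationResult", transform = identityTransform(),
               metricValue = 0, iterations = 0L, converged = TRUE,
               diagnostics = list())
  rec5 <- evaluateRegistration(pair$t1, resampleVolume(pair$t2, shift5),
                               idres, lmRef, lmMis5, cfg, "toy5")
  expect_equal(rec5$mge_mm, 5, tolerance = 1e-9)
})

test_that("MGE and NRMS are co-monotone on residual pure translations", {
  p <- smallPhantomPair()$t1
  lm <- placeLandmarks(p, 10, seed = 4)
  mges <- nrmss <- numeric(0)
  for (t in c(1, 2, 4)) {
    tr <- rigidTransform(translation = c(t, 0, 0))
    mges <- c(mges, maxGeometricError(lm, transformLandmarks(lm, tr)))
    nrmss <- c(nrmss, normalizedRMS(p, resampleVolume(p, tr)))
  }
  expect_equal(mges, c(1, 2, 4), tolerance = 1e-12)
  expect_true(all(diff(mges) > 0))
  expect_true(all(diff(nrmss) >= 0))
})
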