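test_that("phantom generation is deterministic and geometry is shared across modalities", {
  a <- generatePhantom(c(32, 32, 32), c(2, 2, 2), "T1", seed = 11)
  b <- generatePhantom(c(32, 32, 32), c(2, 2, 2), "T1", seed = 11)
  expect_identical(voxels(a), voxels(b))

  pair <- smallPhantomPair(seed = 3)
  expect_identical(voxels(pair$t1) != 0, voxels(pair$t2) != 0)
  # modality-specific intensities: interiors differ even with shared geometry
  inside <- voxels(pair$t1) != 0
  expect_gt(mean(abs(voxels(pair$t1)[inside] - voxels(pair$t2)[inside])), 10)
  # non-monotonic intensity relation (rank correlation well below 1)
  expect_lt(cor(voxels(pair$t1)[inside], voxels(pair$t2)[inside],
                method = "spearman"), 0.5)

  other <- generatePhantom(c(32, 32, 32), c(2, 2, 2), "T1", seed = 12)
  expect_false(identical(voxels(a), voxels(other)))
})

test_that("phantom background is exactly zero before noise and arguments are validated", {
  p <- smallPhantomPair()$t1
  expect_true(all(voxels(p)[!supportMask(p)] == 0))
  expect_gt(sum(!supportMask(p)), 0)
  expect_error(generatePhantom(c(16, 32, 32)), "gridShape")
  expect_error(generatePhantom(c(32, 32, 32), spacing = c(0, 1, 1)),
               "spacing")
})

test_that("TPS jitter interpolates the drawn control displacements and respects the bound", {
  p <- smallPhantomPair()$t1
  field <- PetriReg:::tpsJitterField(p, maxDisplacement = 2, seed = 5)
  expect_true(all(abs(field$disp) <= 2))
  expect_true(all(sqrt(rowSums(field$disp^2)) <= 2 * sqrt(3)))
  # the TPS passes exactly through the control displacements
  atCtrl <- PetriReg:::cpp_tps_disp(field$ctrl, field$W, field$A, field$ctrl)
  expect_lt(max(abs(atCtrl - field$disp)), 1e-8)
})

test_that("TPS jitter degenerates to identity at zero displacement and varies with the seed", {
  p <- smallPhantomPair()$t1
  expect_identical(voxels(applyTPSJitter(p, 0, seed = 1)), voxels(p))
  w1 <- applyTPSJitter(p, 2, seed = 1)
  w2 <- applyTPSJitter(p, 2, seed = 2)
  expect_false(identical(voxels(w1), voxels(w2)))
  expect_identical(voxels(applyTPSJitter(p, 2, seed = 1)), voxels(w1))
  expect_error(applyTPSJitter(p, -1), "maxDisplacement")
})

test_that("misalignment draws stay in the protocol ranges and are proper rigid maps", {
  angs <- matrix(0, 0, 3); trans <- matrix(0, 0, 3)
  for (s in 1:1000) {
    tr <- sampleMisalignment(25, 5, seed = s)
    R <- tr@linear
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
    trans <- rbind(trans, tr@translation)
    # recover ZYX angles from the matrix
    ay <- -asin(R[3, 1])
    ax <- atan2(R[3, 2], R[3, 3]); az <- atan2(R[2, 1], R[1, 1])
    angs <- rbind(angs, c(ax, ay, az) * 180 / pi)
  }
  expect_true(all(trans >= 0 & trans <= 25))
  expect_true(all(abs(angs) <= 5 + 1e-9))
  ident <- sampleMisalignment(0, 0, seed = 1)
  expect_lt(max(abs(transformMatrix(ident) - diag(4))), 1e-12)
  expect_error(sampleMisalignment(-1, 5), "transMax")
})

test_that("resampling honours the pull convention and interpolator contracts", {
  p <- smallPhantomPair()$t1
  for (interp in c("linear", "bspline")) {
    out <- resampleVolume(p, identityTransform(), interp)
    expect_lt(max(abs(voxels(out) - voxels(p))), 1e-6)
  }
  # integer-voxel translation with NN: exact shifted copy in the overlap
  tr <- rigidTransform(translation = c(2, 0, 0))  # one voxel at 2 mm spacing
  out <- resampleVolume(p, tr, "NN")
  expect_identical(voxels(out)[1:31, , ], voxels(p)[2:32, , ])
  # round trip +t then -t with linear interpolation: small smoothing error
  fwd <- resampleVolume(p, rigidTransform(translation = c(1.1, 0.7, -0.4)))
  back <- resampleVolume(fwd, rigidTransform(translation = -c(1.1, 0.7, -0.4)))
  core <- 4:29
  err <- max(abs(voxels(back)[core, core, core] -
                 voxels(p)[core, core, core]))
  expect_lt(err / max(voxels(p)), 0.15)
  expect_error(resampleVolume(p, affineTransform(matrix(1e-20, 3, 3) + 0,
                                                 c(0, 0, 0))),
               "invertible|singular")
})

test_that("landmarks are placed inside the support with the required separation", {
  p <- smallPhantomPair()$t1
  lm <- placeLandmarks(p, 16, seed = 9)
  expect_equal(length(lm), 16)
  expect_identical(landmarkPoints(placeLandmarks(p, 16, seed = 9)),
                   landmarkPoints(lm))
  mask <- supportMask(p)
  idx <- round(sweep(landmarkPoints(lm), 2, voxelSpacing(p), "/")) + 1
  expect_true(all(mask[idx]))
  dmat <- as.matrix(dist(landmarkPoints(lm)))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 5 * min(voxelSpacing(p)))
})

test_that("landmark transport preserves order and inverts exactly", {
  lm <- landmarkSet(rbind(c(0, 0, 0), c(10, 5, 2), c(-3, 7, 1)))
  expect_identical(landmarkPoints(transformLandmarks(lm, identityTransform())),
                   landmarkPoints(lm))
  shifted <- transformLandmarks(landmarkSet(matrix(0, 1, 3)),
                                rigidTransform(translation = c(3, 4, 0)))
  expect_equal(as.numeric(landmarkPoints(shifted)), c(3, 4, 0))
  for (s in 1:25) {
    tr <- sampleMisalignment(25, 5, seed = s, center = c(10, -5, 3))
    round <- transformLandmarks(transformLandmarks(lm, tr),
                                invertTransform(tr))
    expect_lt(max(abs(landmarkPoints(round) - landmarkPoints(lm))), 1e-9)
  }
})

test_that("Rician noise realizes the magnitude-image law", {
  flat <- imageVolume(array(0, c(48, 48, 48)), c(1, 1, 1))
  noisy <- addRicianNoise(flat, sigma = 10, seed = 2)
  x <- as.numeric(voxels(noisy))          # 110592 Rayleigh samples
  expect_equal(mean(x), 10 * sqrt(pi / 2), tolerance = 0.01)
  expect_equal(mean(x^2), 2 * 10^2, tolerance = 0.02)
  bright <- imageVolume(array(1000, c(24, 24, 24)), c(1, 1, 1))
  hn <- addRicianNoise(bright, sigma = 10, seed = 3)  # nu/sigma = 100
  expect_equal(mean(voxels(hn)), 1000, tolerance = 0.01)
  expect_identical(voxels(addRicianNoise(flat, 10, seed = 2)),
                   voxels(noisy))
  expect_error(addRicianNoise(flat, 0), "sigma")
})

test_that("generated noise matches the Rician second moment across SNRs", {
  n <- 1e5
  for (p in list(c(sigma = 8, nu = 0), c(sigma = 5, nu = 5),
                 c(sigma = 4, nu = 40))) {
    x <- drawRician(n, p["sigma"], p["nu"], seed = 31)
    m2 <- p["nu"]^2 + 2 * p["sigma"]^2
    se <- sd(x^2) / sqrt(n)
    expect_lt(abs(mean(x^2) - m2), 3 * se)
  }
})

test_that("moment matching recovers Rician parameters within 5 percent", {
  cases <- list(c(sigma = 10, nu = 0), c(sigma = 5, nu = 5),
                c(sigma = 5, nu = 50))
  for (p in cases) {
    x <- drawRician(1e5, p["sigma"], p["nu"], seed = 77)
    est <- estimateRicianParams(x)
    expect_lt(abs(riceSigma(est) - p["sigma"]) / p["sigma"], 0.05)
    if (p["nu"] == 0) {
      expect_lte(riceNu(est), 0.1 * riceSigma(est))
    } else {
      expect_lt(abs(riceNu(est) - p["nu"]) / p["nu"], 0.05)
    }
  }
})

test_that("degenerate or invalid noise samples are rejected", {
  expect_error(estimateRicianParams(rep(5, 2000)), "degenerate")
  expect_error(estimateRicianParams(c(-1, runif(1999))), "non-negative")
  expect_error(estimateRicianParams(runif(100)), "1000")
})

test_that("background regions are disjoint, signal-free and reproducible", {
  p <- generatePhantom(c(48, 48, 48), c(2, 2, 2), "T1", seed = 4)
  s <- extractBackgroundRegions(p, nRegions = 4, regionSize = c(7, 7, 7),
                                seed = 13)
  expect_length(s, 4 * 7^3)
  expect_true(all(s == 0))                # noiseless phantom background
  corners <- attr(s, "corners")
  expect_equal(nrow(corners), 4)
  mask <- supportMask(p)
  centers <- corners + 3
  expect_false(any(mask[centers]))
  s2 <- extractBackgroundRegions(p, nRegions = 4, regionSize = c(7, 7, 7),
                                 seed = 13)
  expect_identical(attr(s2, "corners"), corners)
  noisy <- addRicianNoise(p, sigma = 12, seed = 1)
  sn <- extractBackgroundRegions(noisy, 4, c(7, 7, 7), seed = 13)
  est <- estimateRicianParams(sn)
  expect_equal(riceSigma(est), 12, tolerance = 0.1)
})
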