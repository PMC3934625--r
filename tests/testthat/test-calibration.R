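# A synthetic evaluation table whose MGEs follow a known additive model.
additiveRecords <- function(wTrue, datasetIds, noise = 0, seed = 1) {
  cfgs <- enumerateConfigs()
  rows <- withr::with_seed(seed, lapply(datasetIds, function(id) {
    do.call(rbind, lapply(cfgs, function(cfg) {
      ids <- PetriReg:::configTransitions(cfg)
      data.frame(dataset_id = id, transform = cfg@transformKind,
                 optimizer = cfg@optimizer, interp = cfg@interpolator,
                 mge_mm = sum(wTrue[ids]) + rnorm(1, 0, noise),
                 nmi = NA_real_, nrms = NA_real_, eo = NA_real_,
                 converged = TRUE, stringsAsFactors = FALSE)
    }))
  }))
  do.call(rbind, rows)
}

test_that("the design matrix has the documented binary structure", {
  A <- buildDesignMatrix(enumeratePaths(buildRegistrationNet()))
  expect_equal(dim(A), c(12L, 7L))
  expect_true(all(A %in% c(0, 1)))
  expect_equal(unname(rowSums(A)), rep(3, 12))
  expect_equal(unname(colSums(A)), c(6, 6, 6, 6, 4, 4, 4))
  expect_equal(qr(A)$rank, 5L)
  expect_error(buildDesignMatrix(rep(enumeratePaths(buildRegistrationNet())[1],
                                     2)), "duplicate")
})

test_that("pseudoinverse solves column-space systems exactly despite rank deficiency", {
  A <- buildDesignMatrix(enumeratePaths(buildRegistrationNet()))
  for (rep in 1:20) {
    wStar <- withr::with_seed(rep, rnorm(7))
    b <- as.numeric(A %*% wStar)
    x <- solveWeights(A, b)
    expect_lt(max(abs(A %*% x - b)), 1e-10)
  }
  expect_identical(unname(solveWeights(A, rep(0, 12))), rep(0, 7))
  I3 <- diag(3); colnames(I3) <- paste0("c", 1:3)
  expect_equal(unname(solveWeights(I3, c(4, -1, 2))), c(4, -1, 2),
               tolerance = 1e-12)
  expect_error(solveWeights(A, 1:5), "conform")
  # cross-check the pseudoinverse against an independent implementation
  expect_equal(pseudoinverse(A), pracma::pinv(A), tolerance = 1e-10)
})

test_that("fitted errors are invariant to null-space shifts of the weights", {
  A <- buildDesignMatrix(enumeratePaths(buildRegistrationNet()))
  w <- solveWeights(A, withr::with_seed(3, runif(12, 0, 5)))
  # shift the transform stage up and the optimizer stage down by c
  nullVec <- c(0.7, 0.7, -0.7, -0.7, 0, 0, 0)
  expect_lt(max(abs(A %*% nullVec)), 1e-12)
  expect_equal(as.numeric(A %*% (w + nullVec)), as.numeric(A %*% w),
               tolerance = 1e-12)
})

test_that("the error vector averages training MGEs in path order", {
  w <- namedWeights(c(1, 1.2, -0.5, 2, 0.3, 1.4, 0.2))
  rec1 <- additiveRecords(w, "d1")
  b1 <- averageErrorVector(rec1, "d1")
  expect_equal(unname(b1),
               vapply(enumerateConfigs(), function(cfg)
                 sum(w[PetriReg:::configTransitions(cfg)]), numeric(1)))
  rec2 <- additiveRecords(2 * w, "d2")
  both <- rbind(rec1, rec2)
  expect_equal(unname(averageErrorVector(both, c("d1", "d2"))),
               unname(1.5 * b1), tolerance = 1e-12)
  expect_equal(averageErrorVector(both, c("d2", "d1")),
               averageErrorVector(both, c("d1", "d2")))
  expect_error(averageErrorVector(rec1[-3, ], "d1"), "incomplete")
})

test_that("calibration on an additive model reproduces all path predictions", {
  w <- namedWeights(c(0.8, 1.0, -1.2, 3.1, 0.7, 1.4, 0.7))
  rec <- additiveRecords(w, c("d1", "d2", "d3"))
  calib <- calibratePipeline(rec)
  expect_lt(max(abs(fittedErrors(calib) - calib@errorVector)), 1e-10)
  expect_lt(residualNorm(calib), 1e-10)
  # weight differences within a stage are identified
  cw <- calibrationWeights(calib)
  expect_equal(cw[["t_nn"]] - cw[["t_linear"]],
               w[["t_nn"]] - w[["t_linear"]], tolerance = 1e-10)
  expect_equal(cw[["t_evo"]] - cw[["t_rsgd"]],
               w[["t_evo"]] - w[["t_rsgd"]], tolerance = 1e-10)
  net <- applyCalibration(buildRegistrationNet(), calib)
  cfg <- pipelineConfig("rigid", "EO", "NN")
  expect_equal(predictInaccuracy(net, cfg),
               sum(w[PetriReg:::configTransitions(cfg)]),
               tolerance = 1e-10)
})

test_that("predictive power equals the Pearson correlation of predictions and MGEs", {
  # weights chosen so three configs predict exactly 1, 2 and 3 mm
  w <- namedWeights(c(1, 2, 0, 1, 0, 0, 0))
  rec <- data.frame(
    dataset_id = "t", transform = c("rigid", "affine", "affine"),
    optimizer = c("RSGD", "RSGD", "EO"),
    interp = "linear", mge_mm = c(1.1, 1.9, 3.2),
    nmi = NA_real_, nrms = NA_real_, eo = NA_real_, converged = TRUE,
    stringsAsFactors = FALSE)
  expect_equal(predictivePower(w, rec), 0.990683605362842,
               tolerance = 1e-12)
  recPerfect <- rec; recPerfect$mge_mm <- c(1, 2, 3)
  expect_equal(predictivePower(w, recPerfect), 1, tolerance = 1e-12)
  recNeg <- rec; recNeg$mge_mm <- c(3, 2, 1)
  expect_equal(predictivePower(w, recNeg), -1, tolerance = 1e-12)
  recConst <- rec; recConst$mge_mm <- rep(2, 3)
  expect_error(predictivePower(namedWeights(rep(0, 7)), recConst),
               "constant")
  expect_error(predictivePower(w, rec[1:2, ]), "3 records")
})

test_that("metric correlation tracks co-monotone metrics and vanishes for noise", {
  w <- namedWeights(c(0.8, 1.0, -1.2, 3.1, 0.7, 1.4, 0.7))
  rec <- additiveRecords(w, paste0("d", 1:8), noise = 0.3, seed = 9)
  rec$nrms <- rec$mge_mm
  expect_equal(metricCorrelation(rec, "NRMS"), 1, tolerance = 1e-12)
  rec$nmi <- withr::with_seed(4, rnorm(nrow(rec)))
  expect_lt(abs(metricCorrelation(rec, "NMI")), 0.3)
})

test_that("robustness rho reproduces the hand-computed correlation of printed weights", {
  wTrain <- c(0.541, 0.435, -0.596, 1.559, 0.352, 0.774, 0.329)
  wTest <- c(0.770, 0.749, 0.210, 1.303, 0.698, 0.880, 0.690)
  expect_equal(robustnessRho(wTrain, wTest), 0.998983316785963,
               tolerance = 1e-12)
  expect_equal(robustnessRho(wTrain, wTrain), 1)
  expect_equal(robustnessRho(wTrain, -wTrain), -1)
  expect_error(robustnessRho(wTrain, wTest[1:5]), "equal length")
  expect_error(robustnessRho(rep(1, 7), wTest), "constant")
})

test_that("train/test splits are seeded, disjoint and exhaustive", {
  ids <- paste0("d", 1:10)
  sp <- splitTrainTest(ids, seed = 4)
  expect_length(sp$train, 5); expect_length(sp$test, 5)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(splitTrainTest(ids, seed = 4), sp)
  expect_false(identical(splitTrainTest(ids, seed = 5), sp))
  odd <- splitTrainTest(paste0("d", 1:7), seed = 1)
  expect_length(odd$train, 4); expect_length(odd$test, 3)
  expect_error(splitTrainTest("only", seed = 1), "at least 2")
})
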