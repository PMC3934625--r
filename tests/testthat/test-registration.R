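test_that("the configuration space enumerates the 12 functional-block combinations", {
  cfgs <- enumerateConfigs()
  expect_length(cfgs, 12)
  keys <- vapply(cfgs, PetriReg:::configKey, character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_identical(keys[1], "rigid/RSGD/NN")
  expect_true(all(vapply(cfgs, function(c) c@metric == "MI", logical(1))))
  expect_error(pipelineConfig("rigid", "simplex", "linear"), "optimizer")
})

test_that("structured-text configurations parse to the same objects as constructors", {
  cfg <- parsePipelineConfig(c("transform: affine", "optimizer: evo",
                               "interp: bspline"))
  expect_identical(PetriReg:::configKey(cfg), "affine/EO/bspline")
  one <- parsePipelineConfig("transform: rigid\noptimizer: rsgd\ninterp: nn")
  expect_identical(PetriReg:::configKey(one), "rigid/RSGD/NN")
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("transform: rigid", "optimizer: rsgd", "interp: linear"), f)
  expect_identical(PetriReg:::configKey(parsePipelineConfig(f)),
                   "rigid/RSGD/linear")
  expect_error(parsePipelineConfig("transform: sideways"), "transform")
  expect_error(parsePipelineConfig("nonsense"), "key")
})

test_that("mutual information behaves like an information measure", {
  p <- smallPhantomPair()$t1
  self <- mutualInformation(p, p)
  # self-MI approximates the marginal entropy of the binned intensities
  # (linear binning spreads mass over adjacent bins, so agreement is to
  # the smoothing tolerance, not exact)
  counts <- tabulate(cut(as.numeric(voxels(p)), 50, labels = FALSE), 50)
  hf <- -sum((counts / sum(counts))[counts > 0] *
               log((counts / sum(counts))[counts > 0]))
  expect_equal(self, hf, tolerance = 0.25)
  # an intensity-shuffled copy shares no spatial structure: MI near zero
  shuf <- imageVolume(array(withr::with_seed(1, sample(voxels(p))),
                            dim(voxels(p))), voxelSpacing(p))
  expect_lt(mutualInformation(p, shuf), 0.05 * self)
  # symmetry on a common grid under the identity
  q <- smallPhantomPair()$t2
  expect_equal(mutualInformation(p, q), mutualInformation(q, p),
               tolerance = 1e-10)
  expect_error(mutualInformation(p, q, bins = 4), "bins")
  far <- rigidTransform(translation = c(1000, 0, 0))
  expect_error(mutualInformation(p, q, far), "overlap")
})

test_that("regular-step gradient ascent solves a concave quadratic to the step tolerance", {
  target <- c(1, -2, 3)
  f <- function(p) -sum((p - target)^2)
  res <- optimizeRSGD(f, c(0, 0, 0), initStep = 2, minStep = 0.01,
                      maxIter = 200)
  expect_true(res$converged)
  expect_lt(sqrt(sum((res$par - target)^2)), 3 * 0.01)
  # already at the maximizer: no uphill direction, parameters unchanged
  at <- optimizeRSGD(f, target)
  expect_identical(at$par, target)
  # zero iterations returns the initial parameters
  none <- optimizeRSGD(f, c(5, 5, 5), maxIter = 0)
  expect_identical(none$par, c(5, 5, 5))
  expect_error(optimizeRSGD(function(p) NaN, c(0, 0)), "finite")
})

test_that("the (1+1) evolutionary optimizer is seeded and converges on the quadratic", {
  f <- function(p) -sum((p - c(0.5, -0.3, 0.2))^2)
  r1 <- optimizeOnePlusOne(f, c(0, 0, 0), maxIter = 500, seed = 11)
  expect_gt(r1$value, -1e-3)
  r2 <- optimizeOnePlusOne(f, c(0, 0, 0), maxIter = 500, seed = 11)
  expect_identical(r1$par, r2$par)
  r3 <- optimizeOnePlusOne(f, c(0, 0, 0), maxIter = 500, seed = 12)
  expect_false(identical(r1$par, r3$par))
  expect_error(optimizeOnePlusOne(f, c(0, 0, 0), shrink = 1.2), "shrink")
  expect_error(optimizeOnePlusOne(f, c(0, 0, 0), grow = 0.9), "grow")
})

test_that("optimizer effort is monotone: more iterations never lose the best value", {
  f <- function(p) -sum((p - c(1, 1, 1))^2) + 0.3 * sin(5 * sum(p))
  vals <- vapply(c(50, 200, 500), function(it)
    optimizeOnePlusOne(f, c(-2, 2, 0), maxIter = it, seed = 3)$value,
    numeric(1))
  expect_true(all(diff(vals) >= 0))
  valsR <- vapply(c(10, 50, 150), function(it)
    optimizeRSGD(f, c(-2, 2, 0), maxIter = it)$value, numeric(1))
  expect_true(all(diff(valsR) >= 0))
})

test_that("self-registration recovers the identity to subvoxel precision", {
  p <- smallPhantomPair()$t1
  res <- registerVolumes(p, p, pipelineConfig("rigid", "RSGD", "linear"),
                         seed = 1)
  est <- estimatedTransform(res)
  expect_identical(transformKind(est), "rigid")
  expect_lt(max(abs(est@translation)), 0.1)
  ang <- acos(pmin(1, (sum(diag(est@linear)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.1)
})

test_that("a known rigid misalignment of a multimodal pair is recovered", {
  pair <- smallPhantomPair()
  truth <- sampleMisalignment(6, 3, seed = 17, center = volumeCenter(pair$t1))
  moving <- resampleVolume(pair$t2, truth, "linear")
  lm <- placeLandmarks(pair$t1, 10, seed = 5)
  lmMis <- transformLandmarks(lm, invertTransform(truth))
  before <- maxGeometricError(lm, lmMis)
  res <- registerVolumes(pair$t1, moving,
                         pipelineConfig("rigid", "RSGD", "linear"), seed = 1)
  rec <- transformLandmarks(lmMis, invertTransform(estimatedTransform(res)))
  after <- maxGeometricError(lm, rec)
  expect_lt(after, before)
  expect_lt(after, 2)           # subvoxel at 2 mm spacing
  # a rigid-config result always carries an orthonormal linear part
  expect_lt(max(abs(crossprod(estimatedTransform(res)@linear) - diag(3))),
            1e-9)
})

test_that("registration failure is reported, not thrown", {
  pair <- smallPhantomPair()
  away <- resampleVolume(pair$t2, rigidTransform(translation = c(500, 0, 0)))
  res <- registerVolumes(pair$t1, away,
                         pipelineConfig("rigid", "RSGD", "linear"), seed = 1)
  expect_s4_class(res, "RegistrationResult")
  # the moving volume is empty in the overlap: either flagged or degenerate
  expect_true(is(res@converged, "logical"))
})
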