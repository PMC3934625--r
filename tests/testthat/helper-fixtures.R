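# Shared fixtures. Everything is generated in code; the expensive phantom
# study used by the acceptance checks is built once per session and cached.

.fixtureCache <- new.env(parent = emptyenv())

# Small phantom pair for module-level tests (cheap: 32^3).
smallPhantomPair <- function(seed = 3) {
  key <- paste0("pair", seed)
  if (is.null(.fixtureCache[[key]])) {
    .fixtureCache[[key]] <- list(
      t1 = generatePhantom(c(32, 32, 32), c(2, 2, 2), "T1", seed = seed),
      t2 = generatePhantom(c(32, 32, 32), c(2, 2, 2), "T2", seed = seed))
  }
  .fixtureCache[[key]]
}

# Study conditions for the end-to-end checks: 6 phantom datasets (64^3,
# 2 mm isotropic), TPS jitter of 2 mm, rigid misalignments drawn from the
# protocol ranges scaled to the phantom extent (<= 10 mm translation per
# axis, +-5 deg), 16 landmarks, and Rician noise of sigma = 8 intensity
# units (white-matter SNR ~ 25) — simulated volumes carry noise matched to
# real acquisitions, as the study protocol prescribes.
acceptanceDatasets <- function() {
  if (is.null(.fixtureCache$datasets)) {
    .fixtureCache$datasets <- lapply(1:6, function(k)
      simulateDataset(seed = k, gridShape = c(64, 64, 64),
                      spacing = c(2, 2, 2), transMax = 10, rotMax = 5,
                      tpsMax = 2, noiseSigma = 8, nLandmarks = 16))
  }
  .fixtureCache$datasets
}

# Full 12-configuration evaluation of the 6 datasets (72 registrations);
# computed once and reused by several acceptance checks.
acceptanceRecords <- function() {
  if (is.null(.fixtureCache$records)) {
    .fixtureCache$records <- evaluateDatasets(acceptanceDatasets(), seed = 1)
  }
  .fixtureCache$records
}

# Noiseless 64^3 pairs for the subvoxel ground-truth-recovery check, which
# is specified on noiseless volumes.
noiselessRecoveryMGEs <- function() {
  if (is.null(.fixtureCache$recoveryMGEs)) {
    cfg <- pipelineConfig("rigid", "RSGD", "linear")
    .fixtureCache$recoveryMGEs <- vapply(1:6, function(k) {
      ds <- simulateDataset(seed = k, gridShape = c(64, 64, 64),
                            spacing = c(2, 2, 2), transMax = 10,
                            rotMax = 5, tpsMax = 2, noiseSigma = 0)
      res <- registerVolumes(ds$fixed, ds$moving, cfg, seed = k)
      rec <- transformLandmarks(ds$landmarksMis,
                                invertTransform(estimatedTransform(res)))
      maxGeometricError(ds$landmarksRef, rec)
    }, numeric(1))
  }
  .fixtureCache$recoveryMGEs
}

# Draw Rician samples directly from the defining complex-Gaussian model --
# an oracle independent of addRicianNoise().
drawRician <- function(n, sigma, nu, seed) {
  withr::with_seed(seed,
    sqrt((nu + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2))
}

# Weights keyed like the calibrated net, from a plain numeric vector in
# column order (rigid, affine, RSGD, EO, linear, NN, bspline).
namedWeights <- function(w) {
  stats::setNames(w, c("t_rigid", "t_affine", "t_rsgd", "t_evo",
                       "t_linear", "t_nn", "t_bspline"))
}
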