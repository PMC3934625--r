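#' Simulate one registration dataset in memory
#'
#' Emulates the full study protocol for one subject: a T1 phantom (the
#' fixed image) and a T2 phantom sharing its geometry are jittered by the
#' same random thin-plate-spline deformation (a surrogate subject), the T2
#' volume is then misaligned by a random rigid transform, landmarks are
#' placed on the fixed image and projected onto the misaligned volume.
#'
#' The ground-truth transform \code{truth} is the resampling map used to
#' create the moving volume, and the misaligned landmarks are the
#' reference landmarks mapped through its inverse. A perfect registration
#' estimate therefore equals \code{invertTransform(truth)}, and
#' transporting the misaligned landmarks through the inverse of the
#' estimate — as [evaluateRegistration()] does — reproduces the reference
#' markers.
#'
#' @param seed integer; drives phantom texture, jitter, misalignment and
#'   landmark placement for this dataset.
#' @param gridShape,spacing phantom geometry (see [generatePhantom()]).
#' @param transMax,rotMax misalignment bounds (see
#'   [sampleMisalignment()]).
#' @param tpsMax thin-plate-spline jitter bound in mm (see
#'   [applyTPSJitter()]); 0 disables the jitter.
#' @param noiseSigma Rician noise level; 0 keeps the volumes noiseless.
#' @param nLandmarks markers per dataset.
#' @return list with \code{fixed}, \code{moving}, \code{landmarksRef},
#'   \code{landmarksMis}, \code{truth}, \code{id}.
#' @export
simulateDataset <- function(seed = 1, gridShape = c(64, 64, 64),
                            spacing = c(2, 2, 2), transMax = 25, rotMax = 5,
                            tpsMax = 2, noiseSigma = 0, nLandmarks = 16) {
  seed <- as.integer(seed)
  t1 <- generatePhantom(gridShape, spacing, "T1", seed = seed)
  t2 <- generatePhantom(gridShape, spacing, "T2", seed = seed)
  if (tpsMax > 0) {
    t1 <- applyTPSJitter(t1, tpsMax, seed = seed + 101L)
    t2 <- applyTPSJitter(t2, tpsMax, seed = seed + 101L)
  }
  truth <- sampleMisalignment(transMax, rotMax, seed = seed + 202L,
                              center = volumeCenter(t2))
  moving <- resampleVolume(t2, truth, "linear")
  landmarksRef <- placeLandmarks(t1, n = nLandmarks, seed = seed + 303L)
  landmarksMis <- transformLandmarks(landmarksRef, invertTransform(truth))
  if (noiseSigma > 0) {
    t1 <- addRicianNoise(t1, noiseSigma, seed = seed + 404L)
    moving <- addRicianNoise(moving, noiseSigma, seed = seed + 505L)
  }
  list(fixed = t1, moving = moving, landmarksRef = landmarksRef,
       landmarksMis = landmarksMis, truth = truth,
       id = sprintf("sim%03d", seed))
}

#' Simulate a study of datasets on disk
#'
#' Writes \code{count} dataset subdirectories under \code{outDir}, each
#' with \code{fixed.nii.gz}, \code{moving.nii.gz},
#' \code{landmarks_ref.csv}, \code{landmarks_mis.csv} and
#' \code{truth_transform.json}, plus a run manifest
#' (\code{manifest.json}) listing every file, seed and setting so the run
#' can be reproduced bit-for-bit. Real NIfTI volume pairs in the same
#' layout drop in unchanged.
#'
#' @param outDir output directory (created if needed).
#' @param count number of datasets.
#' @param seed integer base seed; dataset k uses \code{seed + k - 1}.
#' @param ... further arguments to [simulateDataset()].
#' @return the manifest, invisibly.
#' @export
simulateDatasets <- function(outDir, count = 10, seed = 1, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  settings <- list(...)
  entries <- list()
  for (k in seq_len(count)) {
    ds <- simulateDataset(seed = as.integer(seed) + k - 1L, ...)
    dsDir <- file.path(outDir, ds$id)
    dir.create(dsDir, showWarnings = FALSE)
    files <- c(fixed = file.path(dsDir, "fixed.nii.gz"),
               moving = file.path(dsDir, "moving.nii.gz"),
               landmarks_ref = file.path(dsDir, "landmarks_ref.csv"),
               landmarks_mis = file.path(dsDir, "landmarks_mis.csv"),
               truth = file.path(dsDir, "truth_transform.json"))
    writeVolume(ds$fixed, files[["fixed"]])
    writeVolume(ds$moving, files[["moving"]])
    writeLandmarks(ds$landmarksRef, files[["landmarks_ref"]])
    writeLandmarks(ds$landmarksMis, files[["landmarks_mis"]])
    writeTransform(ds$truth, files[["truth"]])
    entries[[ds$id]] <- list(seed = as.integer(seed) + k - 1L,
                             files = as.list(files))
  }
  manifest <- list(version = as.character(utils::packageVersion("PetriReg")),
                   baseSeed = as.integer(seed), count = count,
                   settings = settings, datasets = entries)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read one dataset directory
#'
#' @param dsDir directory holding the committed dataset layout
#'   (\code{fixed.nii.gz}, \code{moving.nii.gz}, landmark CSVs and,
#'   optionally, \code{truth_transform.json}).
#' @return a dataset list as from [simulateDataset()].
#' @export
readDataset <- function(dsDir) {
  truthPath <- file.path(dsDir, "truth_transform.json")
  list(fixed = readVolume(file.path(dsDir, "fixed.nii.gz"), "T1"),
       moving = readVolume(file.path(dsDir, "moving.nii.gz"), "T2"),
       landmarksRef = readLandmarks(file.path(dsDir, "landmarks_ref.csv")),
       landmarksMis = readLandmarks(file.path(dsDir, "landmarks_mis.csv")),
       truth = if (file.exists(truthPath)) readTransform(truthPath),
       id = basename(dsDir))
}

#' Evaluate every pipeline configuration on a set of datasets
#'
#' Runs each configuration on each dataset and measures the four criteria,
#' producing one evaluation record per (dataset, configuration). A
#' registration failure is recorded as a row flagged
#' \code{converged = FALSE} rather than aborting the run.
#'
#' @param datasets list of dataset lists (from [simulateDataset()] or
#'   [readDataset()]).
#' @param configs configurations to run; all 12 by default.
#' @param seed integer; per-run seeds are derived from it.
#' @param control registration settings from [registrationControl()].
#' @param verbose print one line per run.
#' @return data.frame with \code{12 * length(datasets)} rows (for the full
#'   configuration set).
#' @export
evaluateDatasets <- function(datasets, configs = enumerateConfigs(),
                             seed = 1, control = registrationControl(),
                             verbose = FALSE) {
  rows <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    for (ci in seq_along(configs)) {
      cfg <- configs[[ci]]
      runSeed <- as.integer(seed) + 1000L * di + ci
      rec <- tryCatch({
        res <- registerVolumes(ds$fixed, ds$moving, cfg, seed = runSeed,
                               control = control)
        evaluateRegistration(ds$fixed, ds$moving, res, ds$landmarksRef,
                             ds$landmarksMis, cfg, ds$id)
      }, error = function(e) {
        data.frame(dataset_id = ds$id, transform = cfg@transformKind,
                   optimizer = cfg@optimizer, interp = cfg@interpolator,
                   mge_mm = NA_real_, nmi = NA_real_, nrms = NA_real_,
                   eo = NA_real_, converged = FALSE,
                   stringsAsFactors = FALSE)
      })
      if (verbose)
        message(sprintf("%s %-22s MGE = %.3f mm", ds$id, configKey(cfg),
                        rec$mge_mm))
      rows[[length(rows) + 1L]] <- rec
    }
  }
  do.call(rbind, rows)
}

#' Calibrate, predict and report on a split study
#'
#' The full analysis protocol on an evaluation table: datasets are split
#' half/half into training and testing, the net is calibrated on the
#' training half, predictive power P is computed per test dataset (across
#' its 12 configurations) with the median reported, the intensity-metric
#' correlations C are computed over the test records, and robustness rho
#' is the correlation between the training-half and testing-half weight
#' vectors.
#'
#' @param records data.frame of evaluation records.
#' @param splitSeed integer seed for the dataset split.
#' @return list with \code{split}, \code{calibration} (training half),
#'   \code{calibrationTest} (testing half), \code{weights},
#'   \code{perDatasetP}, \code{medianP}, \code{metricCorrelations},
#'   \code{rho}, and \code{predictedVsMeasured} (12 predicted/measured
#'   pairs on the test mean errors).
#' @export
calibrateAndReport <- function(records, splitSeed = 1) {
  split <- splitTrainTest(unique(records$dataset_id), seed = splitSeed)
  calib <- calibratePipeline(records, split$train)
  calibTest <- calibratePipeline(records, split$test)
  w <- calib@weights
  perP <- vapply(split$test, function(id) {
    predictivePower(w, records[records$dataset_id == id, ])
  }, numeric(1))
  testRec <- records[records$dataset_id %in% split$test, ]
  mc <- vapply(c("NMI", "NRMS", "EO"), function(k)
    metricCorrelation(testRec, k), numeric(1))
  bTest <- averageErrorVector(records, split$test)
  pvm <- data.frame(config = rownames(calib@design),
                    predicted_mm = as.numeric(calib@design %*% w),
                    measured_mm = unname(bTest))
  list(split = split, calibration = calib, calibrationTest = calibTest,
       weights = w, perDatasetP = perP,
       medianP = stats::median(perP),
       metricCorrelations = mc,
       rho = robustnessRho(calib@weights, calibTest@weights),
       predictedVsMeasured = pvm)
}
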