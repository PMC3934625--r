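#' Moore-Penrose pseudoinverse
#'
#' Computed from the singular value decomposition with a relative
#' singular-value cutoff of 1e-12, so rank-deficient systems (like the
#' 12 x 7 registration design matrix, rank 5) are handled without failure
#' and the product with a right-hand side gives the minimum-Euclidean-norm
#' least-squares solution.
#'
#' @param A numeric matrix.
#' @param tol relative singular-value cutoff.
#' @return the pseudoinverse of \code{A}.
#' @export
pseudoinverse <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Build the binary path-by-transition design matrix
#'
#' Row i carries a 1 exactly in the columns of the weighted transitions on
#' path i; for the registration net this is the binary 12 x 7 system
#' matrix with row sums 3 (one selection per stage) and rank 5 (each
#' stage's indicator columns sum to the all-ones vector, losing one degree
#' of freedom per extra stage).
#'
#' @param paths list of [PetriPath-class] from [enumeratePaths()].
#' @return binary matrix with path keys as row names and transition ids as
#'   column names.
#' @export
buildDesignMatrix <- function(paths) {
  cols <- weightedTransitionIds()
  keys <- vapply(paths, function(p) configKey(p@config), character(1))
  if (anyDuplicated(keys))
    stop("duplicate paths in design", call. = FALSE)
  A <- matrix(0, length(paths), length(cols),
              dimnames = list(keys, cols))
  for (i in seq_along(paths)) {
    ids <- intersect(paths[[i]]@transitions, cols)
    A[i, ids] <- 1
  }
  A
}

#' Average measured MGEs into the calibration error vector
#'
#' Element j is the arithmetic mean, over the training datasets, of the
#' MGE measured for path j; element order matches the path enumeration.
#' Every training dataset must contribute all 12 configurations.
#'
#' @param records data.frame of evaluation records (one row per dataset
#'   and configuration, as produced by [evaluateRegistration()] /
#'   [evaluateDatasets()]).
#' @param trainingIds dataset ids to average over.
#' @param aggregate \code{"mean"} (default) or \code{"median"}.
#' @return named numeric 12-vector of mm errors.
#' @export
averageErrorVector <- function(records, trainingIds,
                               aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  keys <- vapply(enumerateConfigs(), configKey, character(1))
  recKey <- paste(records$transform, records$optimizer, records$interp,
                  sep = "/")
  b <- vapply(keys, function(k) {
    vals <- vapply(trainingIds, function(id) {
      hit <- which(records$dataset_id == id & recKey == k)
      if (length(hit) != 1L)
        stop("incomplete evaluation table: dataset ", id,
             " is missing configuration ", k, call. = FALSE)
      records$mge_mm[hit]
    }, numeric(1))
    if (aggregate == "mean") mean(vals) else stats::median(vals)
  }, numeric(1))
  b
}

#' Solve the inverse shortest path system for the transition weights
#'
#' The calibration step: given the binary design \eqn{A} (paths by
#' transitions) and the measured per-path error vector \eqn{b}, returns
#' \eqn{x = A^+ b}, the minimum-norm least-squares solution. Because each
#' stage's columns sum to the all-ones vector, per-stage constant shifts
#' summing to zero lie in the null space: individual weights are only
#' identified up to such shifts (which is why calibrated weights can be
#' negative), but every path sum — every prediction — is unique.
#'
#' @param design binary matrix from [buildDesignMatrix()].
#' @param errorVector numeric vector of per-path mm errors.
#' @return named numeric weight vector (mm).
#' @export
solveWeights <- function(design, errorVector) {
  if (nrow(design) != length(errorVector))
    stop("design and errorVector shapes do not conform", call. = FALSE)
  w <- as.numeric(pseudoinverse(design) %*% errorVector)
  names(w) <- colnames(design)
  w
}

predictionsForRecords <- function(weights, records) {
  keyParts <- cbind(
    ifelse(records$transform == "rigid", "t_rigid", "t_affine"),
    ifelse(records$optimizer == "RSGD", "t_rsgd", "t_evo"),
    c(linear = "t_linear", NN = "t_nn",
      bspline = "t_bspline")[records$interp])
  apply(keyParts, 1, function(ids) sum(weights[ids]))
}

#' Predictive power of calibrated weights
#'
#' Pearson correlation between the predicted inaccuracy of each record
#' (sum of the calibrated weights along the record's path) and its
#' measured MGE.
#'
#' @param weights named weight vector from [solveWeights()].
#' @param records data.frame of evaluation records.
#' @return Pearson correlation in \[-1, 1\].
#' @export
predictivePower <- function(weights, records) {
  if (nrow(records) < 3)
    stop("at least 3 records are required", call. = FALSE)
  pred <- predictionsForRecords(weights, records)
  if (sd(pred) == 0 || sd(records$mge_mm) == 0)
    stop("constant predictions or MGEs: correlation undefined",
         call. = FALSE)
  cor(pred, records$mge_mm)
}

#' Correlation between an intensity-based metric and the MGE
#'
#' @param records data.frame of evaluation records.
#' @param metricKind \code{"NMI"}, \code{"NRMS"} or \code{"EO"}.
#' @return Pearson correlation in \[-1, 1\].
#' @export
metricCorrelation <- function(records, metricKind = c("NMI", "NRMS", "EO")) {
  metricKind <- match.arg(metricKind)
  col <- c(NMI = "nmi", NRMS = "nrms", EO = "eo")[[metricKind]]
  if (nrow(records) < 3)
    stop("at least 3 records are required", call. = FALSE)
  m <- records[[col]]
  if (sd(m) == 0 || sd(records$mge_mm) == 0)
    stop("constant metric or MGEs: correlation undefined", call. = FALSE)
  cor(m, records$mge_mm)
}

#' Robustness of calibration across training sets
#'
#' Pearson correlation between two weight vectors obtained from different
#' training volumes; values near 1 mean the calibration is insensitive to
#' the choice of training data.
#'
#' @param weightsA,weightsB numeric weight vectors of equal length >= 3.
#' @return Pearson correlation.
#' @export
robustnessRho <- function(weightsA, weightsB) {
  if (length(weightsA) != length(weightsB) || length(weightsA) < 3)
    stop("weight vectors must have equal length >= 3", call. = FALSE)
  if (sd(weightsA) == 0 || sd(weightsB) == 0)
    stop("constant weight vector: correlation undefined", call. = FALSE)
  cor(weightsA, weightsB)
}

#' Split dataset ids into training and testing halves
#'
#' Seeded random half/half partition; with an odd count the training half
#' receives the extra dataset. The parts are disjoint and exhaustive.
#'
#' @param datasetIds character vector of >= 2 ids.
#' @param seed integer.
#' @return list with \code{train} and \code{test}.
#' @export
splitTrainTest <- function(datasetIds, seed = 1) {
  ids <- unique(as.character(datasetIds))
  if (length(ids) < 2)
    stop("at least 2 datasets are required for a split", call. = FALSE)
  perm <- withr::with_seed(as.integer(seed), sample(ids))
  nTrain <- ceiling(length(ids) / 2)
  list(train = sort(perm[seq_len(nTrain)]),
       test = sort(perm[-seq_len(nTrain)]))
}

#' Calibrate the Petri net from an evaluation table
#'
#' Builds the design matrix from the enumerated paths, averages the
#' training MGEs into the error vector, solves the pseudoinverse system
#' and packages everything into a [CalibrationResult-class].
#'
#' @param records data.frame of evaluation records covering all 12
#'   configurations for every training dataset.
#' @param trainingIds dataset ids used for training; defaults to all.
#' @param aggregate passed to [averageErrorVector()].
#' @return a [CalibrationResult-class].
#' @export
calibratePipeline <- function(records, trainingIds = NULL,
                              aggregate = "mean") {
  if (is.null(trainingIds)) trainingIds <- unique(records$dataset_id)
  net <- buildRegistrationNet()
  A <- buildDesignMatrix(enumeratePaths(net))
  b <- averageErrorVector(records, trainingIds, aggregate)
  w <- solveWeights(A, b)
  fit <- as.numeric(A %*% w)
  new("CalibrationResult", design = A, weights = w,
      errorVector = unname(b), fitted = fit,
      residualNorm = sqrt(sum((fit - b)^2)),
      trainingIds = as.character(trainingIds))
}

#' Attach calibrated weights to a net
#'
#' @param net a [PetriNetModel-class].
#' @param calibration a [CalibrationResult-class].
#' @return the calibrated net.
#' @export
applyCalibration <- function(net, calibration) {
  netWeights(net) <- calibration@weights
  net
}

#' @rdname CalibrationResult-class
#' @export
setMethod("calibrationWeights", "CalibrationResult",
          function(object) object@weights)

#' @rdname CalibrationResult-class
#' @export
setMethod("fittedErrors", "CalibrationResult", function(object) object@fitted)

#' @rdname CalibrationResult-class
#' @export
setMethod("residualNorm", "CalibrationResult",
          function(object) object@residualNorm)

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: trained on %d dataset(s), residual %.4g mm\n",
              length(object@trainingIds), object@residualNorm))
  w <- data.frame(transition = names(object@weights),
                  weight_mm = round(unname(object@weights), 4))
  print(w, row.names = FALSE)
})
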