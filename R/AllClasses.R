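#' ImageVolume: a 3D scalar grid in physical space
#'
#' Holds a 3D voxel array together with its physical geometry (per-axis
#' voxel spacing and the position of the first voxel, both in mm) and an MR
#' modality tag. The grid is axis-aligned; voxel \code{(i,j,k)} (1-based)
#' sits at \code{origin + (i-1, j-1, k-1) * spacing}.
#'
#' @slot voxels 3D numeric array of intensities (arbitrary units).
#' @slot spacing numeric(3), voxel size in mm per axis; all > 0.
#' @slot origin numeric(3), physical position of voxel (1,1,1) in mm.
#' @slot modality character(1), one of \code{"T1"}, \code{"T2"}.
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric",
                 origin = "numeric", modality = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L || any(dim(object@voxels) < 1L))
      msg <- c(msg, "voxels must be a non-empty 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values (mm)")
    if (length(object@modality) != 1L ||
        !object@modality %in% c("T1", "T2"))
      msg <- c(msg, "modality must be \"T1\" or \"T2\"")
    if (any(!is.finite(object@voxels)))
      msg <- c(msg, "all intensities must be finite")
    if (length(msg)) msg else TRUE
  })

#' SpatialTransform: rigid or affine map in physical coordinates
#'
#' Represents the map \eqn{y = A (x - c) + c + t} with linear part \eqn{A},
#' translation \eqn{t} (mm) and rotation centre \eqn{c} (mm). For
#' \code{kind = "rigid"} the linear part is a proper rotation (orthonormal,
#' determinant +1).
#'
#' @slot kind character(1), \code{"rigid"} or \code{"affine"}.
#' @slot linear 3x3 numeric matrix (dimensionless).
#' @slot translation numeric(3) in mm.
#' @slot center numeric(3) in mm.
#' @exportClass SpatialTransform
setClass("SpatialTransform",
  representation(kind = "character", linear = "matrix",
                 translation = "numeric", center = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("rigid", "affine"))
      msg <- c(msg, "kind must be \"rigid\" or \"affine\"")
    if (!all(dim(object@linear) == c(3L, 3L)))
      msg <- c(msg, "linear must be a 3x3 matrix")
    if (length(object@translation) != 3L || length(object@center) != 3L)
      msg <- c(msg, "translation and center must be length-3")
    if (abs(det(object@linear)) < 1e-12)
      msg <- c(msg, "transform must be invertible")
    if (identical(object@kind, "rigid")) {
      orth <- max(abs(crossprod(object@linear) - diag(3)))
      if (orth > 1e-6 || abs(det(object@linear) - 1) > 1e-6)
        msg <- c(msg, "rigid linear part must be orthonormal with det +1")
    }
    if (length(msg)) msg else TRUE
  })

#' LandmarkSet: ordered labelled 3D marker points in mm
#'
#' Point order is significant: correspondence between two sets is by index,
#' and every transform preserves order and labels.
#'
#' @slot points n x 3 numeric matrix of physical positions (mm).
#' @slot labels character(n) marker identifiers aligned with the rows.
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  representation(points = "matrix", labels = "character"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@points) != 3L)
      msg <- c(msg, "points must have 3 columns (x, y, z in mm)")
    if (any(!is.finite(object@points)))
      msg <- c(msg, "all coordinates must be finite")
    if (length(object@labels) != nrow(object@points))
      msg <- c(msg, "labels must align with points")
    if (length(msg)) msg else TRUE
  })

#' RicianParams: parameters of the Rician magnitude-noise law
#'
#' @slot sigma numeric(1), standard deviation of the complex-domain
#'   Gaussian noise (intensity units), > 0.
#' @slot nu numeric(1), noise-free signal amplitude, >= 0.
#' @exportClass RicianParams
setClass("RicianParams",
  representation(sigma = "numeric", nu = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
        object@sigma <= 0)
      msg <- c(msg, "sigma must be a single positive value")
    if (length(object@nu) != 1L || !is.finite(object@nu) || object@nu < 0)
      msg <- c(msg, "nu must be a single non-negative value")
    if (length(msg)) msg else TRUE
  })

#' PipelineConfig: one registration pipeline configuration
#'
#' A choice of transform model, optimizer and interpolator; the similarity
#' metric is always mutual information (the only metric suited to the
#' multimodal T1/T2 setting), so it is a fixed constant rather than a
#' selectable field.
#'
#' @slot transformKind \code{"rigid"} or \code{"affine"}.
#' @slot optimizer \code{"RSGD"} (regular-step gradient descent) or
#'   \code{"EO"} ((1+1) evolutionary optimizer).
#' @slot interpolator \code{"NN"}, \code{"linear"} or \code{"bspline"}.
#' @slot metric always \code{"MI"}.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(transformKind = "character", optimizer = "character",
                 interpolator = "character", metric = "character"),
  prototype(metric = "MI"),
  validity = function(object) {
    msg <- character()
    if (!object@transformKind %in% c("rigid", "affine"))
      msg <- c(msg, "transformKind must be \"rigid\" or \"affine\"")
    if (!object@optimizer %in% c("RSGD", "EO"))
      msg <- c(msg, "optimizer must be \"RSGD\" or \"EO\"")
    if (!object@interpolator %in% c("NN", "linear", "bspline"))
      msg <- c(msg, "interpolator must be \"NN\", \"linear\" or \"bspline\"")
    if (!identical(object@metric, "MI"))
      msg <- c(msg, "metric is fixed to \"MI\"")
    if (length(msg)) msg else TRUE
  })

#' RegistrationResult: outcome of one registration run
#'
#' @slot transform the estimated [SpatialTransform-class] mapping fixed-image
#'   physical coordinates to moving-image coordinates (resampling
#'   convention).
#' @slot metricValue final mutual-information score (nats).
#' @slot iterations total optimizer iterations across resolution levels.
#' @slot converged logical(1).
#' @slot diagnostics list of per-level details.
#' @exportClass RegistrationResult
setClass("RegistrationResult",
  representation(transform = "SpatialTransform", metricValue = "numeric",
                 iterations = "integer", converged = "logical",
                 diagnostics = "list"),
  validity = function(object) {
    if (object@iterations < 0L) "iterations must be >= 0" else TRUE
  })

#' PetriNetModel: the registration workflow as a Petri net
#'
#' Places model processing states, transitions model method choices, and a
#' distinguished inaccuracy-counter place gathers a weight (in mm) from each
#' weighted transition as the token game proceeds. Weighted transitions are
#' partitioned into decision stages (transform, optimizer, interpolator);
#' the metric transition is stage-tagged \code{"metric"} and unweighted.
#'
#' @slot places character vector of place labels (includes the counter).
#' @slot counter character(1), label of the inaccuracy-counter place.
#' @slot transitions data.frame with columns \code{id}, \code{label},
#'   \code{stage}, \code{weighted}.
#' @slot arcs data.frame with columns \code{from}, \code{to},
#'   \code{cardinality}.
#' @slot weights named numeric, one mm-valued weight per weighted
#'   transition; \code{NA} until calibrated.
#' @exportClass PetriNetModel
setClass("PetriNetModel",
  representation(places = "character", counter = "character",
                 transitions = "data.frame", arcs = "data.frame",
                 weights = "numeric"),
  validity = function(object) {
    msg <- character()
    tr <- object@transitions
    if (length(intersect(object@places, tr$id)))
      msg <- c(msg, "places and transitions must be disjoint")
    if (length(object@counter) != 1L ||
        !object@counter %in% object@places)
      msg <- c(msg, "exactly one inaccuracy-counter place is required")
    wt <- tr$id[tr$weighted]
    if (!setequal(names(object@weights), wt))
      msg <- c(msg, "weights must be named by the weighted transitions")
    toCounter <- object@arcs$from[object@arcs$to == object@counter]
    if (!all(wt %in% toCounter))
      msg <- c(msg, "every weighted transition needs an arc to the counter")
    stages <- tr$stage[tr$weighted]
    if (any(!stages %in% c("transform", "optimizer", "interpolator")))
      msg <- c(msg, "weighted transitions must belong to a decision stage")
    if (length(msg)) msg else TRUE
  })

#' PetriPath: one source-to-sink path through the net
#'
#' Contains exactly one transition per decision stage and maps bijectively
#' to a [PipelineConfig-class].
#'
#' @slot transitions character vector of fired transition ids, in firing
#'   order.
#' @slot config the induced [PipelineConfig-class].
#' @exportClass PetriPath
setClass("PetriPath",
  representation(transitions = "character", config = "PipelineConfig"))

#' CalibrationResult: weights solved from measured errors
#'
#' @slot design binary paths-by-transitions design matrix (12 x 7 for the
#'   registration net).
#' @slot weights named numeric, mm-valued weight per weighted transition
#'   (minimum-norm least-squares representative).
#' @slot errorVector numeric, per-path mean measured MGE in mm (the
#'   right-hand side b).
#' @slot fitted numeric, design %*% weights.
#' @slot residualNorm numeric(1), Euclidean norm of fitted - errorVector.
#' @slot trainingIds character, dataset ids the weights were trained on.
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(design = "matrix", weights = "numeric",
                 errorVector = "numeric", fitted = "numeric",
                 residualNorm = "numeric", trainingIds = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@design) != length(object@errorVector))
      msg <- c(msg, "design rows must match errorVector length")
    if (ncol(object@design) != length(object@weights))
      msg <- c(msg, "design columns must match weights length")
    fit <- as.numeric(object@design %*% object@weights)
    if (max(abs(fit - object@fitted)) > 1e-8)
      msg <- c(msg, "fitted must equal design %*% weights")
    if (length(msg)) msg else TRUE
  })
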