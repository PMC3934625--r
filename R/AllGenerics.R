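#' @rdname ImageVolume-class
#' @param object,x an object.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname ImageVolume-class
#' @export
setGeneric("volumeOrigin", function(object) standardGeneric("volumeOrigin"))

#' @rdname ImageVolume-class
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))

#' @rdname SpatialTransform-class
#' @param object an object.
#' @export
setGeneric("transformKind", function(object) standardGeneric("transformKind"))

#' Apply a spatial transform to 3D points
#'
#' @param transform a [SpatialTransform-class].
#' @param points n x 3 numeric matrix of physical positions (mm), or an
#'   object holding them.
#' @return the mapped points, same shape as the input.
#' @export
setGeneric("applyTransform",
           function(transform, points) standardGeneric("applyTransform"))

#' @rdname LandmarkSet-class
#' @param object an object.
#' @export
setGeneric("landmarkPoints", function(object) standardGeneric("landmarkPoints"))

#' @rdname LandmarkSet-class
#' @export
setGeneric("landmarkLabels", function(object) standardGeneric("landmarkLabels"))

#' @rdname RicianParams-class
#' @param object an object.
#' @export
setGeneric("riceSigma", function(object) standardGeneric("riceSigma"))

#' @rdname RicianParams-class
#' @export
setGeneric("riceNu", function(object) standardGeneric("riceNu"))

#' @rdname PetriNetModel-class
#' @param object an object.
#' @export
setGeneric("netWeights", function(object) standardGeneric("netWeights"))

#' @rdname PetriNetModel-class
#' @param value named numeric replacement weights.
#' @export
setGeneric("netWeights<-",
           function(object, value) standardGeneric("netWeights<-"))

#' @rdname PetriNetModel-class
#' @export
setGeneric("transitionTable",
           function(object) standardGeneric("transitionTable"))

#' @rdname PetriPath-class
#' @param object an object.
#' @export
setGeneric("pathConfig", function(object) standardGeneric("pathConfig"))

#' @rdname PetriPath-class
#' @export
setGeneric("pathTransitions",
           function(object) standardGeneric("pathTransitions"))

#' @rdname CalibrationResult-class
#' @param object an object.
#' @export
setGeneric("calibrationWeights",
           function(object) standardGeneric("calibrationWeights"))

#' @rdname CalibrationResult-class
#' @export
setGeneric("fittedErrors", function(object) standardGeneric("fittedErrors"))

#' @rdname CalibrationResult-class
#' @export
setGeneric("residualNorm", function(object) standardGeneric("residualNorm"))

#' @rdname RegistrationResult-class
#' @param object an object.
#' @export
setGeneric("estimatedTransform",
           function(object) standardGeneric("estimatedTransform"))
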