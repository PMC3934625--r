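#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file (.nii or .nii.gz) into an [ImageVolume-class],
#' honouring voxel spacing and origin. Oblique (non-axis-aligned)
#' orientations are not modelled: spacing is taken from the header pixdim
#' and the origin from the stored transform's translation.
#'
#' @param path file path.
#' @param modality modality tag to attach (\code{"T1"} or \code{"T2"}).
#' @return an [ImageVolume-class].
#' @export
readVolume <- function(path, modality = "T1") {
  img <- RNifti::readNifti(path)
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(xf, "try-error")) {
    sp <- abs(as.numeric(RNifti::pixdim(img))[1:3])
    orig <- c(0, 0, 0)
  } else {
    sp <- sqrt(colSums(xf[1:3, 1:3]^2))
    orig <- as.numeric(xf[1:3, 4])
  }
  imageVolume(array(as.numeric(img), dim(img)[1:3]), sp, orig, modality)
}

#' Write a NIfTI volume
#'
#' @param volume an [ImageVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@voxels)
  xf <- diag(4)
  diag(xf)[1:3] <- volume@spacing
  xf[1:3, 4] <- volume@origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read landmarks from CSV
#'
#' Expects a header with columns \code{label,x_mm,y_mm,z_mm}.
#'
#' @param path CSV file path.
#' @return a [LandmarkSet-class].
#' @export
readLandmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns label,x_mm,y_mm,z_mm",
         call. = FALSE)
  landmarkSet(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), df$label)
}

#' Write landmarks to CSV
#'
#' @param landmarks a [LandmarkSet-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeLandmarks <- function(landmarks, path) {
  df <- data.frame(label = landmarks@labels, landmarks@points)
  names(df)[2:4] <- c("x_mm", "y_mm", "z_mm")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a transform as JSON
#'
#' Stores kind, the 3x3 linear part, translation and centre.
#'
#' @param transform a [SpatialTransform-class].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeTransform <- function(transform, path) {
  doc <- list(kind = transform@kind,
              linear = transform@linear,
              translation = transform@translation,
              center = transform@center)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a transform from JSON
#'
#' @param path JSON file written by [writeTransform()].
#' @return a [SpatialTransform-class].
#' @export
readTransform <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SpatialTransform", kind = doc$kind,
      linear = matrix(as.numeric(doc$linear), 3, 3),
      translation = as.numeric(doc$translation),
      center = as.numeric(doc$center))
}

#' Write evaluation records to CSV
#'
#' One row per (dataset, configuration).
#'
#' @param records data.frame of evaluation records.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeEvaluationCSV <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read evaluation records from CSV
#' @param path CSV written by [writeEvaluationCSV()].
#' @return data.frame of evaluation records.
#' @export
readEvaluationCSV <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a stage/alternative weight table
#'
#' One row per weighted transition (stage, alternative, one weight column
#' per calibration), mirroring how calibrated weights are conventionally
#' tabulated.
#'
#' @param calibrations named list of [CalibrationResult-class] objects;
#'   names become weight column suffixes.
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
writeWeightTable <- function(calibrations, path) {
  net <- buildRegistrationNet()
  tr <- net@transitions[net@transitions$weighted, ]
  tab <- data.frame(stage = tr$stage, alternative = tr$label,
                    stringsAsFactors = FALSE)
  for (nm in names(calibrations))
    tab[[paste0("weight_mm_", nm)]] <-
      unname(calibrations[[nm]]@weights[tr$id])
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
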