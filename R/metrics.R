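#' Maximum geometric error between corresponding landmark sets
#'
#' The worst-case landmark misfit: the maximum over corresponding point
#' pairs (matched by index, with matching labels) of the Euclidean distance
#' in mm. A conservative, clinician-interpretable registration error that
#' lives directly in image space.
#'
#' @param reference a [LandmarkSet-class] (markers on the fixed image).
#' @param recovered a [LandmarkSet-class] (misaligned markers transported
#'   back through the estimated registration).
#' @return maximum distance in mm.
#' @examples
#' a <- landmarkSet(rbind(c(0, 0, 0), c(10, 0, 0)))
#' b <- landmarkSet(rbind(c(0, 0, 1), c(10, 4, 0)))
#' maxGeometricError(a, b)  # 4
#' @export
maxGeometricError <- function(reference, recovered) {
  if (length(reference) != length(recovered))
    stop("landmark sets must have equal cardinality", call. = FALSE)
  if (!identical(reference@labels, recovered@labels))
    stop("landmark labels must match in order", call. = FALSE)
  max(sqrt(rowSums((reference@points - recovered@points)^2)))
}

# Joint histogram (simple binning) of two equal-length intensity vectors.
jointHistogram <- function(a, b, bins) {
  binIdx <- function(v) {
    rng <- range(v)
    if (rng[2] <= rng[1]) return(NULL)
    pmin(pmax(floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L, 1L), bins)
  }
  ia <- binIdx(a); ib <- binIdx(b)
  if (is.null(ia) || is.null(ib)) return(NULL)
  matrix(tabulate(ia + bins * (ib - 1L), nbins = bins * bins), bins, bins)
}

entropyFromCounts <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information of two registered volumes
#'
#' Studholme overlap-invariant form \eqn{(H(F) + H(R)) / H(F, R)} from a
#' bins-by-bins joint histogram, restricted to the fixed support mask;
#' ranges over \[1, 2\] with 2 for identical images and 1 for independent
#' ones.
#'
#' @param fixed,registered [ImageVolume-class] objects on a common grid.
#' @param bins histogram bins (>= 8, default 50).
#' @return NMI in \[1, 2\].
#' @export
normalizedMutualInformation <- function(fixed, registered, bins = 50) {
  if (bins < 8) stop("bins must be >= 8", call. = FALSE)
  stopifnot(all(dim(fixed@voxels) == dim(registered@voxels)))
  mask <- supportMask(fixed)
  a <- fixed@voxels[mask]; b <- registered@voxels[mask]
  H <- jointHistogram(a, b, as.integer(bins))
  if (is.null(H))
    stop("degenerate (constant) image: NMI undefined", call. = FALSE)
  hf <- entropyFromCounts(rowSums(H))
  hr <- entropyFromCounts(colSums(H))
  hfr <- entropyFromCounts(H)
  if (hfr <= 0)
    stop("degenerate joint histogram: NMI undefined", call. = FALSE)
  (hf + hr) / hfr
}

#' Normalized root-mean-square intensity difference
#'
#' RMS of voxelwise (fixed - registered) over the fixed support mask,
#' normalized by the intensity range (max - min) of the fixed image over
#' that mask.
#'
#' @param fixed,registered [ImageVolume-class] objects on a common grid.
#' @return non-negative dimensionless value.
#' @export
normalizedRMS <- function(fixed, registered) {
  stopifnot(all(dim(fixed@voxels) == dim(registered@voxels)))
  mask <- supportMask(fixed)
  a <- fixed@voxels[mask]; b <- registered@voxels[mask]
  rng <- max(a) - min(a)
  if (rng <= 0)
    stop("constant fixed image: NRMS normalization undefined", call. = FALSE)
  sqrt(mean((a - b)^2)) / rng
}

# 3D gradient magnitude (central differences, physical spacing).
gradientMagnitude <- function(volume) {
  v <- volume@voxels; sp <- volume@spacing
  gx <- (shiftArray(v, c(-1, 0, 0)) - shiftArray(v, c(1, 0, 0))) / (2 * sp[1])
  gy <- (shiftArray(v, c(0, -1, 0)) - shiftArray(v, c(0, 1, 0))) / (2 * sp[2])
  gz <- (shiftArray(v, c(0, 0, -1)) - shiftArray(v, c(0, 0, 1))) / (2 * sp[3])
  sqrt(gx^2 + gy^2 + gz^2)
}

#' Edge overlap of two registered volumes
#'
#' Binary edge maps are extracted by thresholding the 3D gradient
#' magnitude at the 90th percentile of its nonzero values (derived
#' identically for both images); each edge set is dilated by one voxel and
#' the Dice coefficient of the dilated sets is returned.
#'
#' @param fixed,registered [ImageVolume-class] objects on a common grid.
#' @return overlap fraction in \[0, 1\].
#' @export
edgeOverlap <- function(fixed, registered) {
  stopifnot(all(dim(fixed@voxels) == dim(registered@voxels)))
  edges <- function(vol) {
    g <- gradientMagnitude(vol)
    nz <- g[g > 0]
    if (!length(nz))
      stop("edgeless (flat) image: edge overlap undefined", call. = FALSE)
    morph3d(g >= as.numeric(quantile(nz, 0.9)), 1, "dilate")
  }
  a <- edges(fixed); b <- edges(registered)
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Evaluate one registration run
#'
#' Applies the full evaluation protocol: the misaligned landmarks are
#' transported back to fixed space through the inverse of the estimated
#' transform and compared to the reference landmarks (MGE); the moving
#' volume is resampled through the estimated transform with the
#' configuration's interpolator and compared to the fixed volume (NMI,
#' NRMS, edge overlap).
#'
#' @param fixed,moving [ImageVolume-class] objects.
#' @param result a [RegistrationResult-class] from [registerVolumes()].
#' @param landmarksReference [LandmarkSet-class] on the fixed image.
#' @param landmarksMisaligned [LandmarkSet-class] on the moving image.
#' @param config the [PipelineConfig-class] that produced \code{result}.
#' @param datasetId label for the volume pair.
#' @return a one-row data.frame (an evaluation record) with columns
#'   \code{dataset_id}, \code{transform}, \code{optimizer}, \code{interp},
#'   \code{mge_mm}, \code{nmi}, \code{nrms}, \code{eo}, \code{converged}.
#' @export
evaluateRegistration <- function(fixed, moving, result, landmarksReference,
                                 landmarksMisaligned, config,
                                 datasetId = "dataset") {
  est <- result@transform
  recovered <- transformLandmarks(landmarksMisaligned, invertTransform(est))
  mge <- maxGeometricError(landmarksReference, recovered)
  registered <- resampleVolume(moving, est, config@interpolator)
  data.frame(dataset_id = datasetId,
             transform = config@transformKind,
             optimizer = config@optimizer,
             interp = config@interpolator,
             mge_mm = mge,
             nmi = normalizedMutualInformation(fixed, registered),
             nrms = normalizedRMS(fixed, registered),
             eo = edgeOverlap(fixed, registered),
             converged = result@converged,
             stringsAsFactors = FALSE)
}
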