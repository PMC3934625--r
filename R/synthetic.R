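#' Generate a brain-like multi-tissue phantom
#'
#' Builds a deterministic (per seed) phantom of nested smooth ellipsoidal
#' compartments: zero background, a "skull" shell, cortical grey matter,
#' white matter and two CSF-filled ventricles. T1 and T2 phantoms generated
#' with the same seed share the exact same geometry but use
#' modality-specific tissue intensity tables (T1: WM > GM > CSF; T2:
#' CSF > GM > WM) whose mapping is non-monotonic, so mutual information is
#' an informative similarity while monomodal metrics (correlation, SSD)
#' would fail — mirroring the multimodal T1/T2 setting the framework
#' targets. A seeded low-frequency intensity texture and a light Gaussian
#' smoothing make the interior non-piecewise-constant; background voxels
#' are exactly 0 before any noise injection.
#'
#' @param gridShape integer(3), voxels per axis (each >= 32).
#' @param spacing numeric(3), voxel size in mm.
#' @param modality \code{"T1"} or \code{"T2"}.
#' @param seed integer; same seed, same arguments give a voxelwise
#'   identical volume.
#' @return an [ImageVolume-class].
#' @examples
#' p <- generatePhantom(c(32, 32, 32), spacing = c(2, 2, 2), seed = 1)
#' @export
generatePhantom <- function(gridShape = c(64, 64, 64), spacing = c(2, 2, 2),
                            modality = c("T1", "T2"), seed = 1) {
  modality <- match.arg(modality)
  gridShape <- as.integer(gridShape)
  if (length(gridShape) != 3L || any(gridShape < 32L))
    stop("gridShape must be 3 integers, each >= 32", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)", call. = FALSE)

  extent <- (gridShape - 1) * spacing
  center <- extent / 2
  # geometry jitter is seeded so different seeds give different subjects,
  # but T1/T2 of the same seed share it exactly
  geo <- withr::with_seed(as.integer(seed), {
    list(axScale = runif(3, 0.95, 1.05),
         ventOff = runif(3, -0.02, 0.02),
         phase   = runif(6, 0, 2 * pi))
  })

  halfAx <- 0.42 * extent * geo$axScale          # outer skull semi-axes
  x <- (seq_len(gridShape[1]) - 1) * spacing[1] - center[1]
  y <- (seq_len(gridShape[2]) - 1) * spacing[2] - center[2]
  z <- (seq_len(gridShape[3]) - 1) * spacing[3] - center[3]
  # normalized squared ellipsoidal radius on the full grid
  rx2 <- (x / halfAx[1])^2
  ry2 <- (y / halfAx[2])^2
  rz2 <- (z / halfAx[3])^2
  r2 <- outer(outer(rx2, ry2, `+`), rz2, `+`)

  tis <- tissueTable(modality)
  vol <- array(0, gridShape)
  vol[r2 <= 1] <- tis["skull"]
  vol[r2 <= 0.88] <- tis["csf"]     # subarachnoid CSF rim
  vol[r2 <= 0.80] <- tis["gm"]
  vol[r2 <= 0.55] <- tis["wm"]

  # two ellipsoidal ventricles, mirrored about the midline
  for (side in c(-1, 1)) {
    vc <- center + extent * (c(side * 0.08, 0.02, 0.05) + geo$ventOff)
    vax <- c(0.06, 0.14, 0.10) * extent
    vr2 <- outer(outer(((x + center[1] - vc[1]) / vax[1])^2,
                       ((y + center[2] - vc[2]) / vax[2])^2, `+`),
                 ((z + center[3] - vc[3]) / vax[3])^2, `+`)
    vol[vr2 <= 1] <- tis["csf"]
  }

  # seeded smooth texture inside the head only (+-6% modulation)
  ph <- geo$phase
  tex <- outer(outer(sin(2 * pi * x / extent[1] + ph[1]) +
                     0.5 * sin(4 * pi * x / extent[1] + ph[2]),
                     sin(2 * pi * y / extent[2] + ph[3]) +
                     0.5 * sin(4 * pi * y / extent[2] + ph[4]), `+`),
               sin(2 * pi * z / extent[3] + ph[5]) +
               0.5 * sin(4 * pi * z / extent[3] + ph[6]), `+`)
  vol <- vol * (1 + 0.02 * tex)

  sm <- cpp_smooth_gauss(as.numeric(vol), gridShape, 0.8)
  vol <- array(sm, gridShape)
  vol[r2 > 1] <- 0                   # background stays exactly zero
  imageVolume(vol, spacing, origin = c(0, 0, 0), modality = modality)
}

# Seeded TPS jitter field: uniform control-point displacements (each
# component in [-maxDisplacement, maxDisplacement]) and the interpolation
# coefficients of the 3D biharmonic TPS that passes through them exactly.
tpsJitterField <- function(volume, maxDisplacement, gridSpacing = NULL,
                           seed = 1) {
  extent <- (dim(volume@voxels) - 1) * volume@spacing
  if (is.null(gridSpacing)) gridSpacing <- max(extent) / 4
  axes <- lapply(1:3, function(ax) {
    n <- max(2L, floor(extent[ax] / gridSpacing) + 1L)
    volume@origin[ax] + seq(0, extent[ax], length.out = n)
  })
  ctrl <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  colnames(ctrl) <- NULL
  K <- nrow(ctrl)
  disp <- withr::with_seed(as.integer(seed),
    matrix(runif(3 * K, -maxDisplacement, maxDisplacement), K, 3))
  # TPS interpolation system [K P; P' 0] [W; A] = [disp; 0]
  dd <- as.matrix(stats::dist(ctrl))
  P <- cbind(1, ctrl)
  sys <- rbind(cbind(dd, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(disp, matrix(0, 4, 3))
  coef <- solve(sys, rhs)
  list(ctrl = ctrl, disp = disp,
       W = coef[seq_len(K), , drop = FALSE],
       A = coef[K + 1:4, , drop = FALSE])
}

tissueTable <- function(modality) {
  if (modality == "T1") c(skull = 90, csf = 40, gm = 140, wm = 200)
  else                  c(skull = 30, csf = 240, gm = 110, wm = 60)
}

#' Warp a volume with a random thin-plate-spline jitter
#'
#' Control points on a regular 3D grid across the volume extent are
#' displaced by uniform random vectors with each component in
#' \code{[-maxDisplacement, +maxDisplacement]}; a thin-plate-spline
#' interpolant (3D biharmonic kernel \eqn{U(r) = r}) of those
#' displacements defines a smooth displacement field, and the volume is
#' warped by pulling each output voxel from its displaced position. The
#' default 2 mm bound produces global jitter on the scale of normal
#' inter-scan anatomical variation without fine local structure.
#'
#' @param volume an [ImageVolume-class].
#' @param maxDisplacement non-negative scalar, per-component displacement
#'   bound in mm (default 2).
#' @param gridSpacing control-grid spacing in mm; default one quarter of
#'   the volume extent per axis.
#' @param seed integer.
#' @param interpolator interpolator used for the warp resampling.
#' @return a warped [ImageVolume-class] on the same grid.
#' @export
applyTPSJitter <- function(volume, maxDisplacement = 2, gridSpacing = NULL,
                           seed = 1, interpolator = "linear") {
  if (!is.finite(maxDisplacement) || maxDisplacement < 0)
    stop("maxDisplacement must be >= 0", call. = FALSE)
  d <- dim(volume@voxels)
  if (maxDisplacement == 0) return(volume)
  field <- tpsJitterField(volume, maxDisplacement, gridSpacing, seed)
  pts <- voxelGridPoints(volume)
  dfield <- cpp_tps_disp(field$ctrl, field$W, field$A, pts)
  samplePts <- pts + dfield
  code <- interpCode(interpolator)
  src <- as.numeric(volume@voxels)
  if (code == 2L) src <- cpp_bspline_prefilter(src, d)
  vals <- cpp_sample_points(src, d, volume@spacing, volume@origin,
                            samplePts, code)
  imageVolume(array(vals, d), volume@spacing, volume@origin,
              volume@modality)
}

#' Sample a random rigid misalignment
#'
#' Each translation component is drawn uniformly from
#' \code{[0, transMax]} mm (the bounds are magnitudes per axis, minimum 0)
#' and each Euler angle uniformly from \code{[-rotMax, +rotMax]} degrees,
#' applied about \code{center}. Mimics head repositioning between serial
#' MRI acquisitions.
#'
#' @param transMax non-negative scalar, mm (default 25).
#' @param rotMax non-negative scalar, degrees (default 5).
#' @param seed integer.
#' @param center numeric(3), physical rotation centre in mm.
#' @return a rigid [SpatialTransform-class].
#' @export
sampleMisalignment <- function(transMax = 25, rotMax = 5, seed = 1,
                               center = c(0, 0, 0)) {
  if (!is.finite(transMax) || transMax < 0 || !is.finite(rotMax) || rotMax < 0)
    stop("transMax and rotMax must be >= 0", call. = FALSE)
  draw <- withr::with_seed(as.integer(seed), {
    list(t = runif(3, 0, transMax), a = runif(3, -rotMax, rotMax))
  })
  rigidTransform(angles = draw$a, translation = draw$t, center = center)
}

#' Place random landmarks inside the support of a volume
#'
#' Markers are seeded uniformly inside the (slightly eroded) support mask
#' with a pairwise separation of at least \code{minSeparation} voxels, and
#' are returned in physical mm coordinates.
#'
#' @param volume an [ImageVolume-class] with non-empty support.
#' @param n number of markers (default 16).
#' @param seed integer.
#' @param minSeparation minimum pairwise separation in voxels.
#' @return a [LandmarkSet-class] with labels \code{"M1"..."Mn"}.
#' @export
placeLandmarks <- function(volume, n = 16, seed = 1, minSeparation = 5) {
  mask <- morph3d(supportMask(volume), 2, "erode")
  cand <- which(mask, arr.ind = TRUE)
  if (nrow(cand) < n)
    stop("support mask too small to host ", n, " landmarks", call. = FALSE)
  minSepMm <- minSeparation * min(volume@spacing)
  sel <- withr::with_seed(as.integer(seed), {
    ord <- sample.int(nrow(cand))
    picked <- integer(0)
    pts <- matrix(0, 0, 3)
    for (i in ord) {
      p <- volume@origin + (cand[i, ] - 1) * volume@spacing
      if (nrow(pts) == 0 ||
          min(sqrt(colSums((t(pts) - p)^2))) >= minSepMm) {
        pts <- rbind(pts, p)
        picked <- c(picked, i)
        if (length(picked) == n) break
      }
    }
    pts
  })
  if (nrow(sel) < n)
    stop("could not place ", n, " landmarks with ", minSeparation,
         "-voxel separation", call. = FALSE)
  rownames(sel) <- NULL
  landmarkSet(sel, paste0("M", seq_len(n)))
}

#' Create a LandmarkSet
#' @param points n x 3 numeric matrix (mm).
#' @param labels character(n); defaults to \code{"M1"..."Mn"}.
#' @return a [LandmarkSet-class].
#' @export
landmarkSet <- function(points, labels = NULL) {
  points <- as.matrix(points)
  if (is.null(labels)) labels <- paste0("M", seq_len(nrow(points)))
  new("LandmarkSet", points = unname(points), labels = as.character(labels))
}

#' @rdname LandmarkSet-class
#' @export
setMethod("landmarkPoints", "LandmarkSet", function(object) object@points)

#' @rdname LandmarkSet-class
#' @export
setMethod("landmarkLabels", "LandmarkSet", function(object) object@labels)

#' @rdname LandmarkSet-class
#' @export
setMethod("length", "LandmarkSet", function(x) nrow(x@points))

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet: %d markers (mm)\n", nrow(object@points)))
  df <- data.frame(label = object@labels, round(object@points, 3))
  names(df)[2:4] <- c("x_mm", "y_mm", "z_mm")
  print(head(df, 8))
  if (nrow(df) > 8) cat("  ...\n")
})

#' Map landmarks through a transform
#'
#' Order and labels are preserved; each point is mapped in physical
#' coordinates.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param transform a [SpatialTransform-class].
#' @return a [LandmarkSet-class].
#' @export
transformLandmarks <- function(landmarks, transform) {
  landmarkSet(applyTransform(transform, landmarks@points),
              landmarks@labels)
}

#' Add Rician magnitude noise to a volume
#'
#' Each output voxel is \eqn{\sqrt{(v + g_1)^2 + g_2^2}} with
#' \eqn{g_1, g_2} independent zero-mean Gaussians of standard deviation
#' \code{sigma}; this realizes exactly the Rician law of MR magnitude
#' images, with the Rayleigh special case on zero-signal background.
#'
#' @param volume an [ImageVolume-class].
#' @param sigma positive scalar, complex-domain noise standard deviation.
#' @param seed integer.
#' @return a noisy [ImageVolume-class].
#' @export
addRicianNoise <- function(volume, sigma, seed = 1) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  d <- dim(volume@voxels)
  n <- prod(d)
  noisy <- withr::with_seed(as.integer(seed), {
    g1 <- rnorm(n, 0, sigma); g2 <- rnorm(n, 0, sigma)
    sqrt((as.numeric(volume@voxels) + g1)^2 + g2^2)
  })
  imageVolume(array(noisy, d), volume@spacing, volume@origin,
              volume@modality)
}

#' Extract background regions from a volume
#'
#' Pools the intensities of \code{nRegions} disjoint rectangular regions
#' lying entirely in the image background — the complement of the support
#' mask eroded by 3 voxels (i.e. the support is first dilated by 3 voxels
#' and the regions avoid it). Used to estimate noise parameters where the
#' signal-free background assumption holds.
#'
#' @param volume an [ImageVolume-class].
#' @param nRegions number of regions (default 4).
#' @param regionSize integer(3) region edge lengths in voxels.
#' @param seed integer.
#' @return numeric vector of pooled intensities, with attribute
#'   \code{"corners"} (region corner voxels, n x 3).
#' @export
extractBackgroundRegions <- function(volume, nRegions = 4,
                                     regionSize = c(8, 8, 8), seed = 1) {
  d <- dim(volume@voxels)
  regionSize <- as.integer(regionSize)
  # despeckle before dilating: on noisy volumes the threshold mask carries
  # isolated background voxels that erosion removes
  support <- morph3d(supportMask(volume), 1, "erode")
  bg <- !morph3d(support, 4, "dilate")
  corners <- withr::with_seed(as.integer(seed), {
    picked <- matrix(0L, 0, 3)
    occupied <- array(FALSE, d)
    tries <- 0L
    while (nrow(picked) < nRegions && tries < 5000L) {
      tries <- tries + 1L
      c0 <- sapply(1:3, function(ax) sample.int(d[ax] - regionSize[ax] + 1L, 1))
      ix <- lapply(1:3, function(ax) c0[ax]:(c0[ax] + regionSize[ax] - 1L))
      inBg <- all(bg[ix[[1]], ix[[2]], ix[[3]]])
      free <- !any(occupied[ix[[1]], ix[[2]], ix[[3]]])
      if (inBg && free) {
        occupied[ix[[1]], ix[[2]], ix[[3]]] <- TRUE
        picked <- rbind(picked, c0)
      }
    }
    picked
  })
  if (nrow(corners) < nRegions)
    stop("insufficient background for ", nRegions, " disjoint regions",
         call. = FALSE)
  samples <- unlist(lapply(seq_len(nRegions), function(r) {
    ix <- lapply(1:3, function(ax)
      corners[r, ax]:(corners[r, ax] + regionSize[ax] - 1L))
    as.numeric(volume@voxels[ix[[1]], ix[[2]], ix[[3]]])
  }))
  rownames(corners) <- NULL
  attr(samples, "corners") <- corners
  samples
}
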