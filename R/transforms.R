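#' Construct a rigid transform from Euler angles
#'
#' Angles follow the intrinsic Z-Y-X convention: the rotation matrix is
#' \eqn{R = R_z(\gamma) R_y(\beta) R_x(\alpha)}. The map acts as
#' \eqn{y = R (x - c) + c + t}.
#'
#' @param angles numeric(3), rotations about x, y, z in degrees.
#' @param translation numeric(3) in mm.
#' @param center numeric(3), physical rotation centre in mm.
#' @return a [SpatialTransform-class] of kind \code{"rigid"}.
#' @examples
#' t <- rigidTransform(c(0, 0, 90), translation = c(1, 0, 0))
#' applyTransform(t, matrix(c(1, 0, 0), 1))
#' @export
rigidTransform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  stopifnot(length(angles) == 3L, all(is.finite(angles)))
  new("SpatialTransform", kind = "rigid", linear = eulerZYX(angles),
      translation = as.numeric(translation), center = as.numeric(center))
}

#' Construct an affine transform
#'
#' The map acts as \eqn{y = A (x - c) + c + t}.
#'
#' @param linear 3x3 numeric matrix.
#' @param translation numeric(3) in mm.
#' @param center numeric(3) in mm.
#' @return a [SpatialTransform-class] of kind \code{"affine"}.
#' @export
affineTransform <- function(linear = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  new("SpatialTransform", kind = "affine",
      linear = matrix(as.numeric(linear), 3, 3),
      translation = as.numeric(translation), center = as.numeric(center))
}

#' Identity transform
#' @param kind \code{"rigid"} or \code{"affine"}.
#' @return a [SpatialTransform-class] that maps every point to itself.
#' @export
identityTransform <- function(kind = "rigid") {
  new("SpatialTransform", kind = kind, linear = diag(3),
      translation = c(0, 0, 0), center = c(0, 0, 0))
}

# Intrinsic Z-Y-X rotation matrix from degrees.
eulerZYX <- function(anglesDeg) {
  a <- anglesDeg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Homogeneous (M, v) form: y = M x + v, folding in the rotation centre.
transformMV <- function(transform) {
  M <- transform@linear
  v <- transform@center + transform@translation -
    as.numeric(M %*% transform@center)
  list(M = M, v = v)
}

#' 4x4 homogeneous matrix of a transform
#' @param transform a [SpatialTransform-class].
#' @return a 4x4 numeric matrix.
#' @export
transformMatrix <- function(transform) {
  mv <- transformMV(transform)
  rbind(cbind(mv$M, mv$v), c(0, 0, 0, 1))
}

#' @describeIn applyTransform map an n x 3 matrix of points.
#' @export
setMethod("applyTransform", signature("SpatialTransform", "matrix"),
  function(transform, points) {
    mv <- transformMV(transform)
    t(mv$M %*% t(points) + mv$v)
  })

#' @describeIn applyTransform map a single point given as numeric(3).
#' @export
setMethod("applyTransform", signature("SpatialTransform", "numeric"),
  function(transform, points) {
    as.numeric(applyTransform(transform, matrix(points, 1, 3)))
  })

#' Compose two transforms
#'
#' Returns the transform \code{a} after \code{b}: the result maps \eqn{x}
#' to \eqn{a(b(x))}. Composing two rigid transforms yields a rigid
#' transform; any other combination is affine.
#'
#' @param a,b [SpatialTransform-class] objects.
#' @return a [SpatialTransform-class] with centre at the origin.
#' @export
composeTransforms <- function(a, b) {
  mva <- transformMV(a); mvb <- transformMV(b)
  M <- mva$M %*% mvb$M
  v <- as.numeric(mva$M %*% mvb$v) + mva$v
  kind <- if (a@kind == "rigid" && b@kind == "rigid") "rigid" else "affine"
  new("SpatialTransform", kind = kind, linear = M, translation = v,
      center = c(0, 0, 0))
}

#' Invert a transform
#' @param transform a [SpatialTransform-class].
#' @return the inverse [SpatialTransform-class] (same kind).
#' @export
invertTransform <- function(transform) {
  mv <- transformMV(transform)
  Mi <- solve(mv$M)
  new("SpatialTransform", kind = transform@kind, linear = Mi,
      translation = as.numeric(-Mi %*% mv$v), center = c(0, 0, 0))
}

#' @rdname SpatialTransform-class
#' @export
setMethod("transformKind", "SpatialTransform", function(object) object@kind)

setMethod("show", "SpatialTransform", function(object) {
  cat(sprintf("SpatialTransform (%s)\n", object@kind))
  cat("  linear:\n")
  print(round(object@linear, 6))
  cat(sprintf("  translation (mm): %s\n",
              paste(round(object@translation, 4), collapse = ", ")))
  cat(sprintf("  center (mm):      %s\n",
              paste(round(object@center, 4), collapse = ", ")))
})
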