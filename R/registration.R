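#' Create a pipeline configuration
#'
#' @param transformKind \code{"rigid"} or \code{"affine"}.
#' @param optimizer \code{"RSGD"} or \code{"EO"}.
#' @param interpolator \code{"NN"}, \code{"linear"} or \code{"bspline"}.
#' @return a [PipelineConfig-class] (metric fixed to MI).
#' @export
pipelineConfig <- function(transformKind = "rigid", optimizer = "RSGD",
                           interpolator = "linear") {
  new("PipelineConfig", transformKind = transformKind, optimizer = optimizer,
      interpolator = interpolator, metric = "MI")
}

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf("PipelineConfig: %s / %s / %s (metric: MI)\n",
              object@transformKind, object@optimizer, object@interpolator))
})

#' Enumerate all pipeline configurations
#'
#' All combinations of the selectable functional blocks, in a fixed
#' documented order: transform outermost (rigid, affine), optimizer middle
#' (RSGD, EO), interpolator innermost (NN, linear, bspline). The first
#' element is therefore (rigid, RSGD, NN).
#'
#' @return list of 12 [PipelineConfig-class] objects.
#' @export
enumerateConfigs <- function() {
  out <- list()
  for (tk in c("rigid", "affine"))
    for (op in c("RSGD", "EO"))
      for (ip in c("NN", "linear", "bspline"))
        out[[length(out) + 1L]] <- pipelineConfig(tk, op, ip)
  out
}

# Short unique key for a configuration (used for record joins).
configKey <- function(config) {
  paste(config@transformKind, config@optimizer, config@interpolator,
        sep = "/")
}

#' Parse a pipeline configuration from structured text
#'
#' Accepts \code{key: value} lines (or a file of them) with keys
#' \code{transform}, \code{optimizer}, \code{interp} and the value
#' spellings used on the command line (\code{rigid/affine},
#' \code{rsgd/evo}, \code{nn/linear/bspline}, case-insensitive).
#'
#' @param x character vector of lines, a single multi-line string, or the
#'   path of a text file.
#' @return a [PipelineConfig-class].
#' @examples
#' parsePipelineConfig(c("transform: rigid", "optimizer: rsgd",
#'                       "interp: linear"))
#' @export
parsePipelineConfig <- function(x) {
  if (length(x) == 1 && file.exists(x)) x <- readLines(x, warn = FALSE)
  lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop("expected 'key: value' lines, got: ", lines[bad][1], call. = FALSE)
  keys <- tolower(trimws(vapply(kv, `[`, "", 1)))
  vals <- tolower(trimws(vapply(kv, `[`, "", 2)))
  names(vals) <- keys
  pick <- function(key, map) {
    v <- vals[[key]]
    if (is.null(v) || !v %in% names(map))
      stop("config needs '", key, ": {", paste(names(map), collapse = ","),
           "}'", call. = FALSE)
    unname(map[[v]])
  }
  pipelineConfig(
    transformKind = pick("transform", c(rigid = "rigid", affine = "affine")),
    optimizer = pick("optimizer", c(rsgd = "RSGD", evo = "EO")),
    interpolator = pick("interp", c(nn = "NN", linear = "linear",
                                    bspline = "bspline")))
}

#' Mutual information between two volumes under a transform
#'
#' MI (in nats) estimated from a bins-by-bins joint histogram of the fixed
#' intensities and the moving intensities sampled at transform-mapped
#' positions, with linear (partial-volume style) binning on both axes.
#' Samples falling outside the moving domain are excluded; the overlap must
#' retain at least 50 samples.
#'
#' @param fixed,moving [ImageVolume-class] objects.
#' @param transform a [SpatialTransform-class]; identity by default.
#' @param bins histogram bins per axis (>= 8, default 50).
#' @param interpolator moving-image interpolator.
#' @param samplePoints optional n x 3 matrix of fixed-space sample
#'   positions (mm); defaults to every fixed voxel centre.
#' @param fixedValues optional intensities at \code{samplePoints}.
#' @return MI in nats (non-negative up to estimator jitter).
#' @export
mutualInformation <- function(fixed, moving, transform = identityTransform(),
                              bins = 50, interpolator = "linear",
                              samplePoints = NULL, fixedValues = NULL) {
  if (bins < 8) stop("bins must be >= 8", call. = FALSE)
  if (is.null(samplePoints)) {
    samplePoints <- voxelGridPoints(fixed)
    fixedValues <- as.numeric(fixed@voxels)
  }
  if (is.null(fixedValues))
    fixedValues <- cpp_sample_points(as.numeric(fixed@voxels), dim(fixed@voxels),
                                     fixed@spacing, fixed@origin,
                                     samplePoints, 1L)
  code <- interpCode(interpolator)
  mov <- as.numeric(moving@voxels)
  if (code == 2L) mov <- cpp_bspline_prefilter(mov, dim(moving@voxels))
  mv <- transformMV(transform)
  mi <- cpp_mi_affine(fixedValues, samplePoints, mov, dim(moving@voxels),
                      moving@spacing, moving@origin, mv$M, mv$v, code,
                      as.integer(bins),
                      min(fixedValues), max(fixedValues),
                      min(moving@voxels), max(moving@voxels), 0L)
  if (is.na(mi))
    stop("empty (or near-empty) overlap between fixed grid and moving domain",
         call. = FALSE)
  mi
}

#' Regular-step gradient ascent
#'
#' Deterministic regular-step gradient method on a scalar objective to be
#' maximized: steps of fixed length along the normalized finite-difference
#' gradient, with the step length halved whenever the gradient direction
#' reverses; stops when the step falls below \code{minStep}, the gradient
#' vanishes, or \code{maxIter} is reached. The best-visited point is
#' tracked and returned, so more iterations can never worsen the reported
#' optimum.
#'
#' @param objective function mapping a parameter vector to a finite scalar.
#' @param par numeric initial parameters.
#' @param initStep,minStep step lengths in parameter units.
#' @param maxIter maximum iterations.
#' @param fdStep central-difference step for the gradient.
#' @param gradTol gradient-norm threshold treated as "no uphill direction".
#' @return list with \code{par}, \code{value}, \code{iterations},
#'   \code{converged}.
#' @export
optimizeRSGD <- function(objective, par, initStep = 2, minStep = 0.01,
                         maxIter = 200, fdStep = 0.25, gradTol = 1e-8) {
  f0 <- objective(par)
  if (!is.finite(f0))
    stop("objective is not finite at the initial parameters", call. = FALSE)
  best <- list(par = par, value = f0)
  step <- initStep
  prevDir <- NULL
  iter <- 0L
  converged <- FALSE
  fcur <- f0
  grad <- function(p, fc) {
    vapply(seq_along(p), function(i) {
      e <- numeric(length(p)); e[i] <- fdStep
      fp <- objective(p + e); fm <- objective(p - e)
      if (!is.finite(fp) && !is.finite(fm)) return(0)
      if (!is.finite(fp)) return((fc - fm) / fdStep)
      if (!is.finite(fm)) return((fp - fc) / fdStep)
      (fp - fm) / (2 * fdStep)
    }, numeric(1))
  }
  while (iter < maxIter) {
    iter <- iter + 1L
    g <- grad(par, fcur)
    ng <- sqrt(sum(g^2))
    if (!is.finite(ng) || ng < gradTol) { converged <- TRUE; break }
    dir <- g / ng
    if (!is.null(prevDir) && sum(dir * prevDir) < 0) step <- step / 2
    if (step < minStep) { converged <- TRUE; break }
    par <- par + step * dir
    fv <- objective(par)
    if (is.finite(fv)) {
      fcur <- fv
      if (fv > best$value) best <- list(par = par, value = fv)
    }
    prevDir <- dir
  }
  list(par = best$par, value = best$value, iterations = iter,
       converged = converged || iter == 0L)
}

#' (1+1) evolutionary ascent
#'
#' Stochastic hill-climber: a single candidate is mutated with an isotropic
#' Gaussian of adaptive radius — grown on acceptance, shrunk on rejection —
#' and accepted iff the objective improves. Seeded, hence reproducible.
#'
#' @param objective function mapping a parameter vector to a finite scalar.
#' @param par numeric initial parameters.
#' @param initRadius initial mutation radius (parameter units).
#' @param grow multiplicative radius growth on acceptance (> 1).
#' @param shrink multiplicative radius shrink on rejection (in (0, 1)).
#' @param maxIter maximum iterations.
#' @param seed integer RNG seed.
#' @return list with \code{par}, \code{value}, \code{iterations},
#'   \code{converged}.
#' @export
optimizeOnePlusOne <- function(objective, par, initRadius = 1, grow = 1.05,
                               shrink = 0.98, maxIter = 500, seed = 1) {
  if (!is.finite(grow) || grow <= 1) stop("grow must be > 1", call. = FALSE)
  if (!is.finite(shrink) || shrink <= 0 || shrink >= 1)
    stop("shrink must lie in (0, 1)", call. = FALSE)
  f0 <- objective(par)
  if (!is.finite(f0))
    stop("objective is not finite at the initial parameters", call. = FALSE)
  n <- length(par)
  withr::with_seed(as.integer(seed), {
    best <- par; fbest <- f0; radius <- initRadius
    for (iter in seq_len(maxIter)) {
      cand <- best + radius * rnorm(n)
      fc <- objective(cand)
      if (is.finite(fc) && fc > fbest) {
        best <- cand; fbest <- fc; radius <- radius * grow
      } else {
        radius <- radius * shrink
      }
    }
    list(par = best, value = fbest, iterations = as.integer(maxIter),
         converged = TRUE)
  })
}

#' Registration engine control settings
#'
#' Defaults: 3-level multiresolution pyramid (4x, 2x, 1x downsampling) —
#' needed for the large capture range of the misalignment protocol — with
#' centroid-alignment initialization; 50-bin MI; RSGD with initial step
#' 2.0, minimum step 0.01 and 200 iterations per level; (1+1) EO with
#' initial radius 1.0, grow 1.05, shrink 0.98 and 500 iterations per level.
#' Optimizer parameters live in a scaled space where one unit corresponds
#' to roughly 1 mm of landmark motion (rotation/shear entries are scaled by
#' \code{angleScale}/\code{matrixScale}).
#'
#' @param levels integer downsampling factors, coarse to fine.
#' @param bins MI histogram bins.
#' @param maxSamplesPerLevel cap on MI sample points per level.
#' @param rsgd,evo optimizer setting lists.
#' @param angleScale radians per optimizer unit for rigid angles.
#' @param matrixScale matrix-entry change per optimizer unit (affine).
#' @return a named list of settings.
#' @export
registrationControl <- function(levels = c(4L, 2L, 1L), bins = 50,
                                maxSamplesPerLevel = c(Inf, 15000, 20000),
                                rsgd = list(initStep = 2, minStep = 0.005,
                                            maxIter = 400, fdStep = 0.25),
                                evo = list(initRadius = 2, grow = 1.05,
                                           shrink = 0.99, maxIter = 1200),
                                angleScale = 0.02, matrixScale = 0.01) {
  list(levels = levels, bins = bins,
       maxSamplesPerLevel = maxSamplesPerLevel, rsgd = rsgd, evo = evo,
       angleScale = angleScale, matrixScale = matrixScale)
}

# Build a SpatialTransform from scaled optimizer parameters.
paramsToTransform <- function(p, kind, center, control) {
  if (kind == "rigid") {
    ang <- p[1:3] * control$angleScale * 180 / pi    # optimizer units -> deg
    rigidTransform(angles = ang, translation = p[4:6], center = center)
  } else {
    A <- diag(3) + matrix(p[1:9] * control$matrixScale, 3, 3)
    affineTransform(linear = A, translation = p[10:12], center = center)
  }
}

#' Register a moving volume to a fixed volume
#'
#' Maximizes mutual information over the parameters of the configured
#' transform model using the configured optimizer, sampling the moving
#' image with the configured interpolator, over a coarse-to-fine
#' multiresolution pyramid. The initial transform aligns the intensity
#' centroids of the two volumes. The returned transform maps fixed-image
#' physical coordinates to moving-image coordinates, i.e. it is directly
#' usable to resample the moving image onto the fixed grid; apply its
#' inverse to transport moving-space landmarks into fixed space.
#'
#' Optimizer failure (for example an empty overlap during search) yields a
#' result flagged \code{converged = FALSE} with diagnostics, never an
#' error.
#'
#' @param fixed,moving [ImageVolume-class] objects sharing physical-space
#'   conventions.
#' @param config a [PipelineConfig-class].
#' @param seed integer; seeds the stochastic optimizer and the MI sample
#'   subselection.
#' @param control settings from [registrationControl()].
#' @return a [RegistrationResult-class].
#' @export
registerVolumes <- function(fixed, moving, config = pipelineConfig(),
                            seed = 1, control = registrationControl()) {
  kind <- config@transformKind
  center <- volumeCenter(fixed)
  nPar <- if (kind == "rigid") 6L else 12L
  p <- numeric(nPar)
  t0 <- intensityCentroid(moving) - intensityCentroid(fixed)
  p[(nPar - 2L):nPar] <- t0
  totalIter <- 0L
  converged <- TRUE
  diagnostics <- list(initialTranslation = t0)
  lastValue <- NA_real_

  for (li in seq_along(control$levels)) {
    fac <- control$levels[li]
    fx <- downsampleVolume(fixed, fac)
    mv <- downsampleVolume(moving, fac)
    pts <- voxelGridPoints(fx)
    cap <- control$maxSamplesPerLevel[min(li, length(control$maxSamplesPerLevel))]
    if (is.finite(cap) && nrow(pts) > cap) {
      # deterministic gradient-weighted sampling: edges carry nearly all
      # of the geometric information in the MI estimate
      gm <- as.numeric(gradientMagnitude(fx))
      keep <- order(gm, decreasing = TRUE)[seq_len(cap)]
      pts <- pts[keep, , drop = FALSE]
    }
    # on the coarse capture levels a frozen sub-voxel jitter de-aliases
    # the sample lattice, keeping the metric quasi-smooth even under
    # nearest-neighbour sampling; the finest level samples at voxel
    # centres so each interpolator keeps its genuine precision limit
    if (fac > 1) {
      jit <- withr::with_seed(7890L + li,
        matrix(runif(3 * nrow(pts), -0.45, 0.45), ncol = 3))
      pts <- pts + jit %*% diag(fx@spacing)
    }
    vals <- cpp_sample_points(as.numeric(fx@voxels), dim(fx@voxels),
                              fx@spacing, fx@origin, pts, 1L)
    code <- interpCode(config@interpolator)
    movArr <- as.numeric(mv@voxels)
    if (code == 2L) movArr <- cpp_bspline_prefilter(movArr, dim(mv@voxels))
    mdim <- dim(mv@voxels); msp <- mv@spacing; mor <- mv@origin
    mmin <- min(mv@voxels); mmax <- max(mv@voxels)
    fmin <- min(vals); fmax <- max(vals)
    bins <- as.integer(control$bins)

    objective <- function(pp) {
      tr <- paramsToTransform(pp, kind, center, control)
      tmv <- transformMV(tr)
      # out-of-domain moving samples count as background zero: magnitude
      # images vanish outside their support, and this keeps the objective
      # free of the shrinking-overlap artefact during search
      mi <- cpp_mi_affine(vals, pts, movArr, mdim, msp, mor, tmv$M, tmv$v,
                          code, bins, fmin, fmax, mmin, mmax, 1L)
      if (is.na(mi)) -Inf else mi
    }

    fInit <- objective(p)
    if (!is.finite(fInit)) {
      converged <- FALSE
      diagnostics$failure <- sprintf(
        "empty overlap at level %d (factor %d)", li, fac)
      break
    }
    res <- if (config@optimizer == "RSGD") {
      # under NN interpolation the MI landscape is piecewise constant on
      # the half-voxel scale; the difference step must straddle it
      fd <- control$rsgd$fdStep
      if (config@interpolator == "NN") fd <- max(fd, min(mv@spacing) / 2)
      optimizeRSGD(objective, p, initStep = control$rsgd$initStep,
                   minStep = control$rsgd$minStep,
                   maxIter = control$rsgd$maxIter,
                   fdStep = fd)
    } else {
      # mutation budget scales with the search dimension
      optimizeOnePlusOne(objective, p, initRadius = control$evo$initRadius,
                         grow = control$evo$grow,
                         shrink = control$evo$shrink,
                         maxIter = ceiling(control$evo$maxIter * nPar / 6),
                         seed = as.integer(seed) + 7L * li)
    }
    p <- res$par
    lastValue <- res$value
    totalIter <- totalIter + res$iterations
    converged <- converged && res$converged
    diagnostics[[paste0("level", fac)]] <-
      list(value = res$value, iterations = res$iterations)
  }

  new("RegistrationResult",
      transform = paramsToTransform(p, kind, center, control),
      metricValue = if (is.na(lastValue)) -Inf else lastValue,
      iterations = totalIter, converged = converged,
      diagnostics = diagnostics)
}

#' @rdname RegistrationResult-class
#' @export
setMethod("estimatedTransform", "RegistrationResult",
          function(object) object@transform)

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: MI = %.4f, %d iterations, %s\n",
              object@metricValue, object@iterations,
              if (object@converged) "converged" else "NOT converged"))
  show(object@transform)
})
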