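#' Build the single system model for a scan
#'
#' One matched forward/adjoint operator pair covering the rays of all
#' \code{nViews * nSources} frames; the single-source configuration is the
#' same constructor applied to the degenerate geometry.  Pixels outside a
#' frame's collimated support carry zero weight in both directions.
#'
#' @param geometry a \code{\linkS4class{ScannerGeometry}}.
#' @param protocol an \code{\linkS4class{AcquisitionProtocol}} (supplies
#'   views and angles; its source count must match the geometry).
#' @param gridDim integer c(nx, ny, nz) of the reconstruction grid.
#' @param voxelSize isotropic reconstruction voxel (mm).
#' @return a \code{\linkS4class{SystemModel}}.
#' @export
buildSystem <- function(geometry, protocol, gridDim, voxelSize) {
  if (protocol@nSources != geometry@nSources)
    stop("protocol and geometry disagree on the number of sources")
  np <- detectorPixels(geometry)
  ns <- geometry@nSources
  angles <- gantryAngles(protocol)
  frameSrc <- rep(seq_len(ns), times = protocol@nViews)
  frameAngle <- rep(angles, each = ns)
  fg <- frameGeometryMatrices(geometry, frameSrc, frameAngle, band = "fwhm")
  fi <- data.frame(frame = seq_along(frameSrc),
                   view = rep(seq_len(protocol@nViews), each = ns),
                   source = frameSrc, angle = frameAngle)
  new("SystemModel", geometry = geometry, frameInfo = fi,
      src = fg$src, detc = fg$detc, uhat = fg$uhat, vhat = fg$vhat,
      band = fg$band, gridDim = as.integer(gridDim),
      voxelSize = as.numeric(voxelSize),
      nu = as.integer(np["nu"]), nv = as.integer(np["nv"]))
}

#' @rdname forwardProject
setMethod("forwardProject", "SystemModel", function(system, volume) {
  stopifnot(identical(dim(volume), as.integer(system@gridDim)))
  p <- cpp_project_forward(as.numeric(volume), system@gridDim,
                           system@voxelSize, system@src, system@detc,
                           system@uhat, system@vhat, system@nu, system@nv,
                           system@geometry@pixelPitch,
                           system@geometry@pixelPitch, system@band)
  array(p, dim = c(system@nu, system@nv, nrow(system@src)))
})

#' @rdname backProject
setMethod("backProject", "SystemModel", function(system, projections) {
  v <- cpp_project_backward(as.numeric(projections), system@gridDim,
                            system@voxelSize, system@src, system@detc,
                            system@uhat, system@vhat, system@nu, system@nv,
                            system@geometry@pixelPitch,
                            system@geometry@pixelPitch, system@band)
  array(v, dim = system@gridDim)
})

#' @rdname frameInfo
setMethod("frameInfo", "SystemModel", function(object) object@frameInfo)

setMethod("show", "SystemModel", function(object) {
  cat(sprintf("SystemModel: %d frames of %d x %d pixels -> %s grid at %.2f mm\n",
              nrow(object@src), object@nu, object@nv,
              paste(object@gridDim, collapse = " x "), object@voxelSize))
})

#' Simultaneous iterative reconstruction (SIRT)
#'
#' Solves the projection system with the row/column-normalized gradient
#' iteration
#' \deqn{x_{k+1} = clip_+ (x_k + \lambda C A^T R (p - A x_k))}
#' where R and C hold the inverse row and column sums of the system weights
#' (rays or voxels with zero weight are excluded) and the clip enforces
#' nonnegative attenuation.  Total-variation denoising can be applied after
#' the iterations (default) or interleaved every \code{tvEvery} iterations.
#'
#' @param projections a line-integral \code{\linkS4class{ProjectionSet}}
#'   (see \code{\link{logNormalize}}), or a plain array matching the system.
#' @param system the \code{\linkS4class{SystemModel}}.
#' @param nIter number of iterations.
#' @param relaxation relaxation factor lambda; SIRT converges for values in
#'   (0, 2), and the near-upper default roughly halves the iterations a
#'   unit step needs.
#' @param tvWeight total-variation weight (0 disables TV).
#' @param tvEvery apply TV every this many iterations (0 = once, after the
#'   loop).
#' @param tvIter inner iterations of the TV solver.
#' @param verbose print the residual every 10 iterations.
#' @return a \code{\linkS4class{ReconVolume}} with the attenuation volume,
#'   iteration count and residual history.
#' @export
sirt <- function(projections, system, nIter = 150L, relaxation = 1.9,
                 tvWeight = 0, tvEvery = 0L, tvIter = 20L, verbose = FALSE) {
  p <- if (is(projections, "ProjectionSet")) {
    if (projections@domain != "lineIntegral")
      stop("projections must be log-normalized to line integrals first")
    projections@data
  } else projections
  if (any(!is.finite(p))) stop("projections contain non-finite values")

  ones <- array(1, dim = system@gridDim)
  rowSum <- forwardProject(system, ones)
  Rw <- ifelse(rowSum > 1e-6, 1 / rowSum, 0)
  p <- p * (rowSum > 1e-6)  # rays outside the system bands carry no data
  colSum <- backProject(system, array(as.numeric(rowSum > 1e-6), dim = dim(rowSum)))
  Cw <- ifelse(colSum > 1e-6, 1 / colSum, 0)

  x <- array(0, dim = system@gridDim)
  res <- numeric(nIter)
  for (k in seq_len(nIter)) {
    r <- p - forwardProject(system, x)
    res[k] <- sqrt(sum(r^2))
    if (k > 1 && res[k] > 10 * res[1])
      stop(sprintf("SIRT diverged at iteration %d (residual %.3g vs initial %.3g)",
                   k, res[k], res[1]))
    x <- x + relaxation * Cw * backProject(system, Rw * r)
    x[x < 0] <- 0
    if (tvWeight > 0 && tvEvery > 0 && k %% tvEvery == 0)
      x <- tvDenoise(x, tvWeight, tvIter)
    if (verbose && k %% 10 == 0)
      message(sprintf("  iter %3d  residual %.4g", k, res[k]))
  }
  if (tvWeight > 0 && tvEvery == 0)
    x <- tvDenoise(x, tvWeight, tvIter)

  new("ReconVolume", mu = x, hu = array(numeric(0), c(0L, 0L, 0L)),
      voxelSize = system@voxelSize, iterations = as.integer(nIter),
      residuals = res,
      provenance = list(relaxation = relaxation, tvWeight = tvWeight,
                        tvEvery = tvEvery, tvIter = tvIter,
                        nFrames = nrow(system@src)))
}

# forward differences with Neumann boundary (last difference zero)
tvGrad <- function(v) {
  d <- dim(v)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[-d[1], , ] <- v[-1, , ] - v[-d[1], , ]
  gy[, -d[2], ] <- v[, -1, ] - v[, -d[2], ]
  gz[, , -d[3]] <- v[, , -1] - v[, , -d[3]]
  list(gx, gy, gz)
}

# negative adjoint of tvGrad
tvDiv <- function(p) {
  d <- dim(p[[1]])
  dv <- array(0, d)
  dv[1, , ] <- p[[1]][1, , ]
  dv[2:(d[1] - 1), , ] <- p[[1]][2:(d[1] - 1), , ] - p[[1]][1:(d[1] - 2), , ]
  dv[d[1], , ] <- -p[[1]][d[1] - 1, , ]
  dv[, 1, ] <- dv[, 1, ] + p[[2]][, 1, ]
  dv[, 2:(d[2] - 1), ] <- dv[, 2:(d[2] - 1), ] +
    p[[2]][, 2:(d[2] - 1), ] - p[[2]][, 1:(d[2] - 2), ]
  dv[, d[2], ] <- dv[, d[2], ] - p[[2]][, d[2] - 1, ]
  dv[, , 1] <- dv[, , 1] + p[[3]][, , 1]
  dv[, , 2:(d[3] - 1)] <- dv[, , 2:(d[3] - 1)] +
    p[[3]][, , 2:(d[3] - 1)] - p[[3]][, , 1:(d[3] - 2)]
  dv[, , d[3]] <- dv[, , d[3]] - p[[3]][, , d[3] - 1]
  dv
}

#' Isotropic total-variation denoising
#'
#' Minimizes \code{0.5 ||x - v||^2 + weight * TV(x)} with Chambolle's
#' dual projected-gradient scheme (isotropic TV, forward differences,
#' Neumann boundaries).  Weight 0 is the identity; a constant volume is a
#' fixed point for any weight.
#'
#' @param volume numeric 3D array.
#' @param weight TV weight (units of the volume values).
#' @param nIter dual iterations.
#' @return denoised array of the same shape.
#' @export
tvDenoise <- function(volume, weight, nIter = 20L) {
  if (weight < 0) stop("weight must be >= 0")
  if (weight == 0) return(volume)
  d <- dim(volume)
  p <- list(array(0, d), array(0, d), array(0, d))
  tau <- 1 / 12  # stable step for the 3D discrete gradient
  for (k in seq_len(nIter)) {
    g <- tvGrad(tvDiv(p) - volume / weight)
    nrm <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
    den <- 1 + tau * nrm
    p <- list((p[[1]] + tau * g[[1]]) / den,
              (p[[2]] + tau * g[[2]]) / den,
              (p[[3]] + tau * g[[3]]) / den)
  }
  volume - weight * tvDiv(p)
}

# cuboid ROI mask given centre (mm, isocenter origin) and half sizes (mm)
roiMask <- function(gridDim, voxelSize, center, halfSize) {
  halfSize <- rep(halfSize, length.out = 3)
  ax <- lapply(1:3, function(a) {
    x <- (seq_len(gridDim[a]) - (gridDim[a] + 1) / 2) * voxelSize
    abs(x - center[a]) <= halfSize[a]
  })
  outer(outer(ax[[1]], ax[[2]], "&"), ax[[3]], "&")
}

#' Calibrate a reconstruction to Hounsfield units
#'
#' Affine calibration from two reference regions, the standard
#' water/air two-point method: the mean attenuation of the water ROI maps
#' to 0 HU and the mean of the air ROI to -1000 HU.
#'
#' @param recon a \code{\linkS4class{ReconVolume}}.
#' @param waterRoi,airRoi either logical masks on the grid or lists
#'   \code{list(center = c(x, y, z), halfSize = h)} in mm (isocenter
#'   origin).
#' @return the \code{\linkS4class{ReconVolume}} with its \code{hu} volume
#'   filled in.
#' @export
calibrateHu <- function(recon, waterRoi, airRoi) {
  toMask <- function(roi) {
    if (is.array(roi) || is.logical(roi)) return(roi)
    roiMask(dim(recon@mu), recon@voxelSize, roi$center, roi$halfSize)
  }
  wm <- toMask(waterRoi); am <- toMask(airRoi)
  if (!any(wm) || !any(am)) stop("empty calibration ROI")
  mw <- mean(recon@mu[wm]); ma <- mean(recon@mu[am])
  if (mw <= ma) stop("degenerate calibration ROIs: mean(water) <= mean(air)")
  recon@hu <- (recon@mu - mw) / (mw - ma) * 1000
  recon@provenance$calibration <- list(method = "two-point", muWaterRoi = mw,
                                       muAirRoi = ma)
  recon
}

#' Calibrate using the nominal water attenuation
#'
#' Linear HU map \code{1000 * (mu / muWater - 1)}; used for phantoms
#' without a water reference region (e.g. the disc stack).
#'
#' @param recon a \code{\linkS4class{ReconVolume}}.
#' @param muWater attenuation of water (mm^-1).
#' @return the calibrated \code{\linkS4class{ReconVolume}}.
#' @export
calibrateHuLinear <- function(recon, muWater = 0.02) {
  recon@hu <- muToHu(recon@mu, muWater)
  recon@provenance$calibration <- list(method = "linear", muWater = muWater)
  recon
}

#' @rdname muVolume
setMethod("muVolume", "ReconVolume", function(object) object@mu)

#' @rdname huVolume
setMethod("huVolume", "ReconVolume", function(object) {
  if (!length(object@hu)) stop("volume is not HU-calibrated yet")
  object@hu
})

#' @rdname voxelSize
setMethod("voxelSize", "ReconVolume", function(object) object@voxelSize)

setMethod("dim", "ReconVolume", function(x) dim(x@mu))

setMethod("show", "ReconVolume", function(object) {
  d <- dim(object@mu)
  cat(sprintf("ReconVolume: %d x %d x %d voxels at %.2f mm, %d iterations\n",
              d[1], d[2], d[3], object@voxelSize, object@iterations))
  cat(sprintf("  final residual %.4g; HU-calibrated: %s\n",
              if (length(object@residuals)) utils::tail(object@residuals, 1) else NA,
              ifelse(length(object@hu) > 0, "yes", "no")))
})
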