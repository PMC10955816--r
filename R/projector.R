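#' @importFrom stats dist
NULL

# Axial (v) coordinate of each detector row centre, mm, panel centre at 0.
vRowCenters <- function(geometry) {
  nv <- detectorPixels(geometry)["nv"]
  (seq_len(nv) - (nv + 1) / 2) * geometry@pixelPitch
}

# Per-row collimation transmission for one source: 1 inside the FWHM band,
# Gaussian penumbra outside it, hard zero below 5% transmission (so the
# support is finite and collimated-out rows carry exactly zero signal).
collimationMask <- function(geometry, sourceIndex) {
  zs <- sourcePositions(geometry)[sourceIndex]
  v <- vRowCenters(geometry)
  h <- geometry@beamFwhm / 2
  s <- geometry@penumbraSigma
  d <- pmax(0, abs(v - zs) - h)
  m <- if (s > 0) exp(-d^2 / (2 * s^2)) else as.numeric(d == 0)
  m[m < 0.05] <- 0
  m
}

# FWHM band and penumbra support rows (1-based, clipped to the panel).
bandRowsFor <- function(geometry, sourceIndex) {
  zs <- sourcePositions(geometry)[sourceIndex]
  v <- vRowCenters(geometry)
  h <- geometry@beamFwhm / 2
  fwhm <- which(abs(v - zs) <= h)
  supp <- which(collimationMask(geometry, sourceIndex) > 0)
  if (!length(supp))
    stop(sprintf("collimated band of source %d falls entirely off the detector",
                 sourceIndex))
  list(band = range(fwhm), support = range(supp))
}

# Frame-wise geometry matrices for the C++ projector: source focal spot,
# panel centre (lateral offset applied), in-plane unit vectors, and the
# 0-based row band traced per frame.  `band` selects which rows carry rays:
# "full" (no collimation), "support" (FWHM plus penumbra; used when
# simulating intensities) or "fwhm" (umbra only; used by the reconstruction
# system model, where penumbra rows carry no tomographic weight).
# `sources` and `angles` have one entry per frame.
frameGeometryMatrices <- function(geometry, sources, angles,
                                  band = c("support", "fwhm", "full")) {
  bandKind <- match.arg(band)
  th <- angles * pi / 180
  zsAll <- sourcePositions(geometry)
  ct <- cos(th); st <- sin(th)
  src <- cbind(-geometry@sid * ct, -geometry@sid * st, zsAll[sources])
  uhat <- cbind(-st, ct, 0)
  vhat <- cbind(0, 0, rep(1, length(th)))
  detc <- cbind((geometry@sdd - geometry@sid) * ct,
                (geometry@sdd - geometry@sid) * st, 0) +
    geometry@lateralOffset * uhat
  nv <- detectorPixels(geometry)["nv"]
  band <- matrix(0L, length(sources), 2)
  for (s in unique(sources)) {
    rows <- switch(bandKind,
                   full = c(1L, nv),
                   support = bandRowsFor(geometry, s)$support,
                   fwhm = bandRowsFor(geometry, s)$band)
    band[sources == s, 1] <- rows[1] - 1L
    band[sources == s, 2] <- rows[2] - 1L
  }
  list(src = src, detc = detc, uhat = uhat, vhat = vhat, band = band)
}

#' Forward-project a phantom onto one detector frame
#'
#' Computes the exact radiological path (integral of mu along the ray from
#' the focal spot to each pixel centre, in mm^-1 * mm) through the voxel
#' grid, for every pixel of the panel.  Collimation is a separate step
#' (\code{\link{applyCollimation}}); the returned frame is uncollimated.
#'
#' @param phantom a \code{\linkS4class{VoxelPhantom}} centred on the
#'   isocenter.
#' @param geometry a \code{\linkS4class{ScannerGeometry}}.
#' @param sourceIndex which focal spot fires (1-based).
#' @param angle gantry angle (degrees).
#' @return a \code{\linkS4class{ProjectionFrame}} in the line-integral
#'   domain.
#' @export
projectFrame <- function(phantom, geometry, sourceIndex, angle) {
  if (sourceIndex < 1L || sourceIndex > geometry@nSources)
    stop("sourceIndex out of range")
  np <- detectorPixels(geometry)
  fg <- frameGeometryMatrices(geometry, sourceIndex, angle, band = "full")
  p <- cpp_project_forward(as.numeric(phantom@mu), dim(phantom@mu),
                           phantom@voxelSize, fg$src, fg$detc, fg$uhat,
                           fg$vhat, np["nu"], np["nv"], geometry@pixelPitch,
                           geometry@pixelPitch, fg$band)
  new("ProjectionFrame", data = matrix(p, np["nu"], np["nv"]),
      domain = "lineIntegral", sourceIndex = as.integer(sourceIndex),
      angle = as.numeric(angle), bandRows = c(NA_integer_, NA_integer_),
      supportRows = c(NA_integer_, NA_integer_),
      maskV = rep(1, np["nv"]))
}

#' Apply the multisource collimator to a frame
#'
#' Restricts the frame to the axial band illuminated by its source: a band
#' of rows of width equal to the beam FWHM at the detector, centred on the
#' source's axial position, with an optional Gaussian penumbra at the edges.
#' Intensity-domain frames are multiplied by the transmission mask;
#' line-integral frames are zeroed outside the support (the penumbra
#' attenuates photons, not path lengths -- it is applied when converting to
#' intensity, where the stored mask is used as the per-row beam profile).
#'
#' @param frame a \code{\linkS4class{ProjectionFrame}}.
#' @param geometry the matching \code{\linkS4class{ScannerGeometry}}.
#' @return the collimated frame with band metadata filled in.
#' @export
applyCollimation <- function(frame, geometry) {
  b <- bandRowsFor(geometry, frame@sourceIndex)
  m <- collimationMask(geometry, frame@sourceIndex)
  d <- frame@data
  if (frame@domain == "intensity") {
    d <- d * rep(m, each = nrow(d))
  } else {
    zero <- m == 0
    d[, zero] <- 0
  }
  initialize(frame, data = d, bandRows = as.integer(b$band),
             supportRows = as.integer(b$support), maskV = m)
}

#' Convert a line-integral frame to detected intensity
#'
#' Beer-Lambert attenuation with the collimation profile as the incident
#' beam: the expected count in pixel (u, v) is
#' \code{i0 * maskV[v] * exp(-p[u, v])}.  With a finite photon budget each
#' pixel is Poisson-sampled, deterministically for a given seed.
#'
#' @param frame a collimated \code{\linkS4class{ProjectionFrame}} in the
#'   line-integral domain.
#' @param i0 reference photons per fully illuminated unattenuated pixel.
#' @param noise logical, Poisson-sample the counts?
#' @param seed integer seed used when \code{noise} is \code{TRUE}.
#' @return an intensity-domain \code{\linkS4class{ProjectionFrame}}.
#' @export
toIntensity <- function(frame, i0, noise = FALSE, seed = NULL) {
  if (i0 < 0) stop("i0 must be >= 0")
  if (frame@domain != "lineIntegral")
    stop("frame is already in the intensity domain")
  expected <- i0 * exp(-frame@data) * rep(frame@maskV, each = nrow(frame@data))
  if (noise) {
    if (is.null(seed)) stop("a seed is required for Poisson sampling")
    set.seed(seed)
    expected[] <- rpois(length(expected), expected)
  }
  initialize(frame, data = expected, domain = "intensity")
}

#' Simulate a full multisource scan
#'
#' Runs the acquisition sequence: at each of \code{nViews} evenly spaced
#' gantry angles every source fires once (step-and-shoot), producing
#' \code{nViews * nSources} collimated intensity frames in (view, source)
#' order.  Scatter, when a \code{\linkS4class{ScatterModel}} is given, is
#' added to the expected primary intensity before Poisson sampling, and the
#' true injected scatter field of every frame is retained for validation.
#' The simulation is bit-reproducible for a given protocol seed.
#'
#' @param phantom a \code{\linkS4class{VoxelPhantom}}.
#' @param geometry a \code{\linkS4class{ScannerGeometry}}.
#' @param protocol an \code{\linkS4class{AcquisitionProtocol}} with
#'   \code{nSources} equal to the geometry's.
#' @param scatter optional \code{\linkS4class{ScatterModel}}.
#' @return a \code{\linkS4class{ProjectionSet}} in the intensity domain.
#' @export
simulateScan <- function(phantom, geometry, protocol, scatter = NULL) {
  if (protocol@nSources != geometry@nSources)
    stop("protocol and geometry disagree on the number of sources")
  np <- detectorPixels(geometry)
  nu <- unname(np["nu"]); nv <- unname(np["nv"])
  ns <- geometry@nSources
  angles <- gantryAngles(protocol)
  nf <- protocol@nViews * ns
  frameSrc <- rep(seq_len(ns), times = protocol@nViews)
  frameAngle <- rep(angles, each = ns)
  frameView <- rep(seq_len(protocol@nViews), each = ns)

  fg <- frameGeometryMatrices(geometry, frameSrc, frameAngle, band = "support")
  p <- cpp_project_forward(as.numeric(phantom@mu), dim(phantom@mu),
                           phantom@voxelSize, fg$src, fg$detc, fg$uhat,
                           fg$vhat, nu, nv, geometry@pixelPitch,
                           geometry@pixelPitch, fg$band)
  p <- array(p, dim = c(nu, nv, nf))

  masks <- vapply(seq_len(ns), function(s) collimationMask(geometry, s),
                  numeric(nv))
  i0 <- if (is.finite(protocol@photonBudget)) protocol@photonBudget else 1

  data <- array(0, dim = c(nu, nv, max(nf, 0L)))
  scat <- if (!is.null(scatter)) array(0, dim = dim(data)) else
    array(0, dim = c(0L, 0L, 0L))
  bands <- lapply(seq_len(ns), function(s) bandRowsFor(geometry, s))
  for (f in seq_len(nf)) {
    s <- frameSrc[f]
    m <- masks[, s]
    prim <- i0 * exp(-p[, , f]) * rep(m, each = nu)
    tot <- prim
    if (!is.null(scatter)) {
      sf <- scatterField(prim, scatter, geometry, s)
      scat[, , f] <- sf
      tot <- prim + sf
    }
    if (is.finite(protocol@photonBudget)) {
      set.seed(deriveSeed(protocol@seed, "noise", f))
      tot[] <- rpois(length(tot), tot)
    }
    data[, , f] <- tot
  }

  fi <- data.frame(
    frame = seq_len(nf), view = frameView, source = frameSrc,
    angle = frameAngle,
    vlo = vapply(frameSrc, function(s) bands[[s]]$support[1], integer(1)),
    vhi = vapply(frameSrc, function(s) bands[[s]]$support[2], integer(1)),
    bandLo = vapply(frameSrc, function(s) bands[[s]]$band[1], integer(1)),
    bandHi = vapply(frameSrc, function(s) bands[[s]]$band[2], integer(1)))

  new("ProjectionSet", data = data, domain = "intensity", frameInfo = fi,
      geometry = geometry, protocol = protocol, i0 = i0, scatterTruth = scat)
}

#' @rdname frameInfo
setMethod("frameInfo", "ProjectionSet", function(object) object@frameInfo)

#' @rdname getFrame
setMethod("getFrame", "ProjectionSet", function(object, i) {
  fi <- object@frameInfo[i, ]
  m <- collimationMask(object@geometry, fi$source)
  new("ProjectionFrame", data = object@data[, , i], domain = object@domain,
      sourceIndex = as.integer(fi$source), angle = fi$angle,
      bandRows = c(fi$bandLo, fi$bandHi),
      supportRows = c(fi$vlo, fi$vhi), maskV = m)
})

setMethod("dim", "ProjectionSet", function(x) dim(x@data))

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProjectionSet: %d frames of %d x %d pixels (%s domain)\n",
              d[3], d[1], d[2], object@domain))
  cat(sprintf("  %d views x %d sources, i0 = %g, scatter truth: %s\n",
              object@protocol@nViews, object@protocol@nSources, object@i0,
              ifelse(length(object@scatterTruth) > 0, "stored", "none")))
})
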