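#' Write a volume as NIfTI with a JSON sidecar
#'
#' Phantoms write their attenuation and truth-HU volumes; reconstructions
#' write attenuation and, when calibrated, HU.  The sidecar records the
#' voxel size, the material table (phantoms) or provenance
#' (reconstructions).
#'
#' @param object a \code{\linkS4class{VoxelPhantom}} or
#'   \code{\linkS4class{ReconVolume}}.
#' @param prefix file path prefix; files \code{<prefix>_mu.nii},
#'   \code{<prefix>_hu.nii} and \code{<prefix>.json} are written.
#' @return invisibly, the paths written.
#' @export
writeVolume <- function(object, prefix) {
  vs <- voxelSize(object)
  paths <- character()
  wr <- function(arr, suffix) {
    path <- paste0(prefix, "_", suffix, ".nii")
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = rep(vs, 3)), path)
    path
  }
  if (is(object, "VoxelPhantom")) {
    paths <- c(paths, wr(object@mu, "mu"), wr(object@truthHu, "hu"))
    side <- list(type = "phantom", voxelSize = vs, dim = dim(object),
                 materials = object@materials)
  } else {
    paths <- c(paths, wr(object@mu, "mu"))
    if (length(object@hu)) paths <- c(paths, wr(object@hu, "hu"))
    side <- list(type = "reconstruction", voxelSize = vs, dim = dim(object),
                 iterations = object@iterations,
                 provenance = object@provenance)
  }
  jp <- paste0(prefix, ".json")
  jsonlite::write_json(side, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, jp))
}

#' Read a NIfTI volume written by \code{\link{writeVolume}}
#'
#' @param prefix the prefix used at write time.
#' @param what \code{"mu"} or \code{"hu"}.
#' @return list with \code{data} (array), \code{voxelSize} and
#'   \code{sidecar}.
#' @export
readVolume <- function(prefix, what = "mu") {
  img <- RNifti::readNifti(paste0(prefix, "_", what, ".nii"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxelSize = side$voxelSize, sidecar = side)
}

#' Write a projection set as multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float page per frame; the sidecar carries the per-frame
#' (view, source, angle, band) table, the reference intensity, the domain
#' and the geometry/protocol parameters needed to rebuild the objects.
#' Scatter-truth fields, when present, go to a second TIFF stack.
#'
#' @param projections a \code{\linkS4class{ProjectionSet}}.
#' @param prefix path prefix; writes \code{<prefix>.tif},
#'   \code{<prefix>_scatter.tif} (optional) and \code{<prefix>.json}.
#' @return invisibly, the paths written.
#' @export
writeProjectionSet <- function(projections, prefix) {
  d <- dim(projections@data)
  # TIFF stores samples in [0, 1]: scale by the stack maximum and record
  # the factor in the sidecar; pages are transposed so u maps to columns
  scale <- max(projections@data, 1e-12)
  pages <- lapply(seq_len(d[3]), function(f) t(projections@data[, , f]) / scale)
  tp <- paste0(prefix, ".tif")
  tiff::writeTIFF(pages, tp, bits.per.sample = 32, reduce = FALSE)
  paths <- tp
  scatterScale <- 1
  if (length(projections@scatterTruth)) {
    sp <- paste0(prefix, "_scatter.tif")
    scatterScale <- max(projections@scatterTruth, 1e-12)
    tiff::writeTIFF(lapply(seq_len(d[3]), function(f)
      t(projections@scatterTruth[, , f]) / scatterScale), sp,
      bits.per.sample = 32)
    paths <- c(paths, sp)
  }
  g <- projections@geometry; p <- projections@protocol
  side <- list(
    domain = projections@domain, i0 = projections@i0, dim = unname(d),
    scale = scale, scatterScale = scatterScale,
    frameInfo = projections@frameInfo,
    geometry = list(nSources = g@nSources, sourcePitch = g@sourcePitch,
                    sdd = g@sdd, sid = g@sid, detWidth = g@detWidth,
                    detHeight = g@detHeight, pixelPitch = g@pixelPitch,
                    lateralOffset = g@lateralOffset, beamFwhm = g@beamFwhm,
                    penumbraSigma = g@penumbraSigma),
    protocol = list(nViews = p@nViews, nSources = p@nSources,
                    tReadout = p@tReadout, tExposure = p@tExposure,
                    tubeCurrent = p@tubeCurrent, doseRate = p@doseRate,
                    angularRange = p@angularRange,
                    photonBudget = if (is.finite(p@photonBudget))
                      p@photonBudget else "Inf",
                    seed = p@seed))
  jp <- paste0(prefix, ".json")
  jsonlite::write_json(side, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, jp))
}

#' Read a projection set written by \code{\link{writeProjectionSet}}
#'
#' Values round-trip at 32-bit float precision.
#'
#' @param prefix the prefix used at write time.
#' @return a \code{\linkS4class{ProjectionSet}}.
#' @export
readProjectionSet <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(side$dim)
  data <- array(0, dim = d)
  for (f in seq_len(d[3])) data[, , f] <- t(pages[[f]]) * side$scale
  scat <- array(0, dim = c(0L, 0L, 0L))
  sp <- paste0(prefix, "_scatter.tif")
  if (file.exists(sp)) {
    spg <- tiff::readTIFF(sp, all = TRUE)
    if (!is.list(spg)) spg <- list(spg)
    scat <- array(0, dim = d)
    for (f in seq_len(d[3])) scat[, , f] <- t(spg[[f]]) * side$scatterScale
  }
  gl <- side$geometry; pl <- side$protocol
  g <- buildGeometry(nSources = gl$nSources, sourcePitch = gl$sourcePitch,
                     sdd = gl$sdd, sid = gl$sid, detWidth = gl$detWidth,
                     detHeight = gl$detHeight, pixelPitch = gl$pixelPitch,
                     lateralOffset = gl$lateralOffset, beamFwhm = gl$beamFwhm,
                     penumbraSigma = gl$penumbraSigma)
  p <- acquisitionProtocol(nViews = pl$nViews, nSources = pl$nSources,
                           tReadout = pl$tReadout, tExposure = pl$tExposure,
                           tubeCurrent = pl$tubeCurrent, doseRate = pl$doseRate,
                           angularRange = pl$angularRange,
                           photonBudget = if (identical(pl$photonBudget, "Inf"))
                             Inf else as.numeric(pl$photonBudget),
                           seed = pl$seed)
  fi <- as.data.frame(side$frameInfo)
  new("ProjectionSet", data = data, domain = side$domain, frameInfo = fi,
      geometry = g, protocol = p, i0 = side$i0, scatterTruth = scat)
}
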