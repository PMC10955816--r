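#' Construct a surrogate scatter model
#'
#' The model is a declared surrogate, not a physical transport model: the
#' scatter field of a frame is a wide Gaussian blur of its primary
#' intensity (scatter is a heavily low-pass-filtered copy of the primary
#' fluence), rescaled so the mean in-band scatter-to-primary ratio (SPR)
#' equals \code{amplitude * bandWidth / axialWidthReference}.  The in-band
#' SPR therefore grows proportionally with the axial beam width -- the
#' physical mechanism that makes a wide-cone acquisition scatter-rich and a
#' narrowly collimated one scatter-poor -- while the blur spreads scatter
#' well beyond the collimated band, which is what the adjacent-band
#' correction exploits.
#'
#' @param kernelSigma Gaussian kernel width at the detector (mm).  The
#'   default (300 mm) makes the field quasi-flat across the panel:
#'   scatter reaching a small flat panel from a large irradiated volume is
#'   dominated by very-low-frequency components, and a quasi-flat field
#'   reproduces the classic scatter phenomenology (cupping, validity of
#'   adjacent-band sampling).
#' @param amplitude mean in-band SPR of a beam as wide as
#'   \code{axialWidthReference}; the default 1 is typical of an
#'   uncorrected wide-cone scan of a 16 cm water cylinder.
#' @param axialWidthReference reference band width (mm); defaults to the
#'   full height of the default detector, so \code{amplitude} is the SPR of
#'   the single-source wide-cone configuration.
#' @return a \code{\linkS4class{ScatterModel}}.
#' @export
scatterModel <- function(kernelSigma = 300, amplitude = 1,
                         axialWidthReference = 113.7) {
  new("ScatterModel", kernelSigma = as.numeric(kernelSigma),
      amplitude = as.numeric(amplitude),
      axialWidthReference = as.numeric(axialWidthReference))
}

# Dense separable Gaussian blur, renormalized per output pixel: the panel is
# small relative to the spatial scale of object scatter, so the field must
# not fall off at the panel edges (the panel samples the interior of a much
# wider distribution).  Frames are small enough for dense operators.
gaussBlurMatrix <- function(n, pitch, sigma) {
  d <- outer(seq_len(n), seq_len(n), "-") * pitch
  w <- exp(-d^2 / (2 * sigma^2))
  w / rowSums(w)
}

# Scatter field for one frame given its expected primary intensity.
scatterField <- function(primary, model, geometry, sourceIndex) {
  if (model@amplitude == 0) return(array(0, dim = dim(primary)))
  b <- bandRowsFor(geometry, sourceIndex)
  bandIdx <- b$band[1]:b$band[2]
  wEff <- length(bandIdx) * geometry@pixelPitch
  nu <- nrow(primary); nv <- ncol(primary)
  Ku <- gaussBlurMatrix(nu, geometry@pixelPitch, model@kernelSigma)
  Kv <- gaussBlurMatrix(nv, geometry@pixelPitch, model@kernelSigma)
  s0 <- Ku %*% primary %*% t(Kv)
  mp <- mean(primary[, bandIdx])
  ms <- mean(s0[, bandIdx])
  if (ms <= 0 || mp <= 0) return(array(0, dim = dim(primary)))
  s0 * (model@amplitude * (wEff / model@axialWidthReference) * mp / ms)
}

#' Inject surrogate scatter into an intensity frame
#'
#' Adds the model's scatter field to a collimated intensity frame and
#' returns both the contaminated frame and the true injected field, so
#' downstream correction can be validated against ground truth.
#'
#' @param frame a collimated intensity-domain
#'   \code{\linkS4class{ProjectionFrame}}.
#' @param model a \code{\linkS4class{ScatterModel}}.
#' @param geometry the matching \code{\linkS4class{ScannerGeometry}}.
#' @return list with elements \code{frame} (contaminated) and
#'   \code{scatter} (the injected field, a matrix).
#' @export
injectScatter <- function(frame, model, geometry) {
  if (frame@domain != "intensity")
    stop("scatter is injected in the intensity domain")
  s <- scatterField(frame@data, model, geometry, frame@sourceIndex)
  list(frame = initialize(frame, data = frame@data + s), scatter = s)
}

#' Mean scatter-to-primary ratio of a simulated scan
#'
#' Computed from the stored ground-truth scatter fields: per frame, the
#' ratio of total scatter to total primary intensity inside the illuminated
#' (FWHM) band, averaged over frames.  The primary is recovered as
#' \code{total - scatter}, which is exact for noiseless simulations.
#'
#' @param projections an intensity-domain \code{\linkS4class{ProjectionSet}}
#'   simulated with a scatter model.
#' @return mean in-band SPR (dimensionless).
#' @export
meanSpr <- function(projections) {
  if (length(projections@scatterTruth) == 0)
    stop("this projection set carries no scatter ground truth")
  fi <- projections@frameInfo
  spr <- vapply(seq_len(nrow(fi)), function(f) {
    rows <- fi$bandLo[f]:fi$bandHi[f]
    s <- sum(projections@scatterTruth[, rows, f])
    p <- sum(projections@data[, rows, f]) - s
    if (p <= 0) NA_real_ else s / p
  }, numeric(1))
  mean(spr, na.rm = TRUE)
}
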