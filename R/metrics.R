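#' Square ROI pixels from an axial slice
#'
#' @param slice numeric matrix (an axial image).
#' @param center integer c(i, j), ROI centre in pixels.
#' @param side ROI side length in pixels.
#' @return numeric vector of the ROI pixels.
#' @export
roiPixels <- function(slice, center, side = 20L) {
  half <- (side - 1) / 2
  ii <- seq.int(round(center[1] - half), round(center[1] + half))
  jj <- seq.int(round(center[2] - half), round(center[2] + half))
  if (min(ii) < 1 || max(ii) > nrow(slice) || min(jj) < 1 || max(jj) > ncol(slice))
    stop("ROI extends beyond the slice")
  as.numeric(slice[ii, jj])
}

#' Default uniformity ROI layout
#'
#' One central ROI plus eight at 60% of the cylinder radius, every 45
#' degrees (the positions are a package convention, recorded with the
#' result); all ROIs are squares of \code{side} pixels.
#'
#' @param sliceDim integer c(n, n), slice size in pixels.
#' @param radiusPx cylinder radius in pixels.
#' @param side ROI side (pixels); 20 pixels equals 10 mm at 0.5 mm pixels.
#' @param angleOffsetDeg rotation of the peripheral ring.
#' @return list of ROI specs \code{list(center, side)}.
#' @export
uniformityRois <- function(sliceDim, radiusPx, side = 20L, angleOffsetDeg = 0) {
  c0 <- (sliceDim + 1) / 2
  ang <- (seq(0, 315, by = 45) + angleOffsetDeg) * pi / 180
  rois <- c(list(list(center = c0, side = side)),
            lapply(ang, function(a)
              list(center = c0 + 0.6 * radiusPx * c(cos(a), sin(a)),
                   side = side)))
  rois
}

#' Hounsfield spatial nonuniformity
#'
#' The standard deviation (n-1 denominator) of the mean HU of nine regions
#' of interest placed on one axial slice.
#'
#' @param slice numeric matrix (HU).
#' @param rois list of exactly 9 ROI specs (\code{list(center, side)}).
#' @return nonuniformity in HU.
#' @export
nonuniformity <- function(slice, rois) {
  if (length(rois) != 9L)
    stop("nonuniformity is defined over exactly 9 ROIs, got ", length(rois))
  means <- vapply(rois, function(r)
    mean(roiPixels(slice, r$center, r$side)), numeric(1))
  stats::sd(means)
}

#' Contrast and contrast-to-noise ratio of an insert
#'
#' Contrast is the absolute HU difference between the insert ROI mean and
#' the mean of its background ROIs; the CNR divides the contrast by the
#' standard deviation of the pooled background pixels.  Using two
#' background ROIs at the same radius as the insert decouples the
#' measurement from any radial (cupping) trend.
#'
#' @param slice numeric matrix (HU).
#' @param insertRoi ROI spec \code{list(center, side)}.
#' @param backgroundRois list of (typically two) background ROI specs.
#' @return list with \code{contrast}, \code{cnr}, \code{insertMean},
#'   \code{backgroundMean}, \code{backgroundSd}.
#' @export
contrastCnr <- function(slice, insertRoi, backgroundRois) {
  ins <- roiPixels(slice, insertRoi$center, insertRoi$side)
  bg <- unlist(lapply(backgroundRois, function(r)
    roiPixels(slice, r$center, r$side)))
  sdBg <- stats::sd(bg)
  contrast <- abs(mean(ins) - mean(bg))
  if (sdBg == 0) {
    if (contrast == 0)
      return(list(contrast = 0, cnr = 0, insertMean = mean(ins),
                  backgroundMean = mean(bg), backgroundSd = 0))
    stop("background standard deviation is zero; CNR undefined")
  }
  list(contrast = contrast, cnr = contrast / sdBg, insertMean = mean(ins),
       backgroundMean = mean(bg), backgroundSd = sdBg)
}

#' Percentage improvement of a metric
#'
#' \code{100 * (new - old) / old}; reported to one decimal in summaries.
#'
#' @param old,new metric values.
#' @return percent change.
#' @export
improvement <- function(old, new) {
  if (any(old == 0)) stop("improvement undefined for a zero baseline")
  100 * (new - old) / old
}

#' Root-mean-square error of HU measurements
#'
#' @param measured,reference per-material mean HU, matched order.
#' @return RMSE in HU.
#' @export
huRmse <- function(measured, reference) {
  if (length(measured) != length(reference))
    stop("measured and reference must have the same length")
  if (!length(measured)) stop("empty input")
  sqrt(mean((measured - reference)^2))
}

#' Axial line profile through a volume
#'
#' @param volume numeric 3D array (HU).
#' @param i,j transaxial voxel indices of the line.
#' @return numeric vector of length \code{dim(volume)[3]}.
#' @export
axialProfile <- function(volume, i, j) {
  d <- dim(volume)
  if (i < 1 || i > d[1] || j < 1 || j > d[2])
    stop("profile line outside the volume")
  volume[i, j, ]
}

#' Modulation depth of an HU profile
#'
#' \code{(max - min) / (max + min + 2000)} over the window: the 2000 HU
#' offset shifts the scale so air is 0 and the ratio stays in [0, 1]; a
#' perfect disc/air alternation gives a value near 1, a constant profile 0.
#'
#' @param profile numeric vector (HU).
#' @param window indices of the profile to evaluate (default: all).
#' @return modulation in [0, 1].
#' @export
modulation <- function(profile, window = seq_along(profile)) {
  if (min(window) < 1 || max(window) > length(profile))
    stop("window outside the profile")
  p <- profile[window]
  (max(p) - min(p)) / (max(p) + min(p) + 2000)
}

#' Effective axial field of view of a uniform-cylinder reconstruction
#'
#' The length of the maximal contiguous axial interval, containing the
#' central slice, over which each slice's in-cylinder mean HU stays within
#' \code{tolerance} of the central slice's mean.  Truncation and cone
#' artefacts push edge slices outside the tolerance, so this operationalizes
#' the usable axial coverage.
#'
#' @param volume numeric 3D array (HU) of a uniform cylinder taller than
#'   the axial FOV.
#' @param voxelSize mm.
#' @param radiusPx transaxial radius (pixels) of the in-cylinder averaging
#'   disc (use ~80% of the cylinder radius to avoid edge voxels).
#' @param tolerance HU.
#' @return effective axial FOV in mm.
#' @export
effectiveAxialFov <- function(volume, voxelSize, radiusPx, tolerance = 50) {
  d <- dim(volume)
  c0 <- (d[1:2] + 1) / 2
  xx <- matrix(seq_len(d[1]), d[1], d[2]) - c0[1]
  yy <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - c0[2]
  diskMask <- xx^2 + yy^2 <= radiusPx^2
  if (!any(diskMask)) stop("empty in-cylinder disc")
  sliceMeans <- vapply(seq_len(d[3]), function(k)
    mean(volume[, , k][diskMask]), numeric(1))
  kc <- ceiling(d[3] / 2)
  ok <- abs(sliceMeans - sliceMeans[kc]) <= tolerance
  if (!ok[kc]) stop("central slice outside its own tolerance (degenerate input)")
  lo <- kc; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- kc; while (hi < d[3] && ok[hi + 1]) hi <- hi + 1
  (hi - lo + 1) * voxelSize
}

# Type-7 style percentile: linear interpolation between order statistics.
percentileInterp <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

#' Nonparametric Bland-Altman agreement statistics
#'
#' For paired per-slice mean HU values of two scanners, returns the median
#' difference and the 2.5th/97.5th percentiles of the differences -- the
#' agreement band used for non-normally distributed data.  Percentiles use
#' linear interpolation between order statistics (recorded in the output).
#'
#' @param valuesA,valuesB equal-length paired measurements.
#' @return list with \code{median}, \code{p2.5}, \code{p97.5}, \code{n},
#'   \code{convention}.
#' @export
blandAltmanNonnormal <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB))
    stop("paired inputs must have equal length")
  if (length(valuesA) < 2) stop("need at least 2 pairs")
  d <- valuesA - valuesB
  list(median = stats::median(d),
       p2.5 = percentileInterp(d, 0.025),
       p97.5 = percentileInterp(d, 0.975),
       n = length(d),
       convention = "linear interpolation between order statistics")
}

#' Threshold segmentation with small-component removal
#'
#' Binary mask of voxels at or above the threshold; connected components
#' (26-connectivity) smaller than \code{minComponent} voxels are removed.
#'
#' @param volume numeric 3D array (calibrated HU).
#' @param threshold HU.
#' @param minComponent minimum component size in voxels (0 keeps all).
#' @return logical array.
#' @export
thresholdSegment <- function(volume, threshold, minComponent = 0L) {
  mask <- volume >= threshold
  if (minComponent > 1L && any(mask)) {
    lab <- cpp_label_components26(as.logical(mask), dim(volume))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= minComponent)
    mask <- array(lab %in% keep, dim = dim(volume))
  }
  mask
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Cupping measure of an axial slice
#'
#' Absolute difference between the central ROI mean and the mean of the
#' eight peripheral ROI means of the standard uniformity layout; scatter
#' depresses the centre of a uniform object, so larger values indicate
#' stronger cupping.
#'
#' @param slice numeric matrix (HU).
#' @param radiusPx cylinder radius in pixels.
#' @param side ROI side (pixels).
#' @return list with \code{cupping} (HU), \code{centerMean},
#'   \code{peripheryMean}.
#' @export
cuppingMeasure <- function(slice, radiusPx, side = 20L) {
  rois <- uniformityRois(dim(slice), radiusPx, side)
  means <- vapply(rois, function(r)
    mean(roiPixels(slice, r$center, r$side)), numeric(1))
  list(cupping = abs(means[1] - mean(means[-1])),
       centerMean = means[1], peripheryMean = mean(means[-1]))
}
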