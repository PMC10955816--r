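#' Parameters of the adjacent scatter ratio subtraction (ASRS)
#'
#' The correction estimates residual scatter in a collimated frame from
#' detector rows just outside the illuminated band: \code{bandRows} rows
#' centred \code{bandOffset} millimetres from the centre of the illuminated
#' area are averaged per detector column to give the adjacent scatter
#' estimate.  The defaults (50 rows, 50 mm) correspond to about a 10 mm
#' sampling band on a 0.198 mm-pitch panel; on coarser simulation grids
#' \code{bandRows} should be scaled to keep the band a few millimetres wide.
#'
#' @param bandOffset distance from the illuminated-band centre to the
#'   sampling-band centre (mm).
#' @param bandRows number of rows averaged in the sampling band.
#' @param spar smoothing parameter of the cubic smoothing spline fitted to
#'   the raw ratio; \code{NA} (default) selects it by generalized
#'   cross-validation.
#' @param ratioClip upper clip applied to the smoothed ratio.
#' @return an \code{\linkS4class{AsrsParams}}.
#' @export
asrsParams <- function(bandOffset = 50, bandRows = 50L, spar = NA_real_,
                       ratioClip = 0.95) {
  new("AsrsParams", bandOffset = as.numeric(bandOffset),
      bandRows = as.integer(bandRows), spar = as.numeric(spar),
      ratioClip = as.numeric(ratioClip))
}

# Sampling rows on one side; NULL (with a reason) if the side is unusable.
samplingRowsSide <- function(centerRow, side, params, pitch, nv, support) {
  offRows <- round(params@bandOffset / pitch)
  c0 <- round(centerRow + ifelse(side == "high", offRows, -offRows))
  half <- (params@bandRows - 1) / 2
  rows <- seq.int(c0 - floor(half), c0 + ceiling(half))
  if (any(rows < 1L) || any(rows > nv))
    return(structure(integer(0), reason = "off-detector"))
  if (any(rows >= support[1] & rows <= support[2]))
    return(structure(integer(0), reason = "overlap"))
  rows
}

#' Measure the raw adjacent scatter ratio of a frame
#'
#' For each detector column u, the adjacent scatter estimate is the mean
#' intensity over the sampling band rows, and the denominator is the mean
#' measured intensity over the illuminated (FWHM) band rows; the raw ratio
#' is their quotient.  When the sampling band fits on both sides of the
#' illuminated band the two sides are averaged; sources near the panel edge
#' use the single available side.
#'
#' @param frame a collimated intensity-domain
#'   \code{\linkS4class{ProjectionFrame}} with band metadata.
#' @param geometry the matching \code{\linkS4class{ScannerGeometry}}.
#' @param params an \code{\linkS4class{AsrsParams}}.
#' @return list with \code{r} (numeric per column), \code{side}
#'   (character vector of sides used) and \code{rows} (sampling rows).
#' @export
measureAdjacentRatio <- function(frame, geometry, params = asrsParams()) {
  if (frame@domain != "intensity")
    stop("the adjacent ratio is measured on intensity frames")
  if (any(is.na(frame@bandRows)))
    stop("frame carries no collimation band; apply collimation first")
  nv <- ncol(frame@data)
  pitch <- geometry@pixelPitch
  center <- mean(frame@bandRows)
  lo <- samplingRowsSide(center, "low", params, pitch, nv, frame@supportRows)
  hi <- samplingRowsSide(center, "high", params, pitch, nv, frame@supportRows)
  sides <- Filter(length, list(low = lo, high = hi))
  if (!length(sides)) {
    reasons <- c(attr(lo, "reason"), attr(hi, "reason"))
    wideBeam <- geometry@beamFwhm >= geometry@detHeight
    if (!wideBeam && "overlap" %in% reasons)
      stop("ASRS configuration error: the sampling band overlaps the ",
           "illuminated band; increase bandOffset or reduce bandRows")
    cond <- simpleError(paste0(
      "ASRS unavailable for source ", frame@sourceIndex,
      ": no adjacent unexposed rows (",
      paste(unique(reasons), collapse = ", "), ")"))
    class(cond) <- c("asrsUnavailableError", class(cond))
    stop(cond)
  }
  denom <- rowMeans(frame@data[, frame@bandRows[1]:frame@bandRows[2], drop = FALSE])
  est <- rowMeans(vapply(sides, function(rows)
    rowMeans(frame@data[, rows, drop = FALSE]), numeric(nrow(frame@data))))
  r <- ifelse(denom > 0, est / denom, NA_real_)
  list(r = r, side = names(sides), rows = sides)
}

#' Smooth the raw adjacent scatter ratio
#'
#' Cubic smoothing spline over detector columns (smoothing chosen by
#' generalized cross-validation unless \code{spar} is fixed), evaluated at
#' every column and clipped to \code{[0, ratioClip]}.  Near-constant input
#' is returned unchanged (a spline reproduces constants).
#'
#' @param r raw per-column ratio (may contain \code{NA}).
#' @param params an \code{\linkS4class{AsrsParams}}.
#' @return smoothed, clipped ratio of the same length.
#' @export
smoothRatio <- function(r, params = asrsParams()) {
  ok <- is.finite(r)
  if (!any(ok)) stop("no finite columns to smooth")
  u <- seq_along(r)
  out <- r
  if (sum(ok) >= 10 && stats::sd(r[ok]) > 1e-12) {
    fit <- if (is.na(params@spar))
      stats::smooth.spline(u[ok], r[ok], cv = FALSE)
    else
      stats::smooth.spline(u[ok], r[ok], spar = params@spar)
    out <- stats::predict(fit, u)$y
  } else {
    out[!ok] <- mean(r[ok])
  }
  pmin(pmax(out, 0), params@ratioClip)
}

#' Correct one frame by adjacent scatter ratio subtraction
#'
#' Multiplies every pixel of the directly illuminated rows by
#' \code{1 - r'(u)}, where \code{r'} is the smoothed adjacent scatter ratio
#' of that column; rows outside the illuminated area are untouched.  When
#' the scatter field is axially flat near the band this returns the true
#' primary exactly.
#'
#' @inheritParams measureAdjacentRatio
#' @return a \code{\linkS4class{CorrectedFrame}}.
#' @export
asrsCorrect <- function(frame, geometry, params = asrsParams()) {
  meas <- measureAdjacentRatio(frame, geometry, params)
  rs <- smoothRatio(meas$r, params)
  d <- frame@data
  rows <- frame@supportRows[1]:frame@supportRows[2]
  d[, rows] <- d[, rows] * (1 - rs)
  new("CorrectedFrame", data = d, domain = frame@domain,
      sourceIndex = frame@sourceIndex, angle = frame@angle,
      bandRows = frame@bandRows, supportRows = frame@supportRows,
      maskV = frame@maskV, rRaw = meas$r, rSmooth = rs, side = meas$side)
}

#' Correct every frame of a projection set
#'
#' Applies \code{\link{asrsCorrect}} frame by frame.  Frames whose sampling
#' band does not fit on the detector are passed through unchanged and
#' flagged in the diagnostics.
#'
#' @param projections an intensity-domain \code{\linkS4class{ProjectionSet}}.
#' @param params an \code{\linkS4class{AsrsParams}}.
#' @return list with \code{projections} (corrected set) and
#'   \code{diagnostics} (per-frame data.frame: mean raw and smoothed ratio,
#'   sides used, corrected flag).
#' @export
asrsCorrectSet <- function(projections, params = asrsParams()) {
  nf <- dim(projections@data)[3]
  out <- projections@data
  diag <- data.frame(frame = seq_len(nf), meanR = NA_real_,
                     meanRSmooth = NA_real_, side = NA_character_,
                     corrected = FALSE)
  for (f in seq_len(nf)) {
    fr <- getFrame(projections, f)
    cf <- tryCatch(asrsCorrect(fr, projections@geometry, params),
                   asrsUnavailableError = function(e) NULL)
    if (is.null(cf)) next
    out[, , f] <- cf@data
    diag$meanR[f] <- mean(cf@rRaw, na.rm = TRUE)
    diag$meanRSmooth[f] <- mean(cf@rSmooth)
    diag$side[f] <- paste(cf@side, collapse = "+")
    diag$corrected[f] <- TRUE
  }
  projections@data <- out
  list(projections = projections, diagnostics = diag)
}

#' Fraction of injected scatter energy removed by a correction
#'
#' Compares a corrected projection set against the ground-truth scatter
#' stored in the original (noiseless) simulation: inside each frame's
#' illuminated band the residual is \code{corrected - primary}; the removal
#' fraction is one minus total absolute residual over total injected
#' scatter.
#'
#' @param original the uncorrected \code{\linkS4class{ProjectionSet}} with
#'   stored scatter truth.
#' @param corrected the corrected set.
#' @return removal fraction in [0, 1] (1 = perfect removal).
#' @export
scatterRemovalFraction <- function(original, corrected) {
  if (length(original@scatterTruth) == 0)
    stop("the original set carries no scatter ground truth")
  fi <- original@frameInfo
  num <- den <- 0
  for (f in seq_len(nrow(fi))) {
    rows <- fi$bandLo[f]:fi$bandHi[f]
    s <- original@scatterTruth[, rows, f]
    prim <- original@data[, rows, f] - s
    num <- num + sum(abs(corrected@data[, rows, f] - prim))
    den <- den + sum(s)
  }
  1 - num / den
}

#' Log-normalize an intensity projection set to line integrals
#'
#' Computes \code{p = -log(I / (i0 * mask))} on the illuminated support of
#' every frame, with intensities clamped at \code{floorFrac * i0} to avoid
#' infinities; pixels outside the collimated support are set to zero (and
#' carry zero weight in reconstruction).
#'
#' @param projections an intensity-domain \code{\linkS4class{ProjectionSet}}.
#' @param floorFrac intensity floor as a fraction of \code{i0}.
#' @return the set in the line-integral domain.
#' @export
logNormalize <- function(projections, floorFrac = 1e-6) {
  if (projections@domain != "intensity")
    stop("projections are not in the intensity domain")
  g <- projections@geometry
  nu <- dim(projections@data)[1]
  masks <- vapply(seq_len(g@nSources), function(s) collimationMask(g, s),
                  numeric(dim(projections@data)[2]))
  out <- projections@data
  i0 <- projections@i0
  for (f in seq_len(dim(out)[3])) {
    m <- masks[, projections@frameInfo$source[f]]
    ref <- i0 * rep(m, each = nu)
    p <- -log(pmax(out[, , f], floorFrac * i0) / pmax(ref, floorFrac * i0))
    p[, m == 0] <- 0
    out[, , f] <- p
  }
  projections@data <- pmax(out, 0)
  projections@domain <- "lineIntegral"
  projections
}
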