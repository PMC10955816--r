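#' Define an acquisition protocol
#'
#' Defaults match the benchtop imaging protocol: 360 views, 8 sources,
#' 11.6 ms readout, 6.5 ms pulses at 15 mA, 1299 uGy/s at the detector.
#'
#' @param nViews gantry positions per scan.
#' @param nSources sources fired per view (must match the geometry used).
#' @param tReadout detector readout time per frame (s).
#' @param tExposure pulse width (s).
#' @param tubeCurrent anode current (mA).
#' @param doseRate dose rate at the detector surface (Gy/s), \code{NA} if
#'   unknown.
#' @param angularRange gantry arc (degrees); views are evenly spaced over it,
#'   starting at 0 and excluding the wrap-around endpoint.
#' @param photonBudget expected photons per unattenuated pixel (\code{Inf}
#'   disables Poisson noise).
#' @param seed integer seed driving every stochastic stage.
#' @return an \code{\linkS4class{AcquisitionProtocol}}.
#' @examples
#' p <- acquisitionProtocol()
#' scanTime(p)            # 52.1 s
#' tubeLoadPerSource(p)   # 35.1 mAs
#' @export
acquisitionProtocol <- function(nViews = 360L, nSources = 8L,
                                tReadout = 11.6e-3, tExposure = 6.5e-3,
                                tubeCurrent = 15, doseRate = 1299e-6,
                                angularRange = 360, photonBudget = Inf,
                                seed = 1L) {
  new("AcquisitionProtocol",
      nViews = as.integer(nViews), nSources = as.integer(nSources),
      tReadout = as.numeric(tReadout), tExposure = as.numeric(tExposure),
      tubeCurrent = as.numeric(tubeCurrent), doseRate = as.numeric(doseRate),
      angularRange = as.numeric(angularRange),
      photonBudget = as.numeric(photonBudget), seed = as.integer(seed))
}

#' Gantry angles of a protocol
#'
#' Strictly increasing, evenly spaced angles spanning the angular range
#' (start inclusive, end exclusive so that 0 and 360 degrees do not repeat).
#'
#' @param protocol an \code{\linkS4class{AcquisitionProtocol}}.
#' @return numeric vector of length \code{nViews} (degrees).
#' @export
gantryAngles <- function(protocol) {
  n <- protocol@nViews
  if (n == 0L) return(numeric())
  seq(0, protocol@angularRange, length.out = n + 1L)[seq_len(n)]
}

#' @rdname scanTime
#' @aliases scanTime,AcquisitionProtocol-method
setMethod("scanTime", "AcquisitionProtocol", function(protocol, ...) {
  validObject(protocol)
  (protocol@tReadout + protocol@tExposure) * protocol@nViews * protocol@nSources
})

#' Illuminated detector area per exposure
#'
#' Detector width times the axial beam FWHM, the area entering the
#' dose-area-product.
#'
#' @param geometry a \code{\linkS4class{ScannerGeometry}}.
#' @return cm^2.
#' @export
illuminatedArea <- function(geometry) {
  geometry@detWidth / 10 * geometry@beamFwhm / 10
}

#' @rdname dap
#' @aliases dap,AcquisitionProtocol,ScannerGeometry-method
setMethod("dap", signature("AcquisitionProtocol", "ScannerGeometry"),
  function(protocol, geometry, ...) {
    validObject(protocol)
    if (is.na(protocol@doseRate))
      stop("dose rate is not available in this protocol; ",
           "set doseRate (Gy/s) to compute a dose-area product")
    protocol@doseRate * protocol@tExposure * illuminatedArea(geometry) *
      protocol@nViews * protocol@nSources
  })

#' @rdname tubeLoadPerSource
#' @aliases tubeLoadPerSource,AcquisitionProtocol-method
setMethod("tubeLoadPerSource", "AcquisitionProtocol", function(protocol, ...) {
  validObject(protocol)
  protocol@tubeCurrent * protocol@tExposure * protocol@nViews
})

#' Dose and timing report for a scanner configuration
#'
#' Pure arithmetic on the protocol: total scan time, dose-area product (in
#' Gy cm^2 and dGy cm^2), per-source tube load, and optionally the dose at
#' the rotation center through a user-supplied conversion factor (mGy per
#' dGy cm^2; the mapping is scanner-specific and is not derived here).
#'
#' @param protocol an \code{\linkS4class{AcquisitionProtocol}}.
#' @param geometry a \code{\linkS4class{ScannerGeometry}}.
#' @param isocenterDosePerDap optional conversion factor (mGy per dGy cm^2).
#' @return a list of class \code{"doseReport"}.
#' @export
doseReport <- function(protocol, geometry, isocenterDosePerDap = NA_real_) {
  d <- if (is.na(protocol@doseRate)) NA_real_ else dap(protocol, geometry)
  out <- list(
    scanTimeS = scanTime(protocol),
    dapGycm2 = d,
    dapDGycm2 = d * 10,
    tubeLoadPerSourceMAs = tubeLoadPerSource(protocol),
    doseAtIsocenterMGy = if (is.na(isocenterDosePerDap) || is.na(d))
      NA_real_ else isocenterDosePerDap * d * 10,
    nFrames = protocol@nViews * protocol@nSources
  )
  class(out) <- "doseReport"
  out
}

#' @export
print.doseReport <- function(x, ...) {
  cat("Scan protocol report\n")
  cat(sprintf("  frames:         %d\n", x$nFrames))
  cat(sprintf("  scan time:      %.1f s\n", x$scanTimeS))
  if (!is.na(x$dapGycm2))
    cat(sprintf("  DAP:            %.3f Gy cm^2 (%.1f dGy cm^2)\n",
                x$dapGycm2, x$dapDGycm2))
  cat(sprintf("  tube load:      %.1f mAs per source\n", x$tubeLoadPerSourceMAs))
  if (!is.na(x$doseAtIsocenterMGy))
    cat(sprintf("  isocenter dose: %.1f mGy\n", x$doseAtIsocenterMGy))
  invisible(x)
}

setMethod("show", "AcquisitionProtocol", function(object) {
  cat(sprintf("AcquisitionProtocol: %d views x %d sources over %.0f deg\n",
              object@nViews, object@nSources, object@angularRange))
  cat(sprintf("  readout %.1f ms, pulse %.1f ms, %.1f mA\n",
              1e3 * object@tReadout, 1e3 * object@tExposure, object@tubeCurrent))
  cat(sprintf("  photon budget %s, seed %d\n",
              ifelse(is.finite(object@photonBudget),
                     format(object@photonBudget), "Inf (noiseless)"),
              object@seed))
})

# One integer stream per (stage, index) derived from the top-level seed, so
# every stochastic stage is independently reproducible.  Kept below 2^31.
deriveSeed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 100003L
  as.integer((as.double(seed) * 7919 + h * 131 + index) %% 2147483629)
}
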