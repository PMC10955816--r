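#' Published benchmark measurements of the prototype scanner
#'
#' Summary measurements reported for the benchtop multisource prototype and
#' its comparators (the same scanner in the single-source wide-cone
#' configuration, a clinical cone-beam scanner and a clinical multidetector
#' CT), shipped with the package so the summary-statistic implementations
#' (\code{\link{huRmse}}, \code{\link{improvement}},
#' \code{\link{scanTime}}, \code{\link{dap}}) can be validated against the
#' published arithmetic.
#'
#' \code{benchmarkHuTable} gives the mean HU of the five contrast-phantom
#' materials per scanner plus the nominal values;
#' \code{benchmarkContrastTable} the insert contrast and CNR of the
#' single-source and multisource configurations;
#' \code{benchmarkUniformity} the reported HU nonuniformity (sd of 9 ROI
#' means); \code{benchmarkProtocol} and \code{benchmarkGeometry} the
#' published acquisition parameters.
#'
#' @return data.frames / objects as described.
#' @name benchmarks
NULL

#' @rdname benchmarks
#' @export
benchmarkHuTable <- function() {
  data.frame(
    material = c("acrylic", "air", "macor", "ldpe", "water"),
    cbct_m = c(160.2, -867.6, 1744.2, -25.8, 87.7),
    n1     = c(66.7, -849.7, 1583.3, -103.3, -27.6),
    ms     = c(87.5, -973.6, 2105.2, -126.3, -11.5),
    mdct   = c(123.8, -1023.3, 2423.3, -119.6, 15.4),
    nominal = c(120, -1000, NA, -95, 0),
    stringsAsFactors = FALSE)
}

#' @rdname benchmarks
#' @export
benchmarkContrastTable <- function() {
  data.frame(
    insert = c("acrylic", "ldpe", "air", "ceramic"),
    contrast_n1 = c(72.1, 100.1, 825.8, 1542.5),
    cnr_n1 = c(1.52, 2.08, 17.70, 28.35),
    contrast_ms = c(89.9, 126.5, 967.7, 2094.3),
    cnr_ms = c(2.34, 2.88, 24.10, 44.25),
    stringsAsFactors = FALSE)
}

#' @rdname benchmarks
#' @export
benchmarkUniformity <- function() {
  c(cbct_m = 38.0, n1 = 38.4, ms = 9.1)
}

#' @rdname benchmarks
#' @export
benchmarkProtocol <- function(seed = 1L) {
  acquisitionProtocol(nViews = 360L, nSources = 8L, tReadout = 11.6e-3,
                      tExposure = 6.5e-3, tubeCurrent = 15,
                      doseRate = 1299e-6, photonBudget = Inf, seed = seed)
}

#' @rdname benchmarks
#' @export
benchmarkGeometry <- function() {
  buildGeometry(nSources = 8L, sourcePitch = 12, sdd = 615, sid = "derive",
                detWidth = 147.3, detHeight = 113.7, pixelPitch = 0.198,
                lateralOffset = 70, beamFwhm = 32.5, penumbraSigma = 1,
                targetFovDiameter = 187)
}
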