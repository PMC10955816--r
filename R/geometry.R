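#' Build a scanner geometry
#'
#' Constructs a \code{\linkS4class{ScannerGeometry}}, optionally deriving the
#' source-to-isocenter distance from a requested transaxial field-of-view
#' diameter.  With a laterally offset panel, the transaxial radius covered at
#' every gantry angle is the far panel edge scaled back to the isocenter,
#' \code{(lateralOffset + detWidth/2) * sid / sdd}; when \code{sid = "derive"}
#' the constructor solves this relation for \code{sid}.
#'
#' Defaults correspond to a benchtop maxillofacial scanner: eight sources at
#' 12 mm pitch, a 147.3 x 113.7 mm panel (0.198 mm binned pixels) shifted by
#' 70 mm, a 615 mm source-to-detector distance and a collimated axial beam
#' FWHM of 32.5 mm at the detector, giving a 187 mm diameter transaxial FOV
#' and about 105 mm of axial coverage.
#'
#' @param nSources number of focal spots.
#' @param sourcePitch axial spacing between focal spots (mm).
#' @param sdd source-to-detector distance (mm).
#' @param sid source-to-isocenter distance (mm), or \code{"derive"} to solve
#'   it from \code{targetFovDiameter}.
#' @param detWidth,detHeight active panel size (mm).
#' @param pixelPitch detector pixel pitch (mm).
#' @param lateralOffset transaxial panel shift (mm).
#' @param beamFwhm axial FWHM of each collimated beam at the detector (mm).
#' @param penumbraSigma Gaussian penumbra width at the band edge (mm).
#' @param targetFovDiameter requested transaxial FOV diameter (mm), used only
#'   when \code{sid = "derive"}.
#' @return a validated \code{\linkS4class{ScannerGeometry}}.
#' @examples
#' g <- buildGeometry()
#' sourcePositions(g)   # {-42, -30, ..., +30, +42}
#' fovDiameter(g)       # ~187 mm
#' @export
buildGeometry <- function(nSources = 8L, sourcePitch = 12,
                          sdd = 615, sid = "derive",
                          detWidth = 147.3, detHeight = 113.7,
                          pixelPitch = 0.198, lateralOffset = 70,
                          beamFwhm = 32.5, penumbraSigma = 1,
                          targetFovDiameter = 187) {
  if (identical(sid, "derive")) {
    reach <- lateralOffset + detWidth / 2
    sid <- targetFovDiameter / 2 * sdd / reach
    if (sid >= sdd) {
      stop(sprintf(
        paste0("requested FOV diameter %.1f mm is infeasible for this ",
               "detector/offset; the maximal achievable diameter is %.1f mm"),
        targetFovDiameter, 2 * reach * (1 - 1e-6)))
    }
  }
  new("ScannerGeometry",
      nSources = as.integer(nSources), sourcePitch = as.numeric(sourcePitch),
      sdd = as.numeric(sdd), sid = as.numeric(sid),
      detWidth = as.numeric(detWidth), detHeight = as.numeric(detHeight),
      pixelPitch = as.numeric(pixelPitch),
      lateralOffset = as.numeric(lateralOffset),
      beamFwhm = as.numeric(beamFwhm),
      penumbraSigma = as.numeric(penumbraSigma))
}

#' @rdname sourcePositions
#' @export
setMethod("sourcePositions", "ScannerGeometry", function(object) {
  n <- object@nSources
  if (n == 1L) return(0)
  (seq_len(n) - (n + 1) / 2) * object@sourcePitch
})

#' Derived geometric quantities
#'
#' \code{coneHalfAngle} is the axial half-opening angle of one collimated
#' beam, \code{atan((beamFwhm/2)/sdd)}, reported in degrees as derived
#' metadata (the collimation masks are driven by the FWHM, not the angle).
#' \code{fovDiameter} is the transaxial diameter covered at all gantry
#' angles by the offset panel; \code{fovAxial} the axial interval covered at
#' the isocenter by the union of all collimated beams (each beam centred on
#' its source's axial plane).
#'
#' @param object a \code{\linkS4class{ScannerGeometry}}.
#' @name derivedGeometry
#' @rdname derivedGeometry
NULL

#' @rdname derivedGeometry
setMethod("coneHalfAngle", "ScannerGeometry", function(object) {
  atan((object@beamFwhm / 2) / object@sdd) * 180 / pi
})

#' @rdname derivedGeometry
setMethod("fovDiameter", "ScannerGeometry", function(object) {
  2 * (object@lateralOffset + object@detWidth / 2) * object@sid / object@sdd
})

#' @rdname derivedGeometry
setMethod("fovAxial", "ScannerGeometry", function(object) {
  m <- object@sid / object@sdd
  span <- (object@nSources - 1) * object@sourcePitch
  # collimated slab height at the isocenter plane, capped by panel height
  slab <- min(object@beamFwhm, object@detHeight) * m
  min(span + slab, object@detHeight * m + span)
})

#' Number of detector pixels
#'
#' @param geometry a \code{\linkS4class{ScannerGeometry}}.
#' @return integer vector \code{c(nu, nv)}: transaxial columns, axial rows.
#' @export
detectorPixels <- function(geometry) {
  c(nu = as.integer(round(geometry@detWidth / geometry@pixelPitch)),
    nv = as.integer(round(geometry@detHeight / geometry@pixelPitch)))
}

#' Degenerate the multisource scanner into a single wide-cone source
#'
#' Returns the conventional cone-beam baseline of the same scanner ("N1"
#' configuration): one source on the scanner mid-plane with the collimation
#' opened so its beam covers the full detector height (a roughly 10 degree
#' cone for the default geometry, against 3 degrees per collimated beam).
#' All other parameters are unchanged, and the operation is idempotent.
#'
#' @param geometry a \code{\linkS4class{ScannerGeometry}}.
#' @param protocol optionally, the matching
#'   \code{\linkS4class{AcquisitionProtocol}}; when supplied, a list with
#'   both degenerate objects is returned (the protocol keeps its timing but
#'   fires one source, so the frame count becomes \code{nViews}).
#' @return the degenerate geometry, or \code{list(geometry, protocol)}.
#' @export
n1Degenerate <- function(geometry, protocol = NULL) {
  g <- geometry
  g@nSources <- 1L
  g@beamFwhm <- g@detHeight
  validObject(g)
  if (is.null(protocol)) return(g)
  p <- protocol
  p@nSources <- 1L
  validObject(p)
  list(geometry = g, protocol = p)
}

setMethod("show", "ScannerGeometry", function(object) {
  cat(sprintf("ScannerGeometry: %d source(s), pitch %.1f mm\n",
              object@nSources, object@sourcePitch))
  cat(sprintf("  SID %.1f mm, SDD %.1f mm, magnification %.2f\n",
              object@sid, object@sdd, object@sdd / object@sid))
  cat(sprintf("  detector %.1f x %.1f mm (%.3f mm pixels), offset %.1f mm\n",
              object@detWidth, object@detHeight, object@pixelPitch,
              object@lateralOffset))
  cat(sprintf("  beam FWHM %.1f mm at detector (half-angle %.2f deg)\n",
              object@beamFwhm, coneHalfAngle(object)))
  cat(sprintf("  FOV: %.1f mm diameter x %.1f mm axial\n",
              fovDiameter(object), fovAxial(object)))
})
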