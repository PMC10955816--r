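#' Scanner geometry of a multisource cone-beam CT system
#'
#' Describes the physical layout of the scanner: an axial array of
#' \code{nSources} focal spots with spacing \code{sourcePitch} on a focal line
#' at distance \code{sid} from the rotation axis, imaged onto a flat-panel
#' detector at distance \code{sdd} from the focal line.  The panel is shifted
#' laterally by \code{lateralOffset} to enlarge the transaxial field of view;
#' each source's beam is collimated to an axial band of full width at half
#' maximum \code{beamFwhm} at the detector surface, with an optional Gaussian
#' penumbra of width \code{penumbraSigma} at the band edges.
#'
#' All lengths are millimetres.  Derived quantities (source axial positions,
#' cone half-angle, transaxial and axial field of view) are available through
#' the accessors \code{\link{sourcePositions}}, \code{\link{coneHalfAngle}},
#' \code{\link{fovDiameter}} and \code{\link{fovAxial}}.
#'
#' @slot nSources integer, number of focal spots (>= 1).
#' @slot sourcePitch numeric, axial spacing between focal spots (mm).
#' @slot sdd numeric, source(focal line)-to-detector distance (mm).
#' @slot sid numeric, source-to-isocenter distance (mm), sid < sdd.
#' @slot detWidth,detHeight numeric, active detector area (mm).
#' @slot pixelPitch numeric, detector pixel pitch after binning (mm).
#' @slot lateralOffset numeric, transaxial shift of the panel centre (mm).
#' @slot beamFwhm numeric, axial FWHM of each collimated beam at the
#'   detector surface (mm).
#' @slot penumbraSigma numeric, Gaussian penumbra width at the collimated
#'   band edges, measured at the detector (mm); 0 gives a hard edge.
#' @export
setClass("ScannerGeometry",
  representation(
    nSources = "integer",
    sourcePitch = "numeric",
    sdd = "numeric",
    sid = "numeric",
    detWidth = "numeric",
    detHeight = "numeric",
    pixelPitch = "numeric",
    lateralOffset = "numeric",
    beamFwhm = "numeric",
    penumbraSigma = "numeric"
  )
)

setValidity("ScannerGeometry", function(object) {
  msg <- character()
  if (length(object@nSources) != 1L || object@nSources < 1L)
    msg <- c(msg, "nSources must be a single integer >= 1")
  if (object@sourcePitch <= 0)
    msg <- c(msg, "sourcePitch must be > 0")
  if (object@sid <= 0 || object@sdd <= 0 || object@sid >= object@sdd)
    msg <- c(msg, "distances must satisfy 0 < sid < sdd")
  if (object@detWidth <= 0 || object@detHeight <= 0 || object@pixelPitch <= 0)
    msg <- c(msg, "detector dimensions and pixel pitch must be > 0")
  if (object@lateralOffset < 0)
    msg <- c(msg, "lateralOffset must be >= 0")
  if (object@beamFwhm <= 0)
    msg <- c(msg, "beamFwhm must be > 0")
  if (object@penumbraSigma < 0)
    msg <- c(msg, "penumbraSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Acquisition protocol
#'
#' Timing, exposure and sampling parameters of one scan.  The scanner fires
#' every source once per gantry position ("view"); the total number of
#' detector frames is \code{nViews * nSources}.  Times are seconds, tube
#' current mA, dose rate Gy/s at the detector surface.  \code{photonBudget}
#' is the expected photon count per detector pixel in an unattenuated,
#' fully illuminated pixel; \code{Inf} disables Poisson noise.
#'
#' @slot nViews integer, number of gantry positions.
#' @slot nSources integer, number of sources fired per view.
#' @slot tReadout numeric, detector readout time per frame (s).
#' @slot tExposure numeric, X-ray pulse width per exposure (s).
#' @slot tubeCurrent numeric, anode current (mA).
#' @slot doseRate numeric, dose rate at the detector surface (Gy/s);
#'   \code{NA} when not characterised.
#' @slot angularRange numeric, gantry arc covered by the views (degrees).
#' @slot photonBudget numeric, photons per unexposed pixel (\code{Inf} =
#'   noiseless).
#' @slot seed integer, base seed for every stochastic stage.
#' @export
setClass("AcquisitionProtocol",
  representation(
    nViews = "integer",
    nSources = "integer",
    tReadout = "numeric",
    tExposure = "numeric",
    tubeCurrent = "numeric",
    doseRate = "numeric",
    angularRange = "numeric",
    photonBudget = "numeric",
    seed = "integer"
  )
)

setValidity("AcquisitionProtocol", function(object) {
  msg <- character()
  if (object@nViews < 0L || object@nSources < 1L)
    msg <- c(msg, "nViews must be >= 0 and nSources >= 1")
  if (object@tReadout < 0 || object@tExposure < 0)
    msg <- c(msg, "timing fields must be >= 0")
  if (object@tubeCurrent < 0)
    msg <- c(msg, "tubeCurrent must be >= 0")
  if (!is.na(object@doseRate) && object@doseRate < 0)
    msg <- c(msg, "doseRate must be >= 0")
  if (object@angularRange <= 0 || object@angularRange > 360)
    msg <- c(msg, "angularRange must be in (0, 360]")
  if (object@photonBudget <= 0)
    msg <- c(msg, "photonBudget must be > 0 (use Inf for noiseless)")
  if (length(msg)) msg else TRUE
})

#' Voxelized digital phantom
#'
#' An isotropic voxel grid centred on the isocenter carrying, per voxel, a
#' material label, the linear attenuation coefficient (mm^-1, fractional on
#' material boundaries through supersampled anti-aliasing) and the nominal
#' Hounsfield value of the labelled material.
#'
#' @slot voxelSize numeric, isotropic voxel edge (mm).
#' @slot labels integer 3D array of material indices into \code{materials}.
#' @slot mu numeric 3D array, linear attenuation (mm^-1).
#' @slot truthHu numeric 3D array, nominal HU of the labelled material.
#' @slot materials data.frame with columns \code{name}, \code{hu}, \code{mu}.
#' @export
setClass("VoxelPhantom",
  representation(
    voxelSize = "numeric",
    labels = "array",
    mu = "array",
    truthHu = "array",
    materials = "data.frame"
  )
)

setValidity("VoxelPhantom", function(object) {
  msg <- character()
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
  if (!identical(dim(object@labels), dim(object@mu)) ||
      !identical(dim(object@labels), dim(object@truthHu)))
    msg <- c(msg, "labels, mu and truthHu must be congruent arrays")
  if (!all(c("name", "hu", "mu") %in% names(object@materials)))
    msg <- c(msg, "materials must have columns name, hu, mu")
  rng <- range(object@labels)
  if (rng[1] < 1L || rng[2] > nrow(object@materials))
    msg <- c(msg, "every label must index the material table")
  if (any(object@mu < 0)) msg <- c(msg, "mu must be >= 0 everywhere")
  if (length(msg)) msg else TRUE
})

#' A single detector frame
#'
#' Pixel grid of one exposure.  The internal matrix is indexed
#' \code{[u, v]}: the first index runs over transaxial detector columns, the
#' second over axial detector rows.  \code{domain} records whether values are
#' radiological path lengths ("lineIntegral") or photon counts ("intensity").
#' \code{bandRows} is the (1-based, inclusive) axial row range illuminated by
#' the collimated beam at full width at half maximum; \code{supportRows} adds
#' the penumbra; \code{maskV} is the per-row collimation transmission in
#' [0, 1].  Uncollimated frames have \code{NA} bands and unit mask.
#'
#' @export
setClass("ProjectionFrame",
  representation(
    data = "matrix",
    domain = "character",
    sourceIndex = "integer",
    angle = "numeric",
    bandRows = "integer",
    supportRows = "integer",
    maskV = "numeric"
  )
)

setValidity("ProjectionFrame", function(object) {
  msg <- character()
  if (!object@domain %in% c("lineIntegral", "intensity"))
    msg <- c(msg, "domain must be 'lineIntegral' or 'intensity'")
  if (any(object@data < 0, na.rm = TRUE))
    msg <- c(msg, "frame values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A frame resulting from adjacent scatter ratio subtraction
#'
#' Extends \code{\linkS4class{ProjectionFrame}} with the raw per-column
#' adjacent scatter ratio \code{rRaw}, its spline-smoothed version
#' \code{rSmooth} and the side(s) of the illuminated band the sampling band
#' was taken from.
#'
#' @export
setClass("CorrectedFrame",
  contains = "ProjectionFrame",
  representation(
    rRaw = "numeric",
    rSmooth = "numeric",
    side = "character"
  )
)

#' Ordered stack of detector frames for a full scan
#'
#' Frames are stored as a \code{nu x nv x nFrames} array in (view, source)
#' lexicographic order: frame index \code{(view - 1) * nSources + source}.
#' \code{frameInfo} tabulates per-frame view, source index, gantry angle and
#' the collimated band; \code{scatterTruth}, when present, holds the injected
#' scatter field of every frame for validation.
#'
#' @slot data numeric array \code{nu x nv x nFrames}.
#' @slot domain character, "intensity" or "lineIntegral".
#' @slot frameInfo data.frame with columns \code{frame}, \code{view},
#'   \code{source}, \code{angle}, \code{vlo}, \code{vhi} (support rows,
#'   1-based), \code{bandLo}, \code{bandHi} (FWHM rows).
#' @slot geometry the \code{\linkS4class{ScannerGeometry}} used.
#' @slot protocol the \code{\linkS4class{AcquisitionProtocol}} used.
#' @slot i0 numeric, reference photon count per fully illuminated pixel.
#' @slot scatterTruth array of injected scatter (same shape as \code{data})
#'   or a 0-length array when no scatter was injected.
#' @export
setClass("ProjectionSet",
  representation(
    data = "array",
    domain = "character",
    frameInfo = "data.frame",
    geometry = "ScannerGeometry",
    protocol = "AcquisitionProtocol",
    i0 = "numeric",
    scatterTruth = "array"
  )
)

setValidity("ProjectionSet", function(object) {
  msg <- character()
  nf <- dim(object@data)[3]
  if (nrow(object@frameInfo) != nf)
    msg <- c(msg, "frameInfo must have one row per frame")
  expected <- object@protocol@nViews * object@protocol@nSources
  if (nf != expected)
    msg <- c(msg, sprintf("frame count (%d) must equal nViews * nSources (%d)",
                          nf, expected))
  if (!object@domain %in% c("lineIntegral", "intensity"))
    msg <- c(msg, "domain must be 'lineIntegral' or 'intensity'")
  if (length(msg)) msg else TRUE
})

#' Surrogate scatter model
#'
#' A deliberately simple, fully declared stand-in for object scatter used to
#' exercise scatter correction and scatter-to-primary-ratio comparisons: the
#' scatter field of a frame is a broad Gaussian blur of its primary intensity,
#' rescaled so that the mean in-band scatter-to-primary ratio equals
#' \code{amplitude * bandWidth / axialWidthReference}.  Wider beams therefore
#' produce proportionally more in-band scatter, and the field extends well
#' beyond the collimated band (the kernel is much wider than the band).
#'
#' @slot kernelSigma numeric, Gaussian kernel width at the detector (mm).
#' @slot amplitude dimensionless coefficient; the mean in-band
#'   scatter-to-primary ratio of a full-height beam.
#' @slot axialWidthReference numeric, band width (mm) at which the in-band
#'   SPR equals \code{amplitude}; defaults to the detector height.
#' @export
setClass("ScatterModel",
  representation(
    kernelSigma = "numeric",
    amplitude = "numeric",
    axialWidthReference = "numeric"
  )
)

setValidity("ScatterModel", function(object) {
  msg <- character()
  if (object@kernelSigma <= 0) msg <- c(msg, "kernelSigma must be > 0")
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@axialWidthReference <= 0)
    msg <- c(msg, "axialWidthReference must be > 0")
  if (length(msg)) msg else TRUE
})

#' Parameters of adjacent scatter ratio subtraction
#'
#' @slot bandOffset numeric, distance (mm) from the centre of the illuminated
#'   band to the centre of the scatter sampling band.
#' @slot bandRows integer, number of detector rows averaged in the sampling
#'   band.
#' @slot spar numeric smoothing parameter passed to the cubic smoothing
#'   spline; \code{NA} selects it by generalized cross-validation.
#' @slot ratioClip numeric, upper clip of the smoothed ratio in [0, 1).
#' @export
setClass("AsrsParams",
  representation(
    bandOffset = "numeric",
    bandRows = "integer",
    spar = "numeric",
    ratioClip = "numeric"
  )
)

setValidity("AsrsParams", function(object) {
  msg <- character()
  if (object@bandOffset <= 0) msg <- c(msg, "bandOffset must be > 0")
  if (object@bandRows < 1L) msg <- c(msg, "bandRows must be >= 1")
  if (object@ratioClip <= 0 || object@ratioClip >= 1)
    msg <- c(msg, "ratioClip must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Matched forward/adjoint system model
#'
#' The single system model covering the rays of every (view, source) frame of
#' a scan; the same operator is used for the multisource and the degenerate
#' single-source configuration.  \code{forwardProject} and
#' \code{backProject} apply the matched operator pair; collimated-out pixels
#' carry zero weight in both directions.
#'
#' @export
setClass("SystemModel",
  representation(
    geometry = "ScannerGeometry",
    frameInfo = "data.frame",
    src = "matrix",
    detc = "matrix",
    uhat = "matrix",
    vhat = "matrix",
    band = "matrix",
    gridDim = "integer",
    voxelSize = "numeric",
    nu = "integer",
    nv = "integer"
  )
)

#' Reconstructed volume
#'
#' @slot mu numeric 3D array, reconstructed attenuation (mm^-1).
#' @slot hu numeric 3D array of calibrated Hounsfield values (filled by
#'   \code{\link{calibrateHu}}; 0-length before calibration).
#' @slot voxelSize numeric (mm).
#' @slot iterations integer, SIRT iterations run.
#' @slot residuals numeric, per-iteration l2 residual of the projection fit.
#' @slot provenance list of reconstruction and calibration parameters.
#' @export
setClass("ReconVolume",
  representation(
    mu = "array",
    hu = "array",
    voxelSize = "numeric",
    iterations = "integer",
    residuals = "numeric",
    provenance = "list"
  )
)

setValidity("ReconVolume", function(object) {
  msg <- character()
  if (any(object@mu < 0)) msg <- c(msg, "mu must be >= 0 (nonnegativity constraint)")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
  if (length(msg)) msg else TRUE
})
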