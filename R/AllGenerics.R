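#' @title Generics
#' @name mscbct-generics
#' @rdname mscbct-generics
#' @keywords internal
NULL

#' Axial positions of the focal spots
#'
#' Positions are symmetric about the scanner mid-plane and span
#' \code{(nSources - 1) * sourcePitch} millimetres.
#'
#' @param object a \code{\linkS4class{ScannerGeometry}}.
#' @return numeric vector of axial positions (mm).
#' @export
setGeneric("sourcePositions", function(object) standardGeneric("sourcePositions"))

#' @export
#' @rdname derivedGeometry
setGeneric("coneHalfAngle", function(object) standardGeneric("coneHalfAngle"))

#' @export
#' @rdname derivedGeometry
setGeneric("fovDiameter", function(object) standardGeneric("fovDiameter"))

#' @export
#' @rdname derivedGeometry
setGeneric("fovAxial", function(object) standardGeneric("fovAxial"))

#' Total scan time of a protocol
#'
#' @param protocol an \code{\linkS4class{AcquisitionProtocol}}.
#' @param ... unused.
#' @return seconds.
#' @export
setGeneric("scanTime", function(protocol, ...) standardGeneric("scanTime"))

#' Dose-area product of a scan
#'
#' @param protocol an \code{\linkS4class{AcquisitionProtocol}} with a known
#'   dose rate.
#' @param geometry a \code{\linkS4class{ScannerGeometry}} providing the
#'   illuminated detector area.
#' @param ... unused.
#' @return DAP in Gy cm^2.
#' @export
setGeneric("dap", function(protocol, geometry, ...) standardGeneric("dap"))

#' Tube load per source
#'
#' @inheritParams scanTime
#' @return mAs delivered by each source over the scan.
#' @export
setGeneric("tubeLoadPerSource", function(protocol, ...) standardGeneric("tubeLoadPerSource"))

#' Attenuation volume of a phantom or reconstruction
#' @param object a \code{\linkS4class{VoxelPhantom}} or
#'   \code{\linkS4class{ReconVolume}}.
#' @return numeric 3D array (mm^-1).
#' @export
setGeneric("muVolume", function(object) standardGeneric("muVolume"))

#' Hounsfield volume of a phantom (nominal truth) or calibrated reconstruction
#' @param object a \code{\linkS4class{VoxelPhantom}} or calibrated
#'   \code{\linkS4class{ReconVolume}}.
#' @return numeric 3D array (HU).
#' @export
setGeneric("huVolume", function(object) standardGeneric("huVolume"))

#' Voxel edge length
#' @param object an object on an isotropic voxel grid.
#' @return mm.
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' Material table of a phantom
#' @param object a \code{\linkS4class{VoxelPhantom}}.
#' @return data.frame with columns \code{name}, \code{hu}, \code{mu}.
#' @export
setGeneric("materials", function(object) standardGeneric("materials"))

#' Frame metadata of a projection stack
#' @param object a \code{\linkS4class{ProjectionSet}} or
#'   \code{\linkS4class{SystemModel}}.
#' @return data.frame, one row per frame.
#' @export
setGeneric("frameInfo", function(object) standardGeneric("frameInfo"))

#' Extract one frame of a projection stack
#' @param object a \code{\linkS4class{ProjectionSet}}.
#' @param i frame index.
#' @return a \code{\linkS4class{ProjectionFrame}}.
#' @export
setGeneric("getFrame", function(object, i) standardGeneric("getFrame"))

#' Apply the system forward model
#' @param system a \code{\linkS4class{SystemModel}}.
#' @param volume numeric 3D array on the system grid.
#' @return numeric array \code{nu x nv x nFrames} of line integrals.
#' @export
setGeneric("forwardProject", function(system, volume) standardGeneric("forwardProject"))

#' Apply the matched adjoint of the system forward model
#' @param system a \code{\linkS4class{SystemModel}}.
#' @param projections numeric array \code{nu x nv x nFrames}.
#' @return numeric 3D array on the system grid.
#' @export
setGeneric("backProject", function(system, projections) standardGeneric("backProject"))
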