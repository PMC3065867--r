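#' Construct an AcquisitionGeometry
#'
#' @param nAngles number of projection angles.
#' @param angularRangeDeg total acquisition arc (degrees).
#' @param orbitRadiusCm detector-face to rotation-axis distance (cm).
#' @param detectorBins transaxial detector bins per row.
#' @param detectorRows axial detector rows.
#' @param binSizeCm detector sampling pitch (cm).
#' @param startAngleDeg gantry angle of the first projection.
#' @return An [AcquisitionGeometry-class].
#' @examples
#' g <- acquisitionGeometry(nAngles = 128, orbitRadiusCm = 24,
#'   detectorBins = 64, detectorRows = 32, binSizeCm = 0.47)
#' head(projectionAngles(g))
#' @export
acquisitionGeometry <- function(nAngles, angularRangeDeg = 360,
    orbitRadiusCm, detectorBins, detectorRows, binSizeCm,
    startAngleDeg = 0) {
  new("AcquisitionGeometry", nAngles = as.integer(nAngles),
    angularRangeDeg = angularRangeDeg, orbitRadiusCm = orbitRadiusCm,
    detectorBins = as.integer(detectorBins),
    detectorRows = as.integer(detectorRows), binSizeCm = binSizeCm,
    startAngleDeg = startAngleDeg)
}

#' @rdname projectionAngles
#' @export
setGeneric("projectionAngles", function(x) standardGeneric("projectionAngles"))

#' Gantry angles of an acquisition
#'
#' Evenly spaced angles over the acquisition arc, end point excluded
#' (a 360-degree, 128-angle orbit steps by 2.8125 degrees).
#'
#' @param x an [AcquisitionGeometry-class] or [ProjectionSet-class].
#' @return numeric vector of gantry angles in degrees.
#' @export
setMethod("projectionAngles", "AcquisitionGeometry", function(x) {
  x@startAngleDeg + (seq_len(x@nAngles) - 1L) * x@angularRangeDeg / x@nAngles
})

#' @rdname projectionAngles
#' @export
setMethod("projectionAngles", "ProjectionSet", function(x) x@anglesDeg)

setMethod("show", "AcquisitionGeometry", function(object) {
  cat(sprintf(
    "AcquisitionGeometry: %d angles / %g deg, orbit %g cm, %d x %d bins @ %g cm\n",
    object@nAngles, object@angularRangeDeg, object@orbitRadiusCm,
    object@detectorBins, object@detectorRows, object@binSizeCm))
})

#' Construct a ProjectionSet
#'
#' @param data 3-D array (bin, row, angle).
#' @param geometry an [AcquisitionGeometry-class].
#' @param anglesDeg per-projection gantry angles; defaults to
#'   [projectionAngles()] of the geometry.
#' @param metadata free-form list.
#' @return A [ProjectionSet-class].
#' @export
projectionSet <- function(data, geometry, anglesDeg = NULL,
    metadata = list()) {
  if (is.null(anglesDeg)) anglesDeg <- projectionAngles(geometry)
  new("ProjectionSet", data = data, geometry = geometry,
    anglesDeg = anglesDeg, metadata = metadata)
}

#' @rdname projectionData
#' @export
setGeneric("projectionData", function(x) standardGeneric("projectionData"))

#' Access projection counts
#'
#' @param x a [ProjectionSet-class].
#' @return 3-D array (bin, row, angle).
#' @export
setMethod("projectionData", "ProjectionSet", function(x) x@data)

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ProjectionSet: %d projections of %d x %d bins, total counts %.6g\n",
    d[3], d[1], d[2], sum(object@data)))
})

#' Construct a CollimatorModel
#'
#' Linear distance-dependent Gaussian PSF,
#' \eqn{\sigma(d) = \sigma_0 + slope \cdot d}. The defaults
#' (\code{sigma0Cm = 0.18}, \code{slope = 0.025}) describe a generic
#' low-energy high-resolution parallel-hole collimator.
#'
#' @param sigma0Cm PSF standard deviation at zero distance (cm).
#' @param slope PSF growth per cm of distance.
#' @param enabled FALSE turns collimator response modelling off (plain
#'   line-integral, "NORR" projection).
#' @return A [CollimatorModel-class].
#' @examples
#' psfSigma(collimatorModel(), d = 24)   # sigma at a 24 cm orbit
#' @export
collimatorModel <- function(sigma0Cm = 0.18, slope = 0.025,
    enabled = TRUE) {
  new("CollimatorModel", sigma0Cm = sigma0Cm, slope = slope,
    enabled = enabled)
}

#' @rdname psfSigma
#' @export
setGeneric("psfSigma", function(x, d) standardGeneric("psfSigma"))

#' PSF standard deviation at a given distance
#'
#' @param x a [CollimatorModel-class].
#' @param d distance(s) from the detector face in cm (>= 0).
#' @return Gaussian sigma in cm, zero when the model is disabled.
#' @export
setMethod("psfSigma", "CollimatorModel", function(x, d) {
  if (!x@enabled) return(rep(0, length(d)))
  x@sigma0Cm + x@slope * pmax(d, 0)
})

setMethod("show", "CollimatorModel", function(object) {
  if (object@enabled)
    cat(sprintf("CollimatorModel: sigma(d) = %g + %g d cm (enabled)\n",
      object@sigma0Cm, object@slope))
  else cat("CollimatorModel: disabled (NORR)\n")
})
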