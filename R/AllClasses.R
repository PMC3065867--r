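#' @import methods
#' @importFrom Matrix sparseMatrix crossprod
#' @importFrom stats rpois median qnorm sd
#' @importFrom utils write.csv packageVersion
#' @useDynLib BayesSPECT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' SpectVolume: a 3-D scalar voxel grid with physical spacing
#'
#' The basic image container of the package. It holds either an activity
#' distribution (counts/voxel or any concentration unit), a linear
#' attenuation map (1/cm), or an anatomical (CT-like) reference image.
#' Voxel data are stored as a numeric \code{array} in (x, y, z) axis order
#' with voxel edge lengths in cm.
#'
#' @slot data 3-D numeric array, axis order (x, y, z).
#' @slot spacing numeric(3), voxel edge lengths in cm (x, y, z); all > 0.
#'
#' @seealso [spectVolume()], [voxelData()], [voxelSpacing()]
#' @export
setClass("SpectVolume",
  representation(data = "array", spacing = "numeric"))

setValidity("SpectVolume", function(object) {
  msg <- NULL
  d <- object@data
  if (length(dim(d)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (!is.numeric(d) || anyNA(d))
    msg <- c(msg, "data must be numeric with no NA")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers (cm)")
  if (!is.null(dim(d)) && any(dim(d) < 1L))
    msg <- c(msg, "grid dimensions must be >= 1 in every axis")
  if (is.null(msg)) TRUE else msg
})

#' AcquisitionGeometry: circular-orbit parallel-beam SPECT geometry
#'
#' Describes a gamma-camera acquisition on a circular orbit: number of
#' projection angles over a total arc, orbit radius (detector face to
#' rotation axis), and the detector sampling grid. The projector assumes
#' parallel-beam collimation, detector bin pitch equal to the in-plane
#' voxel size, and detector rows aligned with the volume's z axis.
#'
#' @slot nAngles number of projection angles (>= 1).
#' @slot angularRangeDeg total acquisition arc in degrees (> 0), e.g. 360.
#' @slot orbitRadiusCm distance from detector face to rotation axis (> 0).
#' @slot detectorBins transaxial bins per detector row.
#' @slot detectorRows axial detector rows.
#' @slot binSizeCm detector sampling pitch in cm (> 0).
#' @slot startAngleDeg gantry angle of the first projection.
#'
#' @seealso [acquisitionGeometry()], [projectionAngles()]
#' @export
setClass("AcquisitionGeometry",
  representation(nAngles = "integer", angularRangeDeg = "numeric",
    orbitRadiusCm = "numeric", detectorBins = "integer",
    detectorRows = "integer", binSizeCm = "numeric",
    startAngleDeg = "numeric"))

setValidity("AcquisitionGeometry", function(object) {
  msg <- NULL
  if (object@nAngles < 1L) msg <- c(msg, "nAngles must be >= 1")
  if (!is.finite(object@angularRangeDeg) || object@angularRangeDeg <= 0)
    msg <- c(msg, "angularRangeDeg must be > 0")
  if (!is.finite(object@orbitRadiusCm) || object@orbitRadiusCm <= 0)
    msg <- c(msg, "orbitRadiusCm must be > 0")
  if (object@detectorBins < 1L || object@detectorRows < 1L)
    msg <- c(msg, "detector grid must be >= 1 in both axes")
  if (!is.finite(object@binSizeCm) || object@binSizeCm <= 0)
    msg <- c(msg, "binSizeCm must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' ProjectionSet: a stack of 2-D projections with acquisition geometry
#'
#' Holds measured or estimated projection data. The data array has axis
#' order (bin, row, angle): \code{data[, , k]} is the 2-D projection
#' acquired at gantry angle \code{anglesDeg[k]}, with transaxial bins along
#' the first axis and axial rows along the second. \code{anglesDeg} must
#' therefore have one entry per slab of the angle (third) axis.
#'
#' @slot data 3-D numeric array (bin, row, angle); non-negative for
#'   measured data.
#' @slot geometry an [AcquisitionGeometry-class].
#' @slot anglesDeg numeric, per-projection gantry angle (degrees).
#' @slot metadata list of free-form metadata (e.g. simulation seed).
#'
#' @seealso [projectionSet()], [forwardProject()], [simulateAcquisition()]
#' @export
setClass("ProjectionSet",
  representation(data = "array", geometry = "AcquisitionGeometry",
    anglesDeg = "numeric", metadata = "list"))

setValidity("ProjectionSet", function(object) {
  msg <- NULL
  d <- object@data
  if (length(dim(d)) != 3L)
    msg <- c(msg, "data must be a 3-D array (bin, row, angle)")
  else {
    if (length(object@anglesDeg) != dim(d)[3L])
      msg <- c(msg, "length(anglesDeg) must equal the angle-axis extent")
    if (dim(d)[1L] != object@geometry@detectorBins ||
        dim(d)[2L] != object@geometry@detectorRows)
      msg <- c(msg, "data bin/row extents must match geometry")
  }
  if (anyNA(d) || any(!is.finite(d)))
    msg <- c(msg, "projection data must be finite")
  if (is.null(msg)) TRUE else msg
})

#' CollimatorModel: distance-dependent Gaussian point-spread function
#'
#' Parameterises the collimator/detector response as an isotropic Gaussian
#' whose standard deviation grows linearly with distance from the detector
#' face: \eqn{\sigma(d) = \sigma_0 + slope \cdot d}. The projector realises
#' this blur by Gaussian diffusion: small incremental convolutions applied
#' plane by plane during the projection sweep. With \code{enabled = FALSE}
#' the projector computes plain attenuated line integrals ("NORR" mode,
#' no resolution recovery).
#'
#' @slot sigma0Cm PSF standard deviation at zero distance (cm, >= 0).
#' @slot slope PSF growth per cm of distance (dimensionless, >= 0).
#' @slot enabled logical; FALSE disables collimator response modelling.
#'
#' @seealso [collimatorModel()], [psfSigma()]
#' @export
setClass("CollimatorModel",
  representation(sigma0Cm = "numeric", slope = "numeric",
    enabled = "logical"))

setValidity("CollimatorModel", function(object) {
  msg <- NULL
  if (!is.finite(object@sigma0Cm) || object@sigma0Cm < 0)
    msg <- c(msg, "sigma0Cm must be >= 0")
  if (!is.finite(object@slope) || object@slope < 0)
    msg <- c(msg, "slope must be >= 0")
  if (length(object@enabled) != 1L || is.na(object@enabled))
    msg <- c(msg, "enabled must be TRUE or FALSE")
  if (is.null(msg)) TRUE else msg
})

#' PriorConfig: Bayesian penalty configuration for one-step-late updates
#'
#' Selects and parameterises the penalty used by the OSL update:
#' \describe{
#'   \item{none}{plain OSEM.}
#'   \item{smooth}{quadratic smoothing prior in relative form; pulls each
#'     voxel toward the inverse-distance-weighted mean of its
#'     neighbourhood.}
#'   \item{mrp}{median root prior; pulls each voxel toward the median of
#'     its neighbourhood window (centre included), preserving locally
#'     monotonic structures.}
#'   \item{bowsher}{anatomically guided smoothing: the local mean is taken
#'     over only the \code{bowsherB} neighbours most similar to the centre
#'     voxel in a co-registered anatomical (CT-like) image, out of the
#'     \code{bowsherScan} nearest neighbours examined.}
#' }
#'
#' @slot priorType one of "none", "smooth", "mrp", "bowsher".
#' @slot beta Bayesian weight (>= 0).
#' @slot neighbourhood odd cubic window edge length (default 3 => 3x3x3,
#'   26 neighbours + centre).
#' @slot bowsherScan number of closest neighbours examined (default 18:
#'   face + edge neighbours of the 3x3x3 cube).
#' @slot bowsherB number of most-similar neighbours kept (default 9).
#' @slot anatomical a grid-matched [SpectVolume-class], required iff
#'   \code{priorType == "bowsher"}; otherwise NULL.
#'
#' @seealso [priorConfig()], [oslUpdate()], [bowsherSelect()]
#' @export
setClass("PriorConfig",
  representation(priorType = "character", beta = "numeric",
    neighbourhood = "integer", bowsherScan = "integer",
    bowsherB = "integer", anatomical = "ANY"))

setValidity("PriorConfig", function(object) {
  msg <- NULL
  if (!object@priorType %in% c("none", "smooth", "mrp", "bowsher"))
    msg <- c(msg, "priorType must be none, smooth, mrp or bowsher")
  if (!is.finite(object@beta) || object@beta < 0)
    msg <- c(msg, "beta must be >= 0")
  w <- object@neighbourhood
  if (w < 1L || w %% 2L == 0L)
    msg <- c(msg, "neighbourhood must be an odd window size")
  nOff <- w^3 - 1L
  if (object@bowsherB > object@bowsherScan || object@bowsherScan > nOff)
    msg <- c(msg,
      "need bowsherB <= bowsherScan <= neighbourhood voxel count - 1")
  if (object@bowsherB < 1L) msg <- c(msg, "bowsherB must be >= 1")
  if (object@priorType == "bowsher" && !is(object@anatomical, "SpectVolume"))
    msg <- c(msg, "bowsher prior requires an anatomical SpectVolume")
  if (is.null(msg)) TRUE else msg
})

#' SubsetScheme: ordered partition of projection angles for OSEM
#'
#' Partitions the angle indices into disjoint subsets processed in an
#' order (bit-reversal of subset index) that maximises angular separation
#' between consecutive sub-iterations.
#'
#' @slot nSubsets number of subsets.
#' @slot subsets list of integer vectors of 1-based angle indices, in
#'   processing order; disjoint and jointly covering all angles.
#'
#' @seealso [makeSubsets()]
#' @export
setClass("SubsetScheme",
  representation(nSubsets = "integer", subsets = "list"))

setValidity("SubsetScheme", function(object) {
  msg <- NULL
  if (object@nSubsets != length(object@subsets))
    msg <- c(msg, "nSubsets must equal length(subsets)")
  if (any(vapply(object@subsets, length, 1L) == 0L))
    msg <- c(msg, "each subset must be non-empty")
  all <- unlist(object@subsets)
  if (anyDuplicated(all))
    msg <- c(msg, "subsets must be disjoint")
  if (length(all) && !setequal(all, seq_len(max(all))))
    msg <- c(msg, "subsets must cover angle indices 1..nAngles completely")
  if (is.null(msg)) TRUE else msg
})

#' ReconConfig: full reconstruction configuration
#'
#' @slot nIterations number of full iterations (each visits every subset).
#' @slot nSubsets number of ordered subsets.
#' @slot prior a [PriorConfig-class].
#' @slot collimator a [CollimatorModel-class].
#' @slot attenuation a [SpectVolume-class] attenuation map (1/cm) or NULL.
#' @slot initialValue positive scalar for the uniform initial estimate, or
#'   NA to use total measured counts / number of voxels.
#' @slot postfilterFwhmCm Gaussian post-filter FWHM in cm (0 = none).
#' @slot epsilon positive stabiliser for divisions.
#'
#' @seealso [reconConfig()], [runReconstruction()]
#' @export
setClass("ReconConfig",
  representation(nIterations = "integer", nSubsets = "integer",
    prior = "PriorConfig", collimator = "CollimatorModel",
    attenuation = "ANY", initialValue = "numeric",
    postfilterFwhmCm = "numeric", epsilon = "numeric"))

setValidity("ReconConfig", function(object) {
  msg <- NULL
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (object@nSubsets < 1L) msg <- c(msg, "nSubsets must be >= 1")
  if (!is.null(object@attenuation) &&
      !is(object@attenuation, "SpectVolume"))
    msg <- c(msg, "attenuation must be a SpectVolume or NULL")
  if (!is.finite(object@epsilon) || object@epsilon <= 0)
    msg <- c(msg, "epsilon must be > 0")
  if (!is.finite(object@postfilterFwhmCm) || object@postfilterFwhmCm < 0)
    msg <- c(msg, "postfilterFwhmCm must be >= 0")
  if (is.null(msg)) TRUE else msg
})
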