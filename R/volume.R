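#' Construct a SpectVolume
#'
#' @param data 3-D numeric array in (x, y, z) axis order. A matrix is
#'   promoted to a single-slice volume.
#' @param spacing voxel edge lengths in cm; scalar (isotropic) or
#'   numeric(3).
#' @return A [SpectVolume-class].
#' @examples
#' v <- spectVolume(array(1, c(4, 4, 2)), spacing = 0.5)
#' dim(voxelData(v))
#' @export
spectVolume <- function(data, spacing = 1) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("SpectVolume", data = data, spacing = as.numeric(spacing))
}

#' @rdname voxelData
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Access the voxel array / spacing of a SpectVolume
#'
#' @param x a [SpectVolume-class].
#' @return \code{voxelData}: the 3-D array; \code{voxelSpacing}: numeric(3)
#'   voxel edge lengths in cm.
#' @export
setMethod("voxelData", "SpectVolume", function(x) x@data)

#' @rdname voxelData
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelData
#' @export
setMethod("voxelSpacing", "SpectVolume", function(x) x@spacing)

setMethod("show", "SpectVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("SpectVolume %d x %d x %d, spacing %.4g x %.4g x %.4g cm\n",
    d[1], d[2], d[3], object@spacing[1], object@spacing[2],
    object@spacing[3]))
  cat(sprintf("  range [%.4g, %.4g], sum %.6g\n",
    min(object@data), max(object@data), sum(object@data)))
})

## internal: new volume with same grid
.likeVolume <- function(vol, data) {
  new("SpectVolume", data = data, spacing = vol@spacing)
}

.sameGrid <- function(a, b) {
  identical(dim(a@data), dim(b@data)) &&
    isTRUE(all.equal(a@spacing, b@spacing, tolerance = 1e-8))
}

.stopIfGridMismatch <- function(a, b, what = "volumes") {
  if (!.sameGrid(a, b))
    stop(what, " must share grid dimensions and spacing", call. = FALSE)
  invisible(TRUE)
}

## Linear attenuation coefficient of water at 140.5 keV (Tc-99m), 1/cm.
MU_WATER_140KEV <- 0.1537

#' Convert a CT-like volume to a linear attenuation map
#'
#' Piecewise-linear ("bilinear") conversion from Hounsfield-like units to
#' linear attenuation coefficients at the emission photon energy, with the
#' breakpoint at water (0 HU): from air (-1000 HU, mu = 0) to water the map
#' is linear up to mu_water(E); above 0 HU the slope is halved to account
#' for the lower effective attenuation of bone-like material per HU at
#' gamma energies. Output is clipped at zero.
#'
#' @param ctVolume a [SpectVolume-class] in Hounsfield-like units.
#' @param photonEnergyKeV emission photon energy; only 140.5 keV (Tc-99m)
#'   has a built-in water coefficient (0.1537/cm); other energies require
#'   \code{muWater}.
#' @param muWater optional override for the water attenuation coefficient
#'   (1/cm) at the photon energy.
#' @return A [SpectVolume-class] attenuation map in 1/cm.
#' @examples
#' ct <- spectVolume(array(c(-1000, -500, 0, 1000), c(4, 1, 1)))
#' voxelData(ctToMu(ct))[, 1, 1]
#' @export
ctToMu <- function(ctVolume, photonEnergyKeV = 140.5, muWater = NULL) {
  hu <- ctVolume@data
  if (any(!is.finite(hu)))
    stop("CT volume contains non-finite values", call. = FALSE)
  if (is.null(muWater)) {
    if (!isTRUE(all.equal(photonEnergyKeV, 140.5, tolerance = 1e-6)))
      stop("supply muWater for photon energies other than 140.5 keV",
        call. = FALSE)
    muWater <- MU_WATER_140KEV
  }
  softSlope <- muWater / 1000          # air (-1000) -> water (0)
  boneSlope <- softSlope * 0.5         # shallower above water
  mu <- ifelse(hu <= 0, muWater + softSlope * hu, muWater + boneSlope * hu)
  mu[mu < 0] <- 0
  .likeVolume(ctVolume, mu)
}

## internal: 1-D unit-sum Gaussian kernel truncated at +-4 sigma (pixels).
## Sampled Gaussians lose variance below ~0.7 px, which would break the
## diffusion semigroup (chained increments must add variances exactly), so
## sub-pixel sigmas use the 3-tap kernel [t, 1-2t, t], t = sigma^2/2, whose
## discrete variance is exactly sigma^2.
.gaussKernel1d <- function(sigmaPx) {
  if (sigmaPx <= 0) return(1)
  if (sigmaPx < 0.7) {
    t <- sigmaPx^2 / 2
    return(c(t, 1 - 2 * t, t))
  }
  r <- max(1L, ceiling(4 * sigmaPx))
  k <- exp(-0.5 * ((-r:r) / sigmaPx)^2)
  k / sum(k)
}

## internal: symmetric band matrix realising zero-padded 1-D convolution
.convMatrix <- function(n, sigmaPx) {
  k <- .gaussKernel1d(sigmaPx)
  if (length(k) == 1L) return(diag(n))
  r <- (length(k) - 1L) / 2L
  m <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    m[cbind(idx[ok], src[ok])] <- k[off + r + 1L]
  }
  m
}

#' Separable 3-D Gaussian smoothing of a volume
#'
#' Gaussian post-filter parameterised by full width at half maximum,
#' \eqn{\sigma = FWHM / (2\sqrt{2\ln 2})}, converted per axis by the voxel
#' spacing. Zero-padded convolution with the kernel truncated at
#' \eqn{\pm 4\sigma} and renormalised to unit sum; \code{fwhmCm = 0} is the
#' identity.
#'
#' @param vol a [SpectVolume-class].
#' @param fwhmCm full width at half maximum in cm (>= 0).
#' @return Smoothed [SpectVolume-class].
#' @export
gaussianPostfilter <- function(vol, fwhmCm) {
  if (!is.finite(fwhmCm) || fwhmCm < 0)
    stop("fwhmCm must be >= 0", call. = FALSE)
  if (fwhmCm == 0) return(vol)
  sigmaCm <- fwhmCm / (2 * sqrt(2 * log(2)))
  d <- dim(vol@data)
  a <- vol@data
  ## axis 1 (x)
  kx <- .convMatrix(d[1], sigmaCm / vol@spacing[1])
  a <- array(kx %*% matrix(a, d[1]), d)
  ## axis 2 (y)
  ky <- .convMatrix(d[2], sigmaCm / vol@spacing[2])
  a <- aperm(array(ky %*% matrix(aperm(a, c(2, 1, 3)), d[2]),
    d[c(2, 1, 3)]), c(2, 1, 3))
  ## axis 3 (z)
  kz <- .convMatrix(d[3], sigmaCm / vol@spacing[3])
  a <- aperm(array(kz %*% matrix(aperm(a, c(3, 1, 2)), d[3]),
    d[c(3, 1, 2)]), c(2, 3, 1))
  .likeVolume(vol, a)
}
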