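## Rotation-based parallel-beam projector.
##
## The system matrix a_ij is realised implicitly, per gantry angle, as
##   A_theta = S * D_theta * R_theta
## where R_theta is a sparse bilinear in-plane rotation (volume rotated so
## the detector is axis-aligned at +y), D_theta the diagonal of per-voxel
## attenuation transmission factors, and S the detector-bound plane sweep
## that interleaves summation with incremental Gaussian blurs (Gaussian
## diffusion).  All three factors have explicit transposes (scatter,
## same diagonal, reversed sweep with the same symmetric kernels), so the
## back-projector is the exact adjoint of the forward projector.

## sparse gather matrix rotating an nx x ny plane CCW by angleDeg about
## its centre; bilinear interpolation, zero fill outside the grid
.rotationMatrix <- function(nx, ny, angleDeg) {
  th <- -angleDeg * pi / 180      # gather: sample source at R(-angle) * t
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  tg <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  sx <- cos(th) * (tg$x - cx) - sin(th) * (tg$y - cy) + cx
  sy <- sin(th) * (tg$x - cx) + cos(th) * (tg$y - cy) + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;   fy <- sy - y0
  tIdx <- rep(seq_len(nx * ny), 4L)
  sxA <- c(x0, x0 + 1, x0, x0 + 1)
  syA <- c(y0, y0, y0 + 1, y0 + 1)
  wA <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  ok <- sxA >= 1 & sxA <= nx & syA >= 1 & syA <= ny & wA > 0
  m <- Matrix::sparseMatrix(i = tIdx[ok], j = sxA[ok] + (syA[ok] - 1L) * nx,
    x = wA[ok], dims = c(nx * ny, nx * ny))
  ## mass preservation: renormalise the total weight each interior source
  ## voxel spreads over the rotated grid to exactly 1, so projection sums
  ## conserve counts; voxels rotating (partly) out of the field keep their
  ## reduced weight (counts leaving the field are lost, not folded back)
  cs <- Matrix::colSums(m)
  sc <- ifelse(cs >= 0.5, 1 / pmax(cs, .Machine$double.eps), 1)
  m %*% Matrix::Diagonal(x = sc)
}

#' Rotate a volume about its axial (z) axis
#'
#' In-plane rotation with bilinear interpolation; the grid shape is
#' preserved and values sampled outside the field fill with zero. This is
#' the rotation the projector applies to align the detector with the grid.
#'
#' @param vol a [SpectVolume-class].
#' @param angleDeg rotation angle in degrees (counter-clockwise in the
#'   (x, y) plane).
#' @return The rotated [SpectVolume-class].
#' @export
rotateVolume <- function(vol, angleDeg) {
  if (!is.finite(angleDeg)) stop("angle must be finite", call. = FALSE)
  d <- dim(vol@data)
  R <- .rotationMatrix(d[1], d[2], angleDeg)
  .likeVolume(vol,
    array(as.numeric(R %*% matrix(vol@data, d[1] * d[2], d[3])), d))
}

#' Per-voxel attenuation transmission factors
#'
#' For a rotated attenuation map with the detector at the +y side, each
#' voxel's transmission is
#' \eqn{\exp(-\Delta (\mu_j/2 + \sum \mu_{between}))}: half the voxel's own
#' attenuation (midpoint correction) plus the full attenuation of every
#' voxel between it and the detector along its projection column,
#' \eqn{\Delta} being the voxel size along y in cm.
#'
#' @param rotatedMu a [SpectVolume-class] attenuation map (1/cm) already
#'   rotated to the detector frame; all values >= 0.
#' @return 3-D array of factors in (0, 1], same dimensions as the input.
#' @export
attenuationFactors <- function(rotatedMu) {
  mu <- rotatedMu@data
  if (any(mu < 0)) stop("attenuation map must be non-negative",
    call. = FALSE)
  dy <- rotatedMu@spacing[2]
  d <- dim(mu)
  ## cumulative attenuation from the detector (+y) side:
  ## exponent = total_column - cumsum_up_to_voxel + mu_voxel / 2
  m <- matrix(aperm(mu, c(2, 1, 3)), d[2], d[1] * d[3])
  cs <- m
  if (d[2] > 1L)
    for (iy in 2:d[2]) cs[iy, ] <- cs[iy - 1L, ] + m[iy, ]
  tot <- rep(cs[d[2], ], each = d[2])
  f <- exp(-dy * (tot - as.numeric(cs) + as.numeric(m) / 2))
  aperm(array(f, d[c(2, 1, 3)]), c(2, 1, 3))
}

#' One incremental Gaussian-diffusion blur
#'
#' Convolves a 2-D plane with an isotropic Gaussian of standard deviation
#' \code{sigmaIncrementCm} (converted to pixels), the primitive the
#' projector chains plane-by-plane so that each plane accumulates the
#' collimator blur of its distance. Zero increment is the identity. The
#' kernel is truncated at \eqn{\pm 4\sigma} and renormalised to unit sum;
#' for sub-pixel sigma a three-tap kernel with exact discrete variance is
#' used so that chained increments accumulate the correct total variance.
#'
#' @param plane 2-D numeric matrix.
#' @param sigmaIncrementCm blur increment in cm (>= 0).
#' @param pixelSizeCm pixel pitch in cm.
#' @return Blurred matrix of the same dimensions.
#' @export
gaussianDiffusionStep <- function(plane, sigmaIncrementCm, pixelSizeCm) {
  if (!is.finite(sigmaIncrementCm) || sigmaIncrementCm < 0)
    stop("sigma increment must be >= 0", call. = FALSE)
  if (sigmaIncrementCm == 0) return(plane)
  s <- sigmaIncrementCm / pixelSizeCm
  kx <- .convMatrix(nrow(plane), s)
  kz <- .convMatrix(ncol(plane), s)
  kx %*% plane %*% kz
}

#' @rdname systemModel
#' @export
setClass("SystemModel",
  representation(geometry = "AcquisitionGeometry",
    collimator = "CollimatorModel", dims = "integer", spacing = "numeric",
    hasMu = "logical", cache = "environment"))

setMethod("show", "SystemModel", function(object) {
  cat(sprintf(
    "SystemModel: %d x %d x %d grid, %d angles, collimator %s, attenuation %s\n",
    object@dims[1], object@dims[2], object@dims[3],
    object@geometry@nAngles,
    if (object@collimator@enabled) "on" else "off (NORR)",
    if (object@hasMu) "on" else "off"))
})

#' Precomputed system model for repeated projection
#'
#' Assembles everything the projector reuses across OSEM sub-iterations:
#' per-angle sparse rotation matrices, per-plane symmetric blur operators
#' realising the Gaussian-diffusion increments, and per-angle attenuation
#' factor grids. [forwardProject()] and [backProject()] accept a
#' \code{SystemModel} to avoid rebuilding these.
#'
#' @param gridDim integer(3) volume dimensions (x, y, z).
#' @param spacing numeric(3) voxel spacing in cm; in-plane spacing must be
#'   isotropic and equal to the detector bin size.
#' @param geometry an [AcquisitionGeometry-class] with
#'   \code{detectorBins == gridDim[1]} and \code{detectorRows == gridDim[3]}.
#' @param collimator a [CollimatorModel-class].
#' @param mu a grid-matched [SpectVolume-class] attenuation map, or NULL.
#' @return A \code{SystemModel} object.
#' @export
systemModel <- function(gridDim, spacing, geometry, collimator,
    mu = NULL) {
  gridDim <- as.integer(gridDim)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (abs(spacing[1] - spacing[2]) > 1e-9 * spacing[1])
    stop("in-plane voxel spacing must be isotropic", call. = FALSE)
  if (geometry@detectorBins != gridDim[1] ||
      geometry@detectorRows != gridDim[3])
    stop("geometry detector grid (", geometry@detectorBins, " x ",
      geometry@detectorRows, ") does not match volume grid (",
      gridDim[1], " x ", gridDim[3], ")", call. = FALSE)
  if (abs(geometry@binSizeCm - spacing[1]) > 1e-9 * spacing[1])
    stop("detector bin size must equal the in-plane voxel size",
      call. = FALSE)
  if (!is.null(mu)) {
    if (!identical(dim(mu@data), gridDim))
      stop("attenuation map grid does not match volume grid",
        call. = FALSE)
    if (any(mu@data < 0))
      stop("attenuation map must be non-negative", call. = FALSE)
  }
  nx <- gridDim[1]; ny <- gridDim[2]; nz <- gridDim[3]
  angles <- projectionAngles(geometry)
  cache <- new.env(parent = emptyenv())
  ## volume is rotated by -gantry angle so the detector sits at +y
  cache$rot <- lapply(angles, function(a) .rotationMatrix(nx, ny, -a))
  ## plane distances from the detector face (iy = 1 farthest)
  dy <- spacing[2]
  yc <- (seq_len(ny) - (ny + 1) / 2) * dy
  dist <- geometry@orbitRadiusCm - yc
  cache$planeDistCm <- dist
  if (collimator@enabled) {
    s2 <- psfSigma(collimator, dist)^2            # cm^2, decreasing in iy
    inc2 <- c(s2[-ny] - s2[-1], s2[ny])
    inc2[inc2 < 0] <- 0                           # guard fp rounding
    sIncPx <- sqrt(inc2) / spacing[1]
    cache$kx <- lapply(sIncPx, function(s)
      if (s < 1e-8) NULL else .convMatrix(nx, s))
    cache$kz <- lapply(sqrt(inc2) / spacing[3], function(s)
      if (s < 1e-8) NULL else .convMatrix(nz, s))
  }
  if (!is.null(mu)) {
    rmu <- mu
    cache$att <- lapply(seq_along(angles), function(k) {
      rot <- .likeVolume(mu, array(
        as.numeric(cache$rot[[k]] %*% matrix(mu@data, nx * ny, nz)),
        gridDim))
      attenuationFactors(rot)
    })
  }
  new("SystemModel", geometry = geometry, collimator = collimator,
    dims = gridDim, spacing = as.numeric(spacing), hasMu = !is.null(mu),
    cache = cache)
}

## forward sweep for one angle: rotated activity array -> nx x nz plane
.sweepForward <- function(model, rotArr, k) {
  d <- model@dims
  att <- if (model@hasMu) model@cache$att[[k]] else NULL
  blur <- model@collimator@enabled
  acc <- matrix(0, d[1], d[3])
  for (iy in seq_len(d[2])) {
    plane <- rotArr[, iy, , drop = TRUE]
    if (d[3] == 1L) plane <- matrix(plane, d[1], 1L)
    if (!is.null(att)) {
      a <- att[, iy, , drop = TRUE]
      if (d[3] == 1L) a <- matrix(a, d[1], 1L)
      plane <- plane * a
    }
    acc <- acc + plane
    if (blur) {
      kx <- model@cache$kx[[iy]]
      kz <- model@cache$kz[[iy]]
      if (!is.null(kx)) acc <- kx %*% acc
      if (!is.null(kz)) acc <- acc %*% kz
    }
  }
  acc
}

## adjoint sweep for one angle: nx x nz plane -> rotated-frame volume array
.sweepBack <- function(model, plane, k) {
  d <- model@dims
  att <- if (model@hasMu) model@cache$att[[k]] else NULL
  blur <- model@collimator@enabled
  out <- array(0, d)
  t <- plane
  for (iy in rev(seq_len(d[2]))) {
    if (blur) {
      kx <- model@cache$kx[[iy]]
      kz <- model@cache$kz[[iy]]
      if (!is.null(kx)) t <- kx %*% t        # symmetric => self-adjoint
      if (!is.null(kz)) t <- t %*% kz
    }
    if (!is.null(att)) {
      a <- att[, iy, , drop = TRUE]
      if (d[3] == 1L) a <- matrix(a, d[1], 1L)
      out[, iy, ] <- t * a
    } else out[, iy, ] <- as.matrix(t)
  }
  out
}

## array-level forward projection over a set of angle indices
.forwardArr <- function(model, fArr, angleIdx) {
  d <- model@dims
  p <- array(0, c(d[1], d[3], length(angleIdx)))
  fm <- matrix(fArr, d[1] * d[2], d[3])
  for (j in seq_along(angleIdx)) {
    k <- angleIdx[j]
    rotArr <- array(as.numeric(model@cache$rot[[k]] %*% fm), d)
    p[, , j] <- as.matrix(.sweepForward(model, rotArr, k))
  }
  p
}

## array-level back projection (exact adjoint of .forwardArr)
.backArr <- function(model, pArr, angleIdx) {
  d <- model@dims
  out <- matrix(0, d[1] * d[2], d[3])
  for (j in seq_along(angleIdx)) {
    k <- angleIdx[j]
    v <- .sweepBack(model, matrix(pArr[, , j], d[1], d[3]), k)
    out <- out + as.matrix(Matrix::crossprod(model@cache$rot[[k]],
      matrix(v, d[1] * d[2], d[3])))
  }
  array(out, d)
}

#' Forward project an activity volume
#'
#' Computes expected projections \eqn{\sum_k a_{ik} f_k} for every gantry
#' angle: the volume is rotated so the detector is axis-aligned, voxels
#' are attenuated by their transmission factors, and planes are swept from
#' farthest to nearest the detector with incremental Gaussian-diffusion
#' blurs so that each plane receives the collimator blur
#' \eqn{\sigma(d)} of its distance. With the collimator disabled and no
#' attenuation map this reduces to plain summed line integrals.
#'
#' @param activity a [SpectVolume-class]; values in counts/voxel.
#' @param geometry an [AcquisitionGeometry-class] (ignored when
#'   \code{model} is given).
#' @param collimator a [CollimatorModel-class] (ignored when \code{model}
#'   is given).
#' @param mu optional grid-matched attenuation [SpectVolume-class]
#'   (ignored when \code{model} is given).
#' @param model optional precomputed [systemModel()]; supply it when
#'   projecting repeatedly.
#' @return A [ProjectionSet-class] of expected counts.
#' @export
forwardProject <- function(activity, geometry = NULL, collimator = NULL,
    mu = NULL, model = NULL) {
  if (is.null(model)) {
    if (!is.null(mu)) .stopIfGridMismatch(activity, mu,
      "activity and attenuation map")
    model <- systemModel(dim(activity@data), activity@spacing, geometry,
      collimator, mu)
  } else if (!identical(dim(activity@data), model@dims))
    stop("activity grid does not match system model", call. = FALSE)
  p <- .forwardArr(model, activity@data,
    seq_len(model@geometry@nAngles))
  projectionSet(p, model@geometry)
}

#' Back project projections into the volume
#'
#' Exact adjoint (transpose) of [forwardProject()] restricted to a subset
#' of angles: \eqn{\sum_{i \in S} a_{ij} y_i}. Back projecting all-ones
#' projections yields the per-voxel sensitivity image
#' \eqn{\sum_{i \in S} a_{ij}}.
#'
#' @inheritParams forwardProject
#' @param proj a [ProjectionSet-class].
#' @param subset integer vector of 1-based angle indices; default all.
#' @return A [SpectVolume-class].
#' @export
backProject <- function(proj, geometry = NULL, collimator = NULL,
    mu = NULL, subset = NULL, model = NULL) {
  if (is.null(model)) {
    gd <- c(proj@geometry@detectorBins, proj@geometry@detectorBins,
      proj@geometry@detectorRows)
    sp <- rep(proj@geometry@binSizeCm, 3L)
    if (!is.null(mu)) { gd <- dim(mu@data); sp <- mu@spacing }
    model <- systemModel(gd, sp, proj@geometry, collimator, mu)
  }
  if (is.null(subset)) subset <- seq_len(model@geometry@nAngles)
  subset <- as.integer(subset)
  if (length(subset) == 0L)
    stop("subset must be non-empty", call. = FALSE)
  if (any(subset < 1L | subset > model@geometry@nAngles))
    stop("subset contains invalid angle indices", call. = FALSE)
  out <- .backArr(model, proj@data[, , subset, drop = FALSE], subset)
  new("SpectVolume", data = out, spacing = model@spacing)
}
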