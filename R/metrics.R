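## Evaluation of reconstructed phantoms: concentric-ROI contrast, line
## profiles with theoretical overlays, and a ringing (centre-dip) index
## quantifying the two-peaked profile artefact of collimator correction.

#' Concentric circular ROI pair around a sphere
#'
#' The inner disc samples the hot sphere on its central axial slice; the
#' non-overlapping annulus between the inner and outer circles samples the
#' local background. Voxel membership is decided by voxel centre in
#' circle, so the masks depend only on the geometry and are identical for
#' every reconstruction evaluated with them.
#'
#' @param centreCm sphere centre (x, y, z) in cm, centred coordinates.
#' @param innerRadiusCm inner (sphere) ROI radius, cm.
#' @param outerRadiusCm outer radius; the background annulus runs from
#'   \code{backgroundInnerRadiusCm} to \code{outerRadiusCm}.
#' @param backgroundInnerRadiusCm inner edge of the background annulus;
#'   defaults to \code{innerRadiusCm} (purely concentric ROIs). Set it
#'   beyond the true sphere radius so the background clears the object.
#' @param sphereId optional label carried into results.
#' @return A list of class \code{"roiPair"}.
#' @export
roiPair <- function(centreCm, innerRadiusCm, outerRadiusCm,
    backgroundInnerRadiusCm = innerRadiusCm, sphereId = NA) {
  if (!(innerRadiusCm > 0 && outerRadiusCm > innerRadiusCm))
    stop("need 0 < innerRadiusCm < outerRadiusCm", call. = FALSE)
  if (backgroundInnerRadiusCm < innerRadiusCm ||
      backgroundInnerRadiusCm >= outerRadiusCm)
    stop("backgroundInnerRadiusCm must lie in [inner, outer)",
      call. = FALSE)
  structure(list(centreCm = centreCm, innerRadiusCm = innerRadiusCm,
    outerRadiusCm = outerRadiusCm,
    backgroundInnerRadiusCm = backgroundInnerRadiusCm,
    sphereId = sphereId), class = "roiPair")
}

## inner / annulus voxel index masks on the slice through the ROI centre
.roiMasks <- function(gridDim, spacing, roi) {
  xs <- .axisCoords(gridDim[1], spacing[1])
  ys <- .axisCoords(gridDim[2], spacing[2])
  zs <- .axisCoords(gridDim[3], spacing[3])
  iz <- which.min(abs(zs - roi$centreCm[3]))
  r2 <- outer((xs - roi$centreCm[1])^2, (ys - roi$centreCm[2])^2, "+")
  bgIn <- roi$backgroundInnerRadiusCm %||% roi$innerRadiusCm
  inner <- which(r2 <= roi$innerRadiusCm^2)
  annulus <- which(r2 > bgIn^2 & r2 <= roi$outerRadiusCm^2)
  list(slice = iz, inner = inner, annulus = annulus)
}

#' Contrast from a concentric ROI pair
#'
#' \deqn{C = (A_{sph} - A_{bg}) / (A_{sph} + A_{bg})}
#' with \eqn{A_{sph}} the mean over the inner disc and \eqn{A_{bg}} the
#' mean over the annulus, both on the slice through the ROI centre.
#' Reported as a fraction in [-1, 1]; multiply by 100 for percent.
#'
#' @param vol a [SpectVolume-class].
#' @param roi a [roiPair()].
#' @return One-row data.frame: \code{sphereId}, \code{aSph}, \code{aBg},
#'   \code{contrast}.
#' @export
computeContrast <- function(vol, roi) {
  m <- .roiMasks(dim(vol@data), vol@spacing, roi)
  if (length(m$inner) == 0L || length(m$annulus) == 0L)
    stop("empty ROI: radii too small for the voxel grid", call. = FALSE)
  slice <- vol@data[, , m$slice]
  aSph <- mean(slice[m$inner])
  aBg <- mean(slice[m$annulus])
  denom <- aSph + aBg
  data.frame(sphereId = roi$sphereId, aSph = aSph, aBg = aBg,
    contrast = if (denom == 0) 0 else (aSph - aBg) / denom)
}

## trilinear interpolation at physical points (cm, centred coordinates);
## points outside the grid return NA
.trilinear <- function(arr, spacing, pts) {
  d <- dim(arr)
  ## continuous voxel index of a physical coordinate
  gx <- pts[, 1] / spacing[1] + (d[1] + 1) / 2
  gy <- pts[, 2] / spacing[2] + (d[2] + 1) / 2
  gz <- pts[, 3] / spacing[3] + (d[3] + 1) / 2
  out <- rep(NA_real_, nrow(pts))
  ok <- gx >= 1 & gx <= d[1] & gy >= 1 & gy <= d[2] &
    gz >= 1 & gz <= d[3]
  if (!any(ok)) return(out)
  x0 <- pmin(floor(gx[ok]), d[1] - 1); fx <- gx[ok] - x0
  y0 <- pmin(floor(gy[ok]), d[2] - 1); fy <- gy[ok] - y0
  z0 <- pmin(floor(gz[ok]), d[3] - 1); fz <- gz[ok] - z0
  idx <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * idx(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * idx(x0 + 1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * idx(x0, y0 + 1, z0) +
    fx * fy * (1 - fz) * idx(x0 + 1, y0 + 1, z0) +
    (1 - fx) * (1 - fy) * fz * idx(x0, y0, z0 + 1) +
    fx * (1 - fy) * fz * idx(x0 + 1, y0, z0 + 1) +
    (1 - fx) * fy * fz * idx(x0, y0 + 1, z0 + 1) +
    fx * fy * fz * idx(x0 + 1, y0 + 1, z0 + 1)
  out[ok] <- v
  out
}

#' Extract a line profile through a volume
#'
#' Samples the volume by trilinear interpolation at uniform steps along a
#' line through \code{centreCm}. When the true sphere radius is supplied,
#' a theoretical top-hat profile (the sphere indicator along the same
#' line, scaled to the maximum of the measured profile) is attached — the
#' usual overlay for judging ringing against the actual insert shape.
#' Samples falling outside the volume are dropped with a warning.
#'
#' @param vol a [SpectVolume-class].
#' @param centreCm line centre (x, y, z) in cm.
#' @param direction direction vector (normalised internally).
#' @param halfLengthCm half-length of the sampled segment (cm).
#' @param stepCm sample spacing (cm); default half the voxel size.
#' @param trueRadiusCm optional true object radius for the theoretical
#'   overlay.
#' @return A data.frame of class \code{"spectProfile"} with columns
#'   \code{position} (signed cm from the centre), \code{value} and
#'   (when available) \code{theoretical}.
#' @export
extractProfile <- function(vol, centreCm, direction = c(1, 0, 0),
    halfLengthCm, stepCm = NULL, trueRadiusCm = NULL) {
  if (is.null(stepCm)) stepCm <- min(vol@spacing) / 2
  u <- direction / sqrt(sum(direction^2))
  ## symmetric sampling about the centre regardless of step/length ratio
  half <- seq(0, halfLengthCm, by = stepCm)
  pos <- c(-rev(half[-1]), half)
  pts <- cbind(centreCm[1] + pos * u[1], centreCm[2] + pos * u[2],
    centreCm[3] + pos * u[3])
  v <- .trilinear(vol@data, vol@spacing, pts)
  if (anyNA(v)) {
    warning("profile line exits the volume; truncating", call. = FALSE)
    keep <- !is.na(v)
    pos <- pos[keep]; v <- v[keep]
  }
  out <- data.frame(position = pos, value = v)
  if (!is.null(trueRadiusCm))
    out$theoretical <- ifelse(abs(pos) <= trueRadiusCm,
      max(v), 0)
  class(out) <- c("spectProfile", "data.frame")
  out
}

#' Ringing (centre-dip) index of a sphere profile
#'
#' Quantifies the two-peaked "hole in the middle" artefact that
#' collimator correction can carve into hot spheres:
#' \deqn{index = \max(0, (P_{edge} - P_{centre}) / P_{edge})}
#' where \eqn{P_{centre}} is the mean of samples within 20% of the object
#' half-width around the centre, and \eqn{P_{edge}} the mean of the left
#' and right maxima inside the object but outside the centre window
#' (excluding the centre window makes every centrally-peaked monotone
#' profile score exactly 0). 0 means no central dip; values near 1 a
#' deep hole.
#'
#' @param profile a data.frame from [extractProfile()].
#' @param objectHalfWidthCm true object half-width (radius) in cm.
#' @return scalar in [0, 1].
#' @export
ringingIndex <- function(profile, objectHalfWidthCm) {
  pos <- profile$position
  val <- profile$value
  if (all(val == 0)) {
    warning("degenerate all-zero profile; ringing index 0",
      call. = FALSE)
    return(0)
  }
  if (max(abs(pos)) < objectHalfWidthCm)
    stop("profile does not span the object", call. = FALSE)
  w <- 0.2 * objectHalfWidthCm
  centre <- val[abs(pos) <= w]
  left <- val[pos >= -objectHalfWidthCm & pos < -w]
  right <- val[pos > w & pos <= objectHalfWidthCm]
  if (!length(centre) || !length(left) || !length(right))
    stop("profile sampling too coarse for the object width",
      call. = FALSE)
  pCentre <- mean(centre)
  pEdge <- mean(c(max(left), max(right)))
  if (pEdge <= 0) return(0)
  max(0, (pEdge - pCentre) / pEdge)
}

#' Evaluate a set of reconstructions of one phantom
#'
#' Computes, for every labelled reconstruction: the concentric-ROI
#' contrast of the \code{nSpheres} largest spheres (identical ROI masks
#' across volumes), the ringing index of the largest sphere's profile,
#' and optionally the coefficient of variation inside a uniform ROI.
#'
#' @param volumes named list of grid-matched [SpectVolume-class] objects
#'   (one per reconstruction method).
#' @param geometry truth geometry data.frame from the phantom builders
#'   (columns id, x, y, z, diameterMm, largest first).
#' @param nSpheres number of largest spheres to measure.
#' @param innerFraction inner ROI radius as a fraction of the true sphere
#'   radius.
#' @param outerFraction outer ROI radius as a fraction of the true radius.
#' @param backgroundInnerFraction inner edge of the background annulus as
#'   a fraction of the true radius; > 1 so the background clears the
#'   sphere and a noise-free truth volume scores contrast exactly 1.
#' @param profileStepCm profile sampling step; default half a voxel.
#' @param covRoi optional [roiPair()] defining a uniform region; its inner
#'   disc is used for the coefficient of variation (NA when omitted).
#' @return A data.frame with one row per method x sphere: method,
#'   sphereId, diameterMm, aSph, aBg, contrast, plus the per-method
#'   ringingLargest and covUniform repeated on each row.
#' @export
evaluateStudy <- function(volumes, geometry, nSpheres = 4,
    innerFraction = 0.8, outerFraction = 1.6,
    backgroundInnerFraction = 1.2, profileStepCm = NULL,
    covRoi = NULL) {
  if (is.null(names(volumes)) || any(names(volumes) == ""))
    stop("volumes must be a named list (one label per method)",
      call. = FALSE)
  if (anyDuplicated(names(volumes)))
    stop("method labels must be unique", call. = FALSE)
  ref <- volumes[[1]]
  for (v in volumes) .stopIfGridMismatch(ref, v, "reconstruction volumes")
  geometry <- geometry[order(-geometry$diameterMm), , drop = FALSE]
  nSpheres <- min(nSpheres, nrow(geometry))
  rois <- lapply(seq_len(nSpheres), function(i) {
    r <- geometry$diameterMm[i] / 20
    roiPair(c(geometry$x[i], geometry$y[i], geometry$z[i]),
      innerFraction * r, outerFraction * r,
      backgroundInnerRadiusCm = backgroundInnerFraction * r,
      sphereId = geometry$id[i])
  })
  largest <- geometry[1, ]
  largestR <- largest$diameterMm / 20
  rows <- lapply(names(volumes), function(mth) {
    vol <- volumes[[mth]]
    cs <- do.call(rbind, lapply(rois, function(roi)
      computeContrast(vol, roi)))
    prof <- extractProfile(vol,
      c(largest$x, largest$y, largest$z), c(1, 0, 0),
      halfLengthCm = 2 * largestR, stepCm = profileStepCm)
    ri <- ringingIndex(prof, largestR)
    cv <- NA_real_
    if (!is.null(covRoi)) {
      m <- .roiMasks(dim(vol@data), vol@spacing, covRoi)
      x <- vol@data[, , m$slice][m$inner]
      cv <- stats::sd(x) / mean(x)
    }
    data.frame(method = mth, sphereId = cs$sphereId,
      diameterMm = geometry$diameterMm[seq_len(nSpheres)],
      aSph = cs$aSph, aBg = cs$aBg, contrast = cs$contrast,
      ringingLargest = ri, covUniform = cv)
  })
  do.call(rbind, rows)
}
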