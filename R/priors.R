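#' Construct a PriorConfig
#'
#' Defaults mirror a typical Bayesian SPECT protocol: 3x3x3 neighbourhood,
#' Bayesian weight 0.3, and for the Bowsher prior 18 scanned / 9 selected
#' neighbours.
#'
#' @param priorType "none", "smooth", "mrp" or "bowsher".
#' @param beta Bayesian weight (>= 0).
#' @param neighbourhood odd cubic window edge length.
#' @param bowsherScan neighbours examined (nearest first).
#' @param bowsherB most-similar neighbours kept.
#' @param anatomical grid-matched anatomical [SpectVolume-class]
#'   (required for "bowsher").
#' @return A [PriorConfig-class].
#' @export
priorConfig <- function(priorType = c("none", "smooth", "mrp", "bowsher"),
    beta = 0.3, neighbourhood = 3, bowsherScan = 18, bowsherB = 9,
    anatomical = NULL) {
  new("PriorConfig", priorType = match.arg(priorType), beta = beta,
    neighbourhood = as.integer(neighbourhood),
    bowsherScan = as.integer(bowsherScan), bowsherB = as.integer(bowsherB),
    anatomical = anatomical)
}

setMethod("show", "PriorConfig", function(object) {
  cat(sprintf("PriorConfig: %s, beta = %g, window %d^3",
    object@priorType, object@beta, object@neighbourhood))
  if (object@priorType == "bowsher")
    cat(sprintf(", Bowsher %d/%d", object@bowsherScan, object@bowsherB))
  cat("\n")
})

## neighbour offsets of an odd cubic window, centre excluded, ordered by
## (physical centre distance, lexicographic offset); weights are inverse
## physical distance
.neighbourOffsets <- function(w, spacing = c(1, 1, 1)) {
  r <- (w - 1L) / 2L
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[!(g$x == 0 & g$y == 0 & g$z == 0), ]
  dist <- sqrt((g$x * spacing[1])^2 + (g$y * spacing[2])^2 +
    (g$z * spacing[3])^2)
  o <- order(dist, g$x, g$y, g$z)
  list(offsets = as.matrix(g[o, , drop = FALSE]), dist = dist[o],
    weights = 1 / dist[o])
}

## zero-filled shift: res[t] = a[t + off] where in range
.shiftArr <- function(a, off) {
  d <- dim(a)
  res <- array(0, d)
  tx <- max(1L, 1L - off[1]):min(d[1], d[1] - off[1])
  ty <- max(1L, 1L - off[2]):min(d[2], d[2] - off[2])
  tz <- max(1L, 1L - off[3]):min(d[3], d[3] - off[3])
  if (length(tx) < 1L || length(ty) < 1L || length(tz) < 1L) return(res)
  res[tx, ty, tz] <- a[tx + off[1], ty + off[2], tz + off[3]]
  res
}

## weighted neighbourhood mean A_j = sum w f / sum w over in-volume
## (optionally per-voxel selected) neighbours; voxels with no neighbours
## fall back to their own value (zero penalty there)
.neighbourMean <- function(fArr, nb, selMat = NULL) {
  d <- dim(fArr)
  num <- array(0, d)
  den <- array(0, d)
  ones <- array(1, d)
  for (k in seq_len(nrow(nb$offsets))) {
    off <- nb$offsets[k, ]
    w <- nb$weights[k]
    if (is.null(selMat)) {
      num <- num + w * .shiftArr(fArr, off)
      den <- den + w * .shiftArr(ones, off)
    } else {
      sk <- array(selMat[, k], d)
      num <- num + (w * sk) * .shiftArr(fArr, off)
      den <- den + w * sk
    }
  }
  out <- fArr
  pos <- den > 0
  out[pos] <- num[pos] / den[pos]
  out
}

## common penalty-factor assembly: c = 1 / (sens + beta (f - A)/max(A,eps)),
## denominator floored; the floor also protects the OSL update when large
## beta drives the denominator non-positive
.penaltyFactor <- function(fArr, AArr, beta, sensArr, epsilon) {
  r <- (fArr - AArr) / pmax(AArr, epsilon)
  den <- sensArr + beta * r
  floorv <- max(epsilon, 1e-8 * mean(sensArr))
  clamped <- sum(den < floorv)
  list(c = 1 / pmax(den, floorv), clamped = clamped)
}

.asFactorVolume <- function(fOld, pf) {
  out <- new("SpectVolume", data = pf$c, spacing = fOld@spacing)
  attr(out, "clampedCount") <- pf$clamped
  out
}

#' Quadratic smoothing prior penalty factor
#'
#' Multiplicative one-step-late penalty factor in relative form:
#' \deqn{c_j^P = 1 / (s_j + \beta (f_j - A_j)/A_j)}
#' where \eqn{s_j} is the subset sensitivity and \eqn{A_j} the
#' inverse-distance-weighted mean of the neighbourhood (weights
#' renormalised over in-volume neighbours, so uniform images incur zero
#' penalty). \eqn{A_j} is floored at \code{epsilon} in the division and
#' the whole denominator floored to keep the update non-negative.
#'
#' @param fOld current estimate, a [SpectVolume-class] (>= 0).
#' @param prior a [PriorConfig-class] with \code{priorType = "smooth"}.
#' @param sensitivity subset sensitivity image \eqn{\sum_{i\in S} a_{ij}}
#'   as a [SpectVolume-class].
#' @param epsilon positive division stabiliser.
#' @return A [SpectVolume-class] of factors; the number of floored
#'   denominators is attached as attribute \code{"clampedCount"}.
#' @export
smoothingPenaltyFactor <- function(fOld, prior, sensitivity,
    epsilon = 1e-12) {
  stopifnot(prior@priorType == "smooth")
  nb <- .neighbourOffsets(prior@neighbourhood, fOld@spacing)
  A <- .neighbourMean(fOld@data, nb)
  .asFactorVolume(fOld,
    .penaltyFactor(fOld@data, A, prior@beta, sensitivity@data, epsilon))
}

#' Median root prior penalty factor
#'
#' As [smoothingPenaltyFactor()] but with the local median \eqn{M_j} of
#' the full cubic window (centre voxel included, truncated at the volume
#' borders) in place of the weighted mean:
#' \deqn{c_j^P = 1 / (s_j + \beta (f_j - M_j)/M_j).}
#' The penalty vanishes on locally monotonic images, which is what lets
#' the median root prior suppress ringing while preserving true edges.
#'
#' @inheritParams smoothingPenaltyFactor
#' @param prior a [PriorConfig-class] with \code{priorType = "mrp"}.
#' @return A [SpectVolume-class] of factors (attribute
#'   \code{"clampedCount"} as in [smoothingPenaltyFactor()]).
#' @export
mrpPenaltyFactor <- function(fOld, prior, sensitivity, epsilon = 1e-12) {
  stopifnot(prior@priorType == "mrp")
  d <- dim(fOld@data)
  M <- array(.cppMedianFilter3(as.numeric(fOld@data), as.integer(d),
    prior@neighbourhood), d)
  .asFactorVolume(fOld,
    .penaltyFactor(fOld@data, M, prior@beta, sensitivity@data, epsilon))
}

#' @rdname bowsherSelect
#' @export
setClass("BowsherSelection",
  representation(offsets = "matrix", weights = "numeric",
    selection = "matrix", dims = "integer"))

setMethod("show", "BowsherSelection", function(object) {
  cat(sprintf(
    "BowsherSelection: %d scanned offsets, %d x %d x %d grid, %d kept/voxel (mean %.2f)\n",
    nrow(object@offsets), object@dims[1], object@dims[2], object@dims[3],
    max(rowSums(object@selection)), mean(rowSums(object@selection))))
})

#' Precompute Bowsher neighbour selection from an anatomical image
#'
#' For every voxel, the \code{bowsherScan} nearest in-window neighbours
#' (by Euclidean centre distance; 18 gives the face and edge neighbours of
#' the 3x3x3 cube) are examined and the \code{bowsherB} with the smallest
#' absolute anatomical-value difference to the centre voxel are kept. Ties
#' break toward the smaller centre distance, then lexicographic offset
#' order. The selection depends only on the anatomical image, so it is
#' computed once and reused across all sub-iterations. Border voxels with
#' fewer than \code{bowsherB} in-volume candidates keep all available.
#'
#' @param anatomical the anatomical (CT-like) [SpectVolume-class] on the
#'   reconstruction grid.
#' @param prior a [PriorConfig-class] with \code{priorType = "bowsher"}.
#' @return A \code{BowsherSelection} object for [bowsherPenaltyFactor()].
#' @export
bowsherSelect <- function(anatomical, prior) {
  stopifnot(prior@priorType == "bowsher")
  nb <- .neighbourOffsets(prior@neighbourhood, anatomical@spacing)
  scan <- seq_len(prior@bowsherScan)
  offs <- nb$offsets[scan, , drop = FALSE]
  d <- dim(anatomical@data)
  sel <- .cppBowsherSelect(as.numeric(anatomical@data), as.integer(d),
    offs, prior@bowsherB)
  new("BowsherSelection", offsets = offs, weights = nb$weights[scan],
    selection = sel, dims = as.integer(d))
}

#' Bowsher (anatomically guided) prior penalty factor
#'
#' Identical in form to [smoothingPenaltyFactor()], but the local mean
#' \eqn{A_j} uses inverse-distance weights renormalised over only the
#' neighbours selected by [bowsherSelect()] — those most similar to the
#' centre voxel in the anatomical image — so smoothing is restricted to
#' anatomically homogeneous regions and does not cross CT edges.
#'
#' @inheritParams smoothingPenaltyFactor
#' @param prior a [PriorConfig-class] with \code{priorType = "bowsher"}.
#' @param selection a precomputed [bowsherSelect()] result.
#' @return A [SpectVolume-class] of factors (attribute
#'   \code{"clampedCount"}).
#' @export
bowsherPenaltyFactor <- function(fOld, prior, selection, sensitivity,
    epsilon = 1e-12) {
  stopifnot(prior@priorType == "bowsher")
  if (!identical(selection@dims, dim(fOld@data)))
    stop("Bowsher selection grid does not match the estimate",
      call. = FALSE)
  nb <- list(offsets = selection@offsets, weights = selection@weights)
  A <- .neighbourMean(fOld@data, nb, selMat = selection@selection)
  .asFactorVolume(fOld,
    .penaltyFactor(fOld@data, A, prior@beta, sensitivity@data, epsilon))
}
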