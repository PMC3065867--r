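#' Partition projection angles into ordered subsets
#'
#' Subset m (0-based) contains angle indices m, m + nSubsets,
#' m + 2 nSubsets, ... so consecutive angles within a subset are maximally
#' spread over the orbit. Subsets are listed in bit-reversed processing
#' order (when \code{nSubsets} is a power of two), the standard OSEM
#' ordering that maximises the angular separation between consecutive
#' sub-iterations.
#'
#' @param nAngles total number of projection angles.
#' @param nSubsets number of subsets; must divide \code{nAngles}.
#' @return A [SubsetScheme-class].
#' @examples
#' makeSubsets(128, 16)
#' @export
makeSubsets <- function(nAngles, nSubsets) {
  nAngles <- as.integer(nAngles)
  nSubsets <- as.integer(nSubsets)
  if (nAngles %% nSubsets != 0L) {
    div <- which(nAngles %% seq_len(nAngles) == 0L)
    stop("nSubsets must divide nAngles = ", nAngles,
      "; valid choices: ", paste(div, collapse = ", "), call. = FALSE)
  }
  subs <- lapply(seq_len(nSubsets) - 1L, function(m)
    seq.int(m + 1L, nAngles, by = nSubsets))
  ## bit-reversal permutation of the subset order
  n <- nSubsets
  if (n > 1L && bitwAnd(n, n - 1L) == 0L) {
    bits <- as.integer(log2(n))
    rev <- vapply(0:(n - 1L), function(i) {
      r <- 0L
      for (b in seq_len(bits)) {
        r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(i, 1L))
        i <- bitwShiftR(i, 1L)
      }
      r
    }, 1L)
    subs <- subs[rev + 1L]
  }
  new("SubsetScheme", nSubsets = nSubsets, subsets = subs)
}

setMethod("show", "SubsetScheme", function(object) {
  cat(sprintf("SubsetScheme: %d subsets of %d angles\n",
    object@nSubsets, length(object@subsets[[1]])))
})

#' Subset sensitivity image
#'
#' Back projection of all-ones projections over the given angles,
#' \eqn{s_j = \sum_{i \in S} a_{ij}}: the normaliser of the OSEM update.
#'
#' @param model a [systemModel()].
#' @param subset integer vector of angle indices.
#' @return A [SpectVolume-class].
#' @export
sensitivityImage <- function(model, subset) {
  ones <- array(1, c(model@dims[1], model@dims[3], length(subset)))
  new("SpectVolume", data = .backArr(model, ones, as.integer(subset)),
    spacing = model@spacing)
}

## shared core of the OSEM / OSL updates: returns the back-projected
## correction factor c^L = sum_{i in S} a_ij p_i / q_i, q floored at eps
.correctionFactor <- function(fArr, pArr, subset, model, epsilon) {
  q <- .forwardArr(model, fArr, subset)
  ratio <- pArr[, , subset, drop = FALSE] / pmax(q, epsilon)
  .backArr(model, ratio, subset)
}

.checkUpdateInputs <- function(fOld, p, model) {
  if (!identical(dim(fOld@data), model@dims))
    stop("estimate grid does not match system model", call. = FALSE)
  if (any(p@data < 0))
    stop("measured projections must be non-negative", call. = FALSE)
  if (any(fOld@data < 0))
    stop("estimate must be non-negative", call. = FALSE)
}

#' One OSEM sub-iteration
#'
#' The multiplicative expectation-maximisation update over one angular
#' subset S:
#' \deqn{f_j^{new} = \frac{f_j^{old}}{\sum_{i\in S} a_{ij}}
#'   \sum_{i\in S} a_{ij} \frac{p_i}{\sum_k a_{ik} f_k^{old}}.}
#' Estimated projections and the sensitivity denominator are floored at
#' \code{epsilon} (the sensitivity additionally at 1e-8 of its mean), so
#' the update maps non-negative images to non-negative images.
#'
#' @param fOld current estimate, a [SpectVolume-class].
#' @param p measured [ProjectionSet-class].
#' @param subset integer vector of angle indices (one subset).
#' @param model a [systemModel()] matching \code{fOld} and \code{p}.
#' @param epsilon positive division stabiliser.
#' @param sensitivity optional precomputed [sensitivityImage()] for this
#'   subset.
#' @return Updated [SpectVolume-class].
#' @export
osemUpdate <- function(fOld, p, subset, model, epsilon = 1e-12,
    sensitivity = NULL) {
  oslUpdate(fOld, p, subset, model, prior = priorConfig("none"),
    epsilon = epsilon, sensitivity = sensitivity)
}

#' One one-step-late (OSL) Bayesian sub-iteration
#'
#' Multiplies the current estimate by the OSEM correction factor
#' \eqn{c^L} and the penalty factor \eqn{c^P} of the configured prior,
#' the prior's derivative being evaluated at the previous iterate
#' ("one step late"):
#' \deqn{f^{new} = f^{old} \, c^P \, c^L.}
#' With \code{priorType = "none"} or \code{beta = 0} this is exactly the
#' OSEM update.
#'
#' @inheritParams osemUpdate
#' @param prior a [PriorConfig-class].
#' @param selection precomputed [bowsherSelect()] result (computed on the
#'   fly if NULL and the prior is "bowsher").
#' @return Updated [SpectVolume-class]; attribute \code{"clampedCount"}
#'   carries the number of floored penalty denominators.
#' @export
oslUpdate <- function(fOld, p, subset, model, prior,
    epsilon = 1e-12, sensitivity = NULL, selection = NULL) {
  .checkUpdateInputs(fOld, p, model)
  subset <- as.integer(subset)
  if (is.null(sensitivity)) sensitivity <- sensitivityImage(model, subset)
  cL <- .correctionFactor(fOld@data, p@data, subset, model, epsilon)
  cP <- switch(prior@priorType,
    none = {
      sens <- sensitivity@data
      floorv <- max(epsilon, 1e-8 * mean(sens))
      .asFactorVolume(fOld, list(c = 1 / pmax(sens, floorv), clamped = 0L))
    },
    smooth = smoothingPenaltyFactor(fOld, prior, sensitivity, epsilon),
    mrp = mrpPenaltyFactor(fOld, prior, sensitivity, epsilon),
    bowsher = {
      if (is.null(selection))
        selection <- bowsherSelect(prior@anatomical, prior)
      bowsherPenaltyFactor(fOld, prior, selection, sensitivity, epsilon)
    })
  out <- new("SpectVolume", data = fOld@data * cP@data * cL,
    spacing = fOld@spacing)
  attr(out, "clampedCount") <- attr(cP, "clampedCount")
  out
}

#' Poisson log-likelihood of projections given an estimate
#'
#' \eqn{\sum_i (p_i \ln q_i - q_i)} with estimated projections q floored
#' at \code{epsilon}; the monitoring quantity that MLEM increases
#' monotonically.
#'
#' @param p measured [ProjectionSet-class] (or 3-D array).
#' @param q estimated projections (same shape).
#' @param epsilon positive floor for the logarithm.
#' @return scalar log-likelihood (up to the constant \eqn{-\ln p_i!}).
#' @export
poissonLogLik <- function(p, q, epsilon = 1e-12) {
  pa <- if (is(p, "ProjectionSet")) p@data else p
  qa <- if (is(q, "ProjectionSet")) q@data else q
  qa <- pmax(qa, epsilon)
  sum(pa * log(qa) - qa)
}

#' Construct a ReconConfig
#'
#' Defaults follow a standard clinical-phantom protocol: 16 subsets,
#' 5 iterations, Bayesian weight 0.3, 3x3x3 neighbourhood, Bowsher 18/9,
#' no post-filter.
#'
#' @param nIterations full iterations.
#' @param nSubsets ordered subsets (must divide the number of angles).
#' @param prior a [PriorConfig-class].
#' @param collimator a [CollimatorModel-class].
#' @param attenuation attenuation [SpectVolume-class] or NULL.
#' @param initialValue uniform starting value, or NA to use
#'   total counts / number of voxels.
#' @param postfilterFwhmCm Gaussian post-filter FWHM (cm); 0 disables.
#' @param epsilon positive division stabiliser.
#' @return A [ReconConfig-class].
#' @export
reconConfig <- function(nIterations = 5, nSubsets = 16,
    prior = priorConfig("none"), collimator = collimatorModel(),
    attenuation = NULL, initialValue = NA_real_, postfilterFwhmCm = 0,
    epsilon = 1e-12) {
  new("ReconConfig", nIterations = as.integer(nIterations),
    nSubsets = as.integer(nSubsets), prior = prior,
    collimator = collimator, attenuation = attenuation,
    initialValue = initialValue, postfilterFwhmCm = postfilterFwhmCm,
    epsilon = epsilon)
}

setMethod("show", "ReconConfig", function(object) {
  cat(sprintf(
    "ReconConfig: %d iterations x %d subsets, prior %s (beta %g), collimator %s\n",
    object@nIterations, object@nSubsets, object@prior@priorType,
    object@prior@beta,
    if (object@collimator@enabled) "on" else "off"))
})

#' @rdname runReconstruction
#' @export
setClass("ReconResult",
  representation(volume = "SpectVolume", log = "data.frame",
    config = "ReconConfig"))

#' @rdname runReconstruction
#' @export
setGeneric("reconVolume", function(x) standardGeneric("reconVolume"))

#' @rdname runReconstruction
#' @export
setMethod("reconVolume", "ReconResult", function(x) x@volume)

#' @rdname runReconstruction
#' @export
setGeneric("reconLog", function(x) standardGeneric("reconLog"))

#' @rdname runReconstruction
#' @export
setMethod("reconLog", "ReconResult", function(x) x@log)

setMethod("show", "ReconResult", function(object) {
  cat("ReconResult\n  ")
  show(object@config)
  cat("  ")
  show(object@volume)
})

#' Run a full OSEM / OSL reconstruction
#'
#' Starts from a uniform positive estimate and loops
#' \code{nIterations} x all subsets (bit-reversed order), applying
#' [oslUpdate()] (which is [osemUpdate()] when the prior is "none" or
#' \code{beta = 0}), then applies the Gaussian post-filter if configured.
#' Per-sub-iteration log records (iteration, subset, estimate min/max,
#' floored-denominator count) are collected; the Poisson log-likelihood of
#' the full data is evaluated per full iteration by default
#' (\code{logLikelihood = "iteration"}) because it costs one complete
#' forward projection; use \code{"subiteration"} to evaluate it at every
#' sub-iteration or \code{"none"} to skip it.
#'
#' @param p measured [ProjectionSet-class].
#' @param cfg a [reconConfig()].
#' @param gridDim reconstruction grid dimensions; default matches the
#'   attenuation map, else (bins, bins, rows).
#' @param spacing voxel spacing (cm); default from the attenuation map,
#'   else isotropic at the detector bin size.
#' @param logLikelihood "iteration", "subiteration" or "none".
#' @param verbose print per-iteration progress.
#' @return A \code{ReconResult}; extract the image with
#'   \code{reconVolume()} and the iteration log with \code{reconLog()}.
#' @export
runReconstruction <- function(p, cfg, gridDim = NULL, spacing = NULL,
    logLikelihood = c("iteration", "subiteration", "none"),
    verbose = FALSE) {
  logLikelihood <- match.arg(logLikelihood)
  geom <- p@geometry
  if (!is.null(cfg@attenuation)) {
    if (is.null(gridDim)) gridDim <- dim(cfg@attenuation@data)
    if (is.null(spacing)) spacing <- cfg@attenuation@spacing
  } else {
    if (is.null(gridDim))
      gridDim <- c(geom@detectorBins, geom@detectorBins, geom@detectorRows)
    if (is.null(spacing)) spacing <- rep(geom@binSizeCm, 3L)
  }
  model <- systemModel(gridDim, spacing, geom, cfg@collimator,
    cfg@attenuation)
  scheme <- makeSubsets(geom@nAngles, cfg@nSubsets)
  sens <- lapply(scheme@subsets, function(s) sensitivityImage(model, s))
  selection <- if (cfg@prior@priorType == "bowsher")
    bowsherSelect(cfg@prior@anatomical, cfg@prior) else NULL
  init <- if (is.na(cfg@initialValue))
    sum(p@data) / prod(gridDim) else cfg@initialValue
  if (init <= 0) stop("initial estimate must be positive", call. = FALSE)
  f <- new("SpectVolume", data = array(init, gridDim),
    spacing = as.numeric(spacing))
  allAngles <- seq_len(geom@nAngles)
  rows <- vector("list", cfg@nIterations * scheme@nSubsets)
  rec <- 0L
  for (it in seq_len(cfg@nIterations)) {
    for (si in seq_len(scheme@nSubsets)) {
      f <- oslUpdate(f, p, scheme@subsets[[si]], model, cfg@prior,
        epsilon = cfg@epsilon, sensitivity = sens[[si]],
        selection = selection)
      ll <- if (logLikelihood == "subiteration" ||
          (logLikelihood == "iteration" && si == scheme@nSubsets))
        poissonLogLik(p@data, .forwardArr(model, f@data, allAngles),
          cfg@epsilon)
      else NA_real_
      rec <- rec + 1L
      rows[[rec]] <- data.frame(iteration = it, subset = si,
        logLik = ll, minVoxel = min(f@data), maxVoxel = max(f@data),
        clamped = as.integer(attr(f, "clampedCount") %||% 0L))
    }
    if (verbose)
      message(sprintf("iteration %d/%d  logLik %.6g", it,
        cfg@nIterations, rows[[rec]]$logLik))
  }
  if (cfg@postfilterFwhmCm > 0)
    f <- gaussianPostfilter(f, cfg@postfilterFwhmCm)
  attr(f, "clampedCount") <- NULL
  new("ReconResult", volume = f, log = do.call(rbind, rows),
    config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
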