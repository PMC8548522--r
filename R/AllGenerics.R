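#' @name accessors
#' @title Accessors for fbmtrack classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object an fbmtrack S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("trackId", function(object) standardGeneric("trackId"))
#' @rdname accessors
#' @export
setMethod("trackId", "Trajectory", function(object) object@trackId)

#' @rdname accessors
#' @export
setGeneric("groupId", function(object) standardGeneric("groupId"))
#' @rdname accessors
#' @export
setMethod("groupId", "Trajectory", function(object) object@groupId)

#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setMethod("timePoints", "Trajectory", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("timePoints", "InterpolatedPath", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("frameIndex", function(object) standardGeneric("frameIndex"))
#' @rdname accessors
#' @export
setMethod("frameIndex", "Trajectory", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "Trajectory", function(object) object@coords)

#' @rdname accessors
#' @export
setGeneric("locErrors", function(object) standardGeneric("locErrors"))
#' @rdname accessors
#' @export
setMethod("locErrors", "Trajectory", function(object) object@locErrors)

#' @rdname accessors
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setMethod("nPoints", "Trajectory", function(object) length(object@times))

#' @rdname accessors
#' @export
setGeneric("nDims", function(object) standardGeneric("nDims"))
#' @rdname accessors
#' @export
setMethod("nDims", "Trajectory", function(object) ncol(object@coords))

#' @rdname accessors
#' @export
setGeneric("diffusionCoef", function(object) standardGeneric("diffusionCoef"))
#' @rdname accessors
#' @export
setMethod("diffusionCoef", "DiffusionParams", function(object) object@D)
#' @rdname accessors
#' @export
setMethod("diffusionCoef", "FbmFit", function(object) object@params@D)

#' @rdname accessors
#' @export
setGeneric("anomalousExponent",
           function(object) standardGeneric("anomalousExponent"))
#' @rdname accessors
#' @export
setMethod("anomalousExponent", "DiffusionParams", function(object) object@alpha)
#' @rdname accessors
#' @export
setMethod("anomalousExponent", "FbmFit", function(object) object@params@alpha)

#' @rdname accessors
#' @export
setGeneric("meanOffset", function(object) standardGeneric("meanOffset"))
#' @rdname accessors
#' @export
setMethod("meanOffset", "DiffusionParams", function(object) object@mu)

#' @rdname accessors
#' @export
setGeneric("fittedParams", function(object) standardGeneric("fittedParams"))
#' @rdname accessors
#' @export
setMethod("fittedParams", "FbmFit", function(object) object@params)

#' @rdname accessors
#' @export
setGeneric("trajectories", function(object) standardGeneric("trajectories"))
#' @rdname accessors
#' @export
setMethod("trajectories", "FbmEnsemble", function(object) object@trajectories)

#' @rdname accessors
#' @export
setGeneric("particleParams", function(object) standardGeneric("particleParams"))
#' @rdname accessors
#' @export
setMethod("particleParams", "FbmEnsemble", function(object) object@particleParams)
#' @rdname accessors
#' @export
setMethod("particleParams", "FbmEnsembleFit",
          function(object) object@ensemble@particleParams)

#' @rdname accessors
#' @export
setGeneric("substrateParams",
           function(object) standardGeneric("substrateParams"))
#' @rdname accessors
#' @export
setMethod("substrateParams", "FbmEnsemble",
          function(object) object@substrateParams)
#' @rdname accessors
#' @export
setMethod("substrateParams", "FbmEnsembleFit",
          function(object) object@ensemble@substrateParams)

#' @rdname accessors
#' @export
setGeneric("uncorrectedFits", function(object) standardGeneric("uncorrectedFits"))
#' @rdname accessors
#' @export
setMethod("uncorrectedFits", "FbmEnsembleFit",
          function(object) object@uncorrected)

#' @rdname accessors
#' @export
setGeneric("chainSamples", function(object) standardGeneric("chainSamples"))
#' @rdname accessors
#' @export
setMethod("chainSamples", "PosteriorChain", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("acceptanceRate", function(object) standardGeneric("acceptanceRate"))
#' @rdname accessors
#' @export
setMethod("acceptanceRate", "PosteriorChain",
          function(object) object@acceptanceRate)

#' @rdname accessors
#' @export
setGeneric("pathMean", function(object) standardGeneric("pathMean"))
#' @rdname accessors
#' @export
setMethod("pathMean", "InterpolatedPath", function(object) object@mean)

#' @rdname accessors
#' @export
setGeneric("pathLower", function(object) standardGeneric("pathLower"))
#' @rdname accessors
#' @export
setMethod("pathLower", "InterpolatedPath", function(object) object@lower)

#' @rdname accessors
#' @export
setGeneric("pathUpper", function(object) standardGeneric("pathUpper"))
#' @rdname accessors
#' @export
setMethod("pathUpper", "InterpolatedPath", function(object) object@upper)

#' Posterior credible intervals
#'
#' Equal-tailed quantile intervals of the sampled parameters.
#'
#' @param object a [PosteriorChain-class].
#' @param level credible level (default 0.95).
#' @return A matrix with one row per parameter and columns `lower`,
#'   `median`, `upper`.
#' @export
setGeneric("credibleIntervals",
           function(object, level = 0.95) standardGeneric("credibleIntervals"))

#' @rdname credibleIntervals
#' @export
setMethod("credibleIntervals", "PosteriorChain", function(object, level = 0.95) {
  a <- (1 - level) / 2
  ci <- t(apply(object@samples, 2L, quantile, probs = c(a, 0.5, 1 - a),
                names = FALSE))
  colnames(ci) <- c("lower", "median", "upper")
  ci
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory '%s' (group '%s'): %d points, %dD, t in [%g, %g] s\n",
              object@trackId, object@groupId, nPoints(object), nDims(object),
              min(object@times), max(object@times)))
  if (any(object@locErrors > 0))
    cat(sprintf("  mean localization error: %.4g\n", mean(object@locErrors)))
})

setMethod("show", "DiffusionParams", function(object) {
  cat(sprintf("DiffusionParams: D = %.4g, alpha = %.4g, mu = (%s)\n",
              object@D, object@alpha,
              paste(signif(object@mu, 4), collapse = ", ")))
})

setMethod("show", "FbmFit", function(object) {
  cat(sprintf("FbmFit (%d displacements): D = %.4g, alpha = %.4g, logPost = %.3f%s\n",
              object@nUsed, object@params@D, object@params@alpha,
              object@logPost, if (object@flagged) " [flagged]" else ""))
})

setMethod("show", "FbmEnsemble", function(object) {
  cat(sprintf("FbmEnsemble: %d particles, substrate D = %.4g, alpha = %.4g\n",
              length(object@trajectories), object@substrateParams@D,
              object@substrateParams@alpha))
})

setMethod("show", "FbmEnsembleFit", function(object) {
  cat(sprintf("FbmEnsembleFit: %d particles, logPost = %.3f%s\n",
              length(object@ensemble@trajectories), object@logPost,
              if (object@flagged) " [flagged]" else ""))
  show(object@ensemble@substrateParams)
})

setMethod("show", "PosteriorChain", function(object) {
  cat(sprintf("PosteriorChain: %d samples (burn-in %d), acceptance %.2f\n",
              nrow(object@samples), object@burnIn, object@acceptanceRate))
})

setMethod("show", "InterpolatedPath", function(object) {
  cat(sprintf("InterpolatedPath: %d query times, %dD, %.0f%% band\n",
              length(object@times), ncol(object@mean), 100 * object@level))
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve: %d lags (%dD), first values: %s\n",
              length(object@lags), object@nDims,
              paste(signif(head(object@values, 3), 4), collapse = ", ")))
})

setMethod("show", "VACFCurve", function(object) {
  cat(sprintf("VACFCurve: epsilon = %g s, %d lags\n", object@epsilon,
              length(object@taus)))
})

setMethod("show", "VarianceDecomposition", function(object) {
  cat(sprintf(
    "VarianceDecomposition (%d groups): total = %.4g, intra = %.4g (%.1f%%), inter = %.4g (%.1f%%)\n",
    object@nGroups, object@total, object@intra,
    100 * object@proportions[["intra"]], object@inter,
    100 * object@proportions[["inter"]]))
})

setMethod("show", "SpotFit", function(object) {
  cat(sprintf(
    "SpotFit: center (%.3f, %.3f) +- (%.3g, %.3g) px, size (%.3f, %.3f), theta %.3f%s\n",
    object@center[1], object@center[2], object@locError[1], object@locError[2],
    object@size[1], object@size[2], object@theta,
    if (object@converged) "" else " [failed]"))
})

setMethod("show", "ChannelAlignment", function(object) {
  cat(sprintf(
    "ChannelAlignment: scale (%.4f, %.4f), shift (%.3f, %.3f) px, rotation %.4f rad\n",
    object@scale[1], object@scale[2], object@translation[1],
    object@translation[2], object@theta))
})
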