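#' @useDynLib fbmtrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats optim rnorm runif qnorm quantile var median coef lm
#'   plogis qlogis sd ks.test setNames aggregate dnorm approx
#' @importFrom utils read.csv write.csv head
NULL

#' Trajectory: one particle's observed time series
#'
#' Holds the observed positions of a single tracked particle, the observation
#' times in seconds, integer frame indices on the acquisition grid (used by
#' lag-based estimators to pair displacements across occlusions), and optional
#' per-point, per-dimension localization errors (standard deviations, same
#' length units as the positions).
#'
#' @slot trackId character scalar identifier.
#' @slot groupId character scalar; particles sharing a `groupId` (e.g. one
#'   cell) are eligible for joint substrate-corrected fitting.
#' @slot frames integer vector of frame indices, strictly increasing.
#' @slot times numeric vector of times in seconds, strictly increasing.
#' @slot coords numeric matrix, one row per time point, one column per spatial
#'   dimension (1-3).
#' @slot locErrors numeric matrix, same shape as `coords`, localization error
#'   standard deviations (0 = noiseless).
#' @export
setClass("Trajectory",
  representation(trackId = "character", groupId = "character",
                 frames = "integer", times = "numeric",
                 coords = "matrix", locErrors = "matrix"))

setValidity("Trajectory", function(object) {
  n <- length(object@times)
  if (n < 1L) return("trajectory needs at least one time point")
  if (!all(is.finite(object@times))) return("times must be finite")
  if (n > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (length(object@frames) != n) return("frames/times length mismatch")
  if (n > 1L && any(diff(object@frames) <= 0L))
    return("frames must be strictly increasing")
  if (nrow(object@coords) != n) return("coords rows must match times")
  d <- ncol(object@coords)
  if (!d %in% 1:3) return("coords must have 1-3 columns")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (!identical(dim(object@locErrors), dim(object@coords)))
    return("locErrors must have the same shape as coords")
  if (any(!is.finite(object@locErrors)) || any(object@locErrors < 0))
    return("locErrors must be finite and non-negative")
  TRUE
})

#' Construct a Trajectory
#'
#' @param times numeric vector of observation times (seconds), strictly
#'   increasing.
#' @param coords numeric matrix (or vector for 1D) of positions, one row per
#'   time point.
#' @param locErrors localization error standard deviations: a scalar
#'   (broadcast), a per-point vector, or a full matrix matching `coords`.
#' @param trackId,groupId identifiers.
#' @param frames integer frame indices; defaults to `0:(n-1)`.
#' @return A [Trajectory-class] object.
#' @examples
#' tr <- Trajectory(times = c(0, 0.5, 1), coords = cbind(c(0, .1, .3), c(0, 0, .2)))
#' nPoints(tr)
#' @export
Trajectory <- function(times, coords, locErrors = 0,
                       trackId = "track1", groupId = "group1",
                       frames = NULL) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1L)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(dim(locErrors))) {
    locErrors <- matrix(locErrors, nrow = nrow(coords), ncol = ncol(coords),
                        byrow = length(locErrors) == ncol(coords) &&
                          length(locErrors) > 1L)
  }
  locErrors <- as.matrix(locErrors)
  storage.mode(locErrors) <- "double"
  if (is.null(frames)) frames <- seq_along(times) - 1L
  new("Trajectory", trackId = as.character(trackId),
      groupId = as.character(groupId), frames = as.integer(frames),
      times = as.numeric(times), coords = coords, locErrors = locErrors)
}

#' Diffusion parameters of one FBM process
#'
#' @slot D apparent diffusion coefficient, units length^2 / time^alpha, > 0.
#' @slot alpha anomalous exponent in (0, 2); 1 is ordinary Brownian motion.
#' @slot mu per-dimension constant mean offset (length units).
#' @export
setClass("DiffusionParams",
  representation(D = "numeric", alpha = "numeric", mu = "numeric"))

setValidity("DiffusionParams", function(object) {
  if (length(object@D) != 1L || !is.finite(object@D) || object@D <= 0)
    return("D must be a single positive finite number")
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha <= 0 || object@alpha >= 2)
    return("alpha must lie strictly inside (0, 2)")
  if (!all(is.finite(object@mu))) return("mu must be finite")
  TRUE
})

#' Construct DiffusionParams
#' @param D apparent diffusion coefficient (> 0).
#' @param alpha anomalous exponent in (0, 2).
#' @param mu per-dimension mean offset; scalar is accepted.
#' @return A [DiffusionParams-class] object.
#' @export
DiffusionParams <- function(D, alpha, mu = 0) {
  new("DiffusionParams", D = as.numeric(D), alpha = as.numeric(alpha),
      mu = as.numeric(mu))
}

#' Multi-particle ensemble sharing substrate motion
#'
#' Two or more trajectories from the same group (cell) whose observed motion
#' is modeled as independent FBM particle motion plus one common FBM substrate
#' process added to all of them.
#'
#' @slot trajectories list of [Trajectory-class] (>= 2), same `groupId`.
#' @slot particleParams list of [DiffusionParams-class], one per trajectory.
#' @slot substrateParams [DiffusionParams-class] for the substrate; its mean
#'   offset is fixed at 0 (particle means absorb any constant).
#' @export
setClass("FbmEnsemble",
  representation(trajectories = "list", particleParams = "list",
                 substrateParams = "DiffusionParams"))

setValidity("FbmEnsemble", function(object) {
  K <- length(object@trajectories)
  if (K < 2L) return("an ensemble needs at least two trajectories")
  if (!all(vapply(object@trajectories, is, TRUE, "Trajectory")))
    return("trajectories must all be Trajectory objects")
  if (length(unique(vapply(object@trajectories, groupId, ""))) != 1L)
    return("all trajectories must share one groupId")
  if (length(object@particleParams) != K)
    return("one particleParams entry per trajectory required")
  if (!all(vapply(object@particleParams, is, TRUE, "DiffusionParams")))
    return("particleParams must all be DiffusionParams")
  if (any(object@substrateParams@mu != 0))
    return("substrate mean offset must be fixed at 0")
  TRUE
})

#' Construct an FbmEnsemble
#' @param trajectories list of >= 2 [Trajectory-class] objects with a common
#'   `groupId`.
#' @param particleParams list of [DiffusionParams-class], one per trajectory.
#' @param substrateParams [DiffusionParams-class] of the shared substrate
#'   process (mean fixed at 0).
#' @return An [FbmEnsemble-class] object.
#' @export
FbmEnsemble <- function(trajectories, particleParams, substrateParams) {
  new("FbmEnsemble", trajectories = trajectories,
      particleParams = particleParams, substrateParams = substrateParams)
}

#' Metropolis-Hastings posterior sample
#'
#' @slot samples matrix of posterior draws in natural units (columns `D`,
#'   `alpha`, then one `mu.*` per dimension), burn-in removed.
#' @slot logPost log-posterior value of each stored draw.
#' @slot acceptanceRate overall post-burn-in acceptance fraction.
#' @slot burnIn number of discarded sweeps.
#' @slot seed integer seed the chain was run with.
#' @export
setClass("PosteriorChain",
  representation(samples = "matrix", logPost = "numeric",
                 acceptanceRate = "numeric", burnIn = "integer",
                 seed = "integer"))

setValidity("PosteriorChain", function(object) {
  if (nrow(object@samples) < 1L) return("empty chain")
  if (!all(is.finite(object@samples))) return("samples must be finite")
  if (object@acceptanceRate <= 0 || object@acceptanceRate >= 1)
    return("acceptance rate must lie in (0, 1)")
  TRUE
})

#' Interpolated path with credible band
#'
#' @slot times query times (seconds).
#' @slot mean posterior mean positions (rows = times).
#' @slot lower,upper pointwise credible bounds, same shape as `mean`.
#' @slot level credible level (default 0.95).
#' @export
setClass("InterpolatedPath",
  representation(times = "numeric", mean = "matrix",
                 lower = "matrix", upper = "matrix", level = "numeric"))

setValidity("InterpolatedPath", function(object) {
  if (any(object@lower > object@mean + 1e-9) ||
      any(object@upper < object@mean - 1e-9))
    return("credible bounds must bracket the mean")
  TRUE
})

#' Single-trajectory maximum a posteriori fit
#'
#' @slot params fitted [DiffusionParams-class].
#' @slot logPost log-posterior at the optimum (flat priors: the log-likelihood).
#' @slot convergence optimizer convergence code (0 = converged).
#' @slot nUsed number of anchored displacements entering the likelihood.
#' @slot flagged TRUE when no optimizer start converged cleanly.
#' @slot details list with per-start diagnostics.
#' @export
setClass("FbmFit",
  representation(params = "DiffusionParams", logPost = "numeric",
                 convergence = "integer", nUsed = "integer",
                 flagged = "logical", details = "list"))

#' Joint substrate-corrected ensemble fit
#'
#' @slot ensemble [FbmEnsemble-class] carrying the jointly fitted particle and
#'   substrate parameters.
#' @slot uncorrected list of per-particle [FbmFit-class] obtained by ignoring
#'   the substrate (for comparison).
#' @slot logPost joint log-posterior at the optimum.
#' @slot convergence optimizer convergence code.
#' @slot flagged TRUE when the joint fit fell back or failed to converge.
#' @slot details list (initialization, optimizer reports).
#' @export
setClass("FbmEnsembleFit",
  representation(ensemble = "FbmEnsemble", uncorrected = "list",
                 logPost = "numeric", convergence = "integer",
                 flagged = "logical", details = "list"))

#' MSD curve
#'
#' Sliding-window mean squared displacement versus lag, occlusion-aware (a
#' pair contributes to lag n only when both endpoints were observed).
#'
#' @slot lags integer step intervals (frames).
#' @slot taus lag times in seconds.
#' @slot values mean squared displacements (length^2, summed over dimensions).
#' @slot counts number of contributing pairs per lag.
#' @slot nDims number of spatial dimensions.
#' @export
setClass("MSDCurve",
  representation(lags = "integer", taus = "numeric", values = "numeric",
                 counts = "integer", nDims = "integer"))

#' Velocity autocorrelation curve
#'
#' @slot taus lag times in seconds.
#' @slot values autocorrelation normalized to 1 at tau = 0.
#' @slot epsilon velocity discretization interval (seconds).
#' @slot counts contributing products per lag.
#' @export
setClass("VACFCurve",
  representation(taus = "numeric", values = "numeric", epsilon = "numeric",
                 counts = "integer"))

#' Inter-/intra-group variance decomposition
#'
#' Law-of-total-variance split of a per-track statistic into the average
#' within-group (population) variance and the variance of group means.
#'
#' @slot total total population variance.
#' @slot intra member-weighted mean of within-group population variances.
#' @slot inter member-weighted population variance of group means.
#' @slot proportions named fractions (intra, inter) of the total; NA when the
#'   total variance is zero.
#' @slot nGroups number of groups used (singletons excluded).
#' @export
setClass("VarianceDecomposition",
  representation(total = "numeric", intra = "numeric", inter = "numeric",
                 proportions = "numeric", nGroups = "integer"))

#' Refined sub-pixel spot model
#'
#' Parameters of a rotated 2D Gaussian spot fitted to an image patch:
#' center, per-axis size, a correlation-type rotation parameter in (-1, 1),
#' signal and background intensities, and the posterior standard deviation of
#' the center reported as localization error.
#'
#' @slot center fitted center (x, y) in pixel coordinates.
#' @slot size spot size (Lx, Ly) in pixels.
#' @slot theta rotation/correlation parameter in (-1, 1).
#' @slot intensity peak signal above background.
#' @slot background constant background level.
#' @slot locError posterior sd of (x, y) center, pixels.
#' @slot converged TRUE when the fit is usable.
#' @slot details list of fit diagnostics.
#' @export
setClass("SpotFit",
  representation(center = "numeric", size = "numeric", theta = "numeric",
                 intensity = "numeric", background = "numeric",
                 locError = "numeric", converged = "logical",
                 details = "list"))

#' Two-channel affine alignment
#'
#' Composition scaling x translation x rotation x re-centering, stored with
#' its raw parameters and the composed 3x3 homogeneous matrix mapping
#' channel-2 pixel coordinates into the channel-1 frame.
#'
#' @slot scale (sx, sy) scale factors.
#' @slot translation (dx, dy) pixels.
#' @slot center (cx, cy) rotation center, pixels.
#' @slot theta rotation angle, radians.
#' @slot width,height image dimensions in pixels.
#' @slot matrix composed 3x3 matrix.
#' @export
setClass("ChannelAlignment",
  representation(scale = "numeric", translation = "numeric",
                 center = "numeric", theta = "numeric",
                 width = "numeric", height = "numeric", matrix = "matrix"))

setValidity("ChannelAlignment", function(object) {
  if (any(object@scale <= 0)) return("scale factors must be positive")
  if (abs(det(object@matrix)) < 1e-12)
    return("composed matrix must be invertible")
  TRUE
})
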