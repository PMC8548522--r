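#' Fractional Brownian motion covariance kernel
#'
#' Evaluates the FBM kernel
#' \deqn{\Sigma(t, t') = D (|t|^\alpha + |t'|^\alpha - |t - t'|^\alpha)}
#' on a grid of time pairs. With \eqn{\alpha = 1} this reduces to the Brownian
#' kernel \eqn{2 D \min(t, t')}; the implied mean squared displacement is
#' \eqn{2 n D t^\alpha} for \eqn{n} spatial degrees of freedom.
#'
#' @param timesA,timesB numeric vectors of non-negative times (seconds);
#'   `timesB` defaults to `timesA`, giving a symmetric matrix.
#' @param D apparent diffusion coefficient (> 0).
#' @param alpha anomalous exponent in (0, 2).
#' @return A `length(timesA)` x `length(timesB)` covariance matrix (length^2).
#' @examples
#' fbmCovariance(c(1, 2), D = 0.5, alpha = 1)   # Brownian: 2 D min(t, t')
#' @export
fbmCovariance <- function(timesA, timesB = timesA, D, alpha) {
  .checkParams(D, alpha)
  stopifnot(all(is.finite(timesA)), all(is.finite(timesB)),
            all(timesA >= 0), all(timesB >= 0))
  ta <- abs(timesA)^alpha
  tb <- abs(timesB)^alpha
  D * (outer(ta, rep(1, length(tb))) + outer(rep(1, length(ta)), tb) -
         abs(outer(timesA, timesB, "-"))^alpha)
}

.checkParams <- function(D, alpha) {
  if (!is.finite(D) || D <= 0)
    stop("D must be positive and finite", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 2)
    stop("alpha must lie strictly inside (0, 2)", call. = FALSE)
  invisible(TRUE)
}

#' Add localization-error variances to a covariance matrix
#'
#' Measurement noise that is decorrelated across time points and normally
#' distributed enters the model as the diagonal term \eqn{\sigma_i^2
#' \delta_{ij}}; off-diagonal entries are untouched.
#'
#' @param cov square covariance matrix.
#' @param sigmas localization error standard deviations: scalar (broadcast) or
#'   one per row of `cov`.
#' @return `cov + diag(sigmas^2)`.
#' @export
addLocalizationNoise <- function(cov, sigmas) {
  n <- nrow(cov)
  if (ncol(cov) != n) stop("cov must be square", call. = FALSE)
  if (length(sigmas) == 1L) sigmas <- rep(sigmas, n)
  if (length(sigmas) != n)
    stop("length(sigmas) must equal the covariance dimension", call. = FALSE)
  cov + diag(sigmas^2, n)
}

# relative jitter applied before every Cholesky factorization
.JITTER <- 1e-10

# --- anchored-likelihood machinery ------------------------------------------
#
# Trajectories are re-referenced so their first observed point is the anchor:
# the likelihood acts on displacements y_i = r(t_i) - r(t_0) observed at times
# t_i (absolute), with the anchor time kept so that multi-particle substrate
# terms with different anchors stay exact. The cache pools every |t_i - t_j|,
# |t_i - anchor| and |anchor - anchor| value once so each parameter evaluation
# needs only O(#unique) pow calls (times on a regular frame grid have few
# unique lags).

.likCache <- function(trajs) {
  K <- length(trajs)
  anchors <- vapply(trajs, function(tr) tr@times[1L], 0)
  yl <- list(); sl <- list(); tl <- list(); blk <- integer(0)
  for (k in seq_len(K)) {
    tr <- trajs[[k]]
    if (nPoints(tr) < 2L)
      stop("trajectory '", tr@trackId,
           "' has no displacements after anchoring", call. = FALSE)
    yl[[k]] <- sweep(tr@coords[-1L, , drop = FALSE], 2L, tr@coords[1L, ])
    sl[[k]] <- tr@locErrors[-1L, , drop = FALSE]^2
    tl[[k]] <- tr@times[-1L]
    blk <- c(blk, rep(k, length(tl[[k]])))
  }
  tt <- unlist(tl)
  n <- length(tt)
  dlag <- abs(outer(tt, tt, "-"))
  dA <- abs(outer(tt, anchors, "-"))
  dAA <- abs(outer(anchors, anchors, "-"))
  V <- unique(c(dlag, dA, dAA))
  list(Y = do.call(rbind, yl), SIG2 = do.call(rbind, sl),
       blk = as.integer(blk), V = V,
       ILAG = matrix(match(dlag, V), n, n),
       IA = matrix(match(dA, V), n, K),
       IAA = matrix(match(dAA, V), K, K),
       n = n, d = ncol(yl[[1L]]), K = K,
       anchors = anchors,
       r0 = do.call(rbind, lapply(trajs, function(tr) tr@coords[1L, ])),
       times = tt)
}

# log-likelihood for a parameter setting on a prepared cache.
# D, alpha: length-K particle parameters; MU: K x d mean offsets;
# substrate (DR, aR) included when useR is TRUE.
.cacheLogLik <- function(cache, D, alpha, MU, DR = 0, aR = 1, useR = FALSE) {
  .cppJointLogLik(cache$Y, cache$SIG2, cache$blk, cache$V, cache$ILAG,
                  cache$IA, cache$IAA, as.numeric(D), as.numeric(alpha),
                  DR, aR, useR, MU)
}

.muMatrix <- function(mu, K, d) {
  mu <- as.numeric(mu)
  if (length(mu) == 1L) mu <- rep(mu, d)
  matrix(mu, K, d, byrow = TRUE)
}

#' Exact FBM log-likelihood of one trajectory
#'
#' Computes the multivariate normal log-density of the anchored displacements
#' \eqn{y_i = r(t_i) - r(t_0)} under the FBM kernel with the trajectory's
#' per-point localization-error variances on the diagonal. Spatial dimensions
#' are independent processes sharing \eqn{(D, \alpha)} with a free constant
#' mean per dimension; the total is the sum over dimensions. A relative jitter
#' of `1e-10 * max(diag)` stabilizes the Cholesky factorization.
#'
#' @param traj a [Trajectory-class] with at least 2 points.
#' @param params a [DiffusionParams-class]; `mu` is recycled across dimensions
#'   if scalar.
#' @return Log-likelihood in nats (`-Inf` if the covariance is numerically
#'   singular even after jitter).
#' @examples
#' tr <- simulateFBM(nPoints = 50, dt = 0.5, D = 1, alpha = 0.8, seed = 1)
#' trajLogLikelihood(tr, DiffusionParams(1, 0.8))
#' @export
trajLogLikelihood <- function(traj, params) {
  stopifnot(is(traj, "Trajectory"), is(params, "DiffusionParams"))
  if (nPoints(traj) < 2L)
    stop("need at least two points (anchor + one displacement)",
         call. = FALSE)
  cache <- .likCache(list(traj))
  ll <- .cacheLogLik(cache, params@D, params@alpha,
                     .muMatrix(params@mu, 1L, cache$d))
  if (!is.finite(ll) && ll == -Inf)
    warning("covariance not positive definite after jitter")
  ll
}

#' Joint covariance matrix of a substrate-coupled ensemble
#'
#' Assembles the block covariance of K stacked anchored trajectories whose
#' observed motion is particle FBM plus one shared substrate FBM: diagonal
#' blocks \eqn{\Sigma_k + \Sigma_R + diag(\sigma^2)}, off-diagonal blocks
#' \eqn{\Sigma_R} evaluated on the cross pairs of observation times. Each
#' particle's block is built on its own (possibly occluded) time grid; no
#' common grid is required.
#'
#' @param ensemble an [FbmEnsemble-class].
#' @param dim which spatial dimension's localization errors to place on the
#'   diagonal (default 1).
#' @return The joint covariance matrix, rows ordered by particle then time.
#' @export
ensembleCovariance <- function(ensemble, dim = 1L) {
  stopifnot(is(ensemble, "FbmEnsemble"))
  cache <- .likCache(ensemble@trajectories)
  D <- vapply(ensemble@particleParams, function(p) p@D, 0)
  A <- vapply(ensemble@particleParams, function(p) p@alpha, 0)
  C <- .cppJointCov(cache$blk, cache$V, cache$ILAG, cache$IA, cache$IAA,
                    D, A, ensemble@substrateParams@D,
                    ensemble@substrateParams@alpha, TRUE)
  diag(C) <- diag(C) + cache$SIG2[, dim]
  C
}

#' Joint log-likelihood of a substrate-coupled ensemble
#'
#' Exact multivariate normal log-density of the stacked, mean-subtracted
#' anchored trajectories under the joint covariance of
#' [ensembleCovariance()], summed over spatial dimensions. In the
#' \eqn{D_R \to 0} limit it factorizes into the sum of per-particle
#' [trajLogLikelihood()] values.
#'
#' @param ensemble an [FbmEnsemble-class] carrying particle and substrate
#'   parameters.
#' @return Log-likelihood in nats.
#' @export
ensembleLogLikelihood <- function(ensemble) {
  stopifnot(is(ensemble, "FbmEnsemble"))
  cache <- .likCache(ensemble@trajectories)
  D <- vapply(ensemble@particleParams, function(p) p@D, 0)
  A <- vapply(ensemble@particleParams, function(p) p@alpha, 0)
  MU <- do.call(rbind, lapply(ensemble@particleParams, function(p) {
    mu <- p@mu
    if (length(mu) == 1L) mu <- rep(mu, cache$d)
    mu
  }))
  .cacheLogLik(cache, D, A, MU, ensemble@substrateParams@D,
               ensemble@substrateParams@alpha, TRUE)
}
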