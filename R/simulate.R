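# Exact FBM simulation by Cholesky factorization of the full kernel matrix
# (trajectories of a few hundred points make this the simplest exact sampler;
# no circulant embedding needed at this scale).

# independent sub-seeds for path / noise / occlusion so each corruption stage
# is separately reproducible
.subSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate an exact FBM trajectory
#'
#' Draws a clean trajectory from the Gaussian process with FBM kernel on the
#' regular grid \eqn{t = 0, dt, \ldots, (n-1) dt}. The position at \eqn{t = 0}
#' is the process origin (exactly zero); later positions are an exact
#' multivariate normal draw via Cholesky factorization of the kernel matrix,
#' independently per dimension.
#'
#' @param nPoints number of time points including the origin (>= 2).
#' @param dt frame interval in seconds (> 0).
#' @param D apparent diffusion coefficient (> 0).
#' @param alpha anomalous exponent in (0, 2).
#' @param nDims number of spatial dimensions (default 2).
#' @param seed integer seed; identical seeds give bit-identical trajectories.
#' @param trackId,groupId identifiers passed to the [Trajectory-class].
#' @return A clean (noiseless, un-occluded) [Trajectory-class].
#' @examples
#' tr <- simulateFBM(nPoints = 100, dt = 0.5, D = 0.5, alpha = 0.7, seed = 3)
#' @export
simulateFBM <- function(nPoints = 250L, dt = 0.5, D = 1, alpha = 1,
                        nDims = 2L, seed = 1L, trackId = "sim1",
                        groupId = "group1") {
  .checkParams(D, alpha)
  if (nPoints < 2L) stop("nPoints must be at least 2", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  times <- (seq_len(nPoints) - 1L) * dt
  K <- fbmCovariance(times[-1L], D = D, alpha = alpha)
  diag(K) <- diag(K) + .JITTER * max(diag(K))
  L <- chol(K)
  set.seed(as.integer(seed))
  z <- matrix(rnorm((nPoints - 1L) * nDims), nPoints - 1L, nDims)
  pos <- rbind(matrix(0, 1L, nDims), crossprod(L, z))
  Trajectory(times = times, coords = pos, trackId = trackId,
             groupId = groupId)
}

#' Corrupt a trajectory with localization noise and occlusions
#'
#' Adds i.i.d. Gaussian noise of standard deviation `sigma` to every
#' coordinate and removes a uniformly random subset of non-anchor points
#' (`round(occlusionRate * (n - 1))` of them, without replacement). The
#' anchor (first) point is never removed. The applied `sigma` is recorded in
#' the `locErrors` slot. Noise and occlusion use independent random streams
#' derived from `seed`.
#'
#' @param traj a [Trajectory-class].
#' @param sigma localization noise standard deviation (>= 0); scalar or one
#'   value per dimension.
#' @param occlusionRate fraction of non-anchor points to remove, in [0, 0.8].
#' @param seed integer seed.
#' @return The corrupted [Trajectory-class].
#' @export
corruptTrajectory <- function(traj, sigma = 0, occlusionRate = 0, seed = 1L) {
  stopifnot(is(traj, "Trajectory"))
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  if (occlusionRate < 0 || occlusionRate > 0.8)
    stop("occlusionRate must lie in [0, 0.8]", call. = FALSE)
  n <- nPoints(traj)
  d <- nDims(traj)
  ss <- .subSeeds(seed, 2L)
  pos <- traj@coords
  if (any(sigma > 0)) {
    set.seed(ss[1L])
    pos <- pos + matrix(rnorm(n * d, sd = rep(sigma, each = n)), n, d)
  }
  keep <- seq_len(n)
  nRemove <- round(occlusionRate * (n - 1L))
  if (nRemove > 0L) {
    set.seed(ss[2L])
    drop <- sample(2:n, nRemove)
    keep <- setdiff(keep, drop)
  }
  Trajectory(times = traj@times[keep], coords = pos[keep, , drop = FALSE],
             locErrors = matrix(rep(sigma, each = length(keep)),
                                length(keep), d),
             trackId = traj@trackId, groupId = traj@groupId,
             frames = traj@frames[keep])
}

#' Simulate a substrate-coupled ensemble
#'
#' Generates K independent particle FBM paths \eqn{a_k(t)} and one substrate
#' FBM path \eqn{R(t)} on a shared grid, observes \eqn{r_k(t) = a_k(t) +
#' R(t)}, then corrupts each observed trajectory independently with noise and
#' occlusion. The returned ground truth keeps the clean particle paths, the
#' substrate path, and all generating parameters.
#'
#' @param D,alpha numeric vectors (length K >= 2) of particle parameters.
#' @param substrateD,substrateAlpha substrate FBM parameters (`substrateD`
#'   must be > 0; pass e.g. `1e-12` for an effectively static substrate).
#' @param nPoints,dt shared time grid.
#' @param sigma localization noise sd applied to each particle.
#' @param occlusionRate fraction of non-anchor points occluded per particle.
#' @param nDims spatial dimensions.
#' @param seed integer seed.
#' @param groupId group identifier shared by the ensemble.
#' @return A list with elements `ensemble` (an [FbmEnsemble-class] holding the
#'   observed corrupted trajectories and the true generating parameters) and
#'   `truth` (list: `particles` clean a_k paths, `substrate` the R path,
#'   `observedClean` the clean r_k = a_k + R paths, plus parameters and seed).
#' @export
simulateEnsemble <- function(D, alpha, substrateD, substrateAlpha,
                             nPoints = 250L, dt = 0.5, sigma = 0.1,
                             occlusionRate = 0.1, nDims = 2L, seed = 1L,
                             groupId = "cell1") {
  K <- length(D)
  if (K < 2L) stop("an ensemble needs at least two particles", call. = FALSE)
  if (length(alpha) != K) stop("alpha must match length(D)", call. = FALSE)
  .checkParams(substrateD, substrateAlpha)
  ss <- .subSeeds(seed, K + 2L)
  particles <- lapply(seq_len(K), function(k) {
    simulateFBM(nPoints, dt, D[k], alpha[k], nDims, seed = ss[k],
                trackId = sprintf("p%d", k), groupId = groupId)
  })
  substrate <- simulateFBM(nPoints, dt, substrateD, substrateAlpha, nDims,
                           seed = ss[K + 1L], trackId = "substrate",
                           groupId = groupId)
  corruptSeeds <- .subSeeds(ss[K + 2L], K)
  observedClean <- vector("list", K)
  observed <- vector("list", K)
  for (k in seq_len(K)) {
    clean <- Trajectory(times = particles[[k]]@times,
                        coords = particles[[k]]@coords + substrate@coords,
                        trackId = sprintf("p%d", k), groupId = groupId,
                        frames = particles[[k]]@frames)
    observedClean[[k]] <- clean
    observed[[k]] <- corruptTrajectory(clean, sigma, occlusionRate,
                                       seed = corruptSeeds[k])
  }
  ens <- FbmEnsemble(observed,
                     particleParams = lapply(seq_len(K), function(k)
                       DiffusionParams(D[k], alpha[k], rep(0, nDims))),
                     substrateParams = DiffusionParams(substrateD,
                                                       substrateAlpha,
                                                       rep(0, nDims)))
  list(ensemble = ens,
       truth = list(particles = particles, substrate = substrate,
                    observedClean = observedClean, D = D, alpha = alpha,
                    substrateD = substrateD,
                    substrateAlpha = substrateAlpha, sigma = sigma,
                    occlusionRate = occlusionRate, seed = seed))
}

#' Default benchmark parameter ranges
#'
#' Uniform sampling ranges used by [benchmarkDataset()]: apparent diffusion
#' coefficient in (0.01, 1.5), anomalous exponent in (0.01, 1.9), frame
#' interval in (0.1, 1.0) s, localization noise sd in (0.001, 0.25), and
#' occlusion fraction in (0, 0.8).
#'
#' @return A named list of length-2 numeric ranges.
#' @export
benchmarkRanges <- function() {
  list(D = c(0.01, 1.5), alpha = c(0.01, 1.9), dt = c(0.1, 1.0),
       sigma = c(0.001, 0.25), occlusion = c(0, 0.8))
}

#' Generate a benchmark dataset with ground truth
#'
#' Draws `nTraj` independent parameter settings uniformly from `ranges`
#' (redrawn per trajectory, including the frame interval), simulates a clean
#' FBM trajectory for each, and corrupts it with the drawn localization noise
#' and occlusion rate. Fully reproducible from `seed`.
#'
#' @param nTraj number of trajectories (>= 1).
#' @param ranges named list as returned by [benchmarkRanges()].
#' @param nPoints points per trajectory before occlusion (default 250).
#' @param nDims spatial dimensions (default 2).
#' @param seed integer seed.
#' @return A list of records, each with elements `traj` (corrupted
#'   [Trajectory-class]), `clean` (the noiseless full trajectory), and the
#'   generating `D`, `alpha`, `dt`, `sigma`, `occlusion`, `seed`.
#' @export
benchmarkDataset <- function(nTraj, ranges = benchmarkRanges(),
                             nPoints = 250L, nDims = 2L, seed = 1L) {
  if (nTraj < 1L) stop("nTraj must be at least 1", call. = FALSE)
  need <- c("D", "alpha", "dt", "sigma", "occlusion")
  if (!all(need %in% names(ranges)) ||
      any(vapply(ranges[need], length, 0L) != 2L))
    stop("ranges must contain length-2 entries ", paste(need, collapse = ", "),
         call. = FALSE)
  set.seed(as.integer(seed))
  draws <- vapply(need, function(p) runif(nTraj, ranges[[p]][1L],
                                          ranges[[p]][2L]),
                  numeric(nTraj))
  draws <- matrix(draws, nrow = nTraj,
                  dimnames = list(NULL, need))
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * nTraj)
  lapply(seq_len(nTraj), function(i) {
    clean <- simulateFBM(nPoints, draws[i, "dt"], draws[i, "D"],
                         draws[i, "alpha"], nDims, seed = seeds[2L * i - 1L],
                         trackId = sprintf("bench%04d", i))
    traj <- corruptTrajectory(clean, draws[i, "sigma"],
                              draws[i, "occlusion"], seed = seeds[2L * i])
    list(traj = traj, clean = clean, D = draws[i, "D"],
         alpha = draws[i, "alpha"], dt = draws[i, "dt"],
         sigma = draws[i, "sigma"], occlusion = draws[i, "occlusion"],
         seed = seeds[2L * i - 1L])
  })
}
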