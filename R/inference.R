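# Parameters are optimized and sampled in the unconstrained space
#   theta = (log D, log(alpha / (2 - alpha)), mu...)
# with flat priors taken in the natural (D, alpha, mu) space; the MAP is the
# likelihood optimum, while Metropolis-Hastings in theta carries the Jacobian
# log D + log(alpha (2 - alpha) / 2) explicitly.

.toAlpha <- function(la) 2 * plogis(la)
.fromAlpha <- function(alpha) qlogis(alpha / 2)

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# moment-based (log D, logit alpha) start from a quick MSD power-law fit
.momentInit <- function(traj) {
  d <- nDims(traj)
  init <- tryCatch({
    curve <- msdCurve(traj)
    sig <- sqrt(mean(traj@locErrors^2))
    p <- suppressWarnings(fitMSD(curve, sigmaMean = sig))
    c(log(p@D), .fromAlpha(p@alpha))
  }, error = function(e) NULL)
  if (is.null(init) || any(!is.finite(init))) {
    dtbar <- mean(diff(traj@times))
    msd1 <- mean(rowSums(diff(traj@coords)^2))
    D0 <- max(msd1 / (2 * d * dtbar), 1e-6)
    init <- c(log(D0), 0)
  }
  c(.clip(init[1L], -10, 10), .clip(init[2L], -5, 5))
}

#' Maximum a posteriori fit of FBM diffusion parameters
#'
#' Maximizes the exact GP log-likelihood of one trajectory (flat priors, so
#' the posterior mode equals the likelihood optimum) over
#' \eqn{(\log D, \mathrm{logit}(\alpha/2), \mu)} with the Nelder-Mead
#' simplex, using a moment-based start from a quick MSD fit plus
#' deterministically perturbed restarts; the best final value wins, ties
#' broken toward the lower anomalous exponent.
#'
#' @param traj a [Trajectory-class].
#' @param minPoints minimum number of usable displacements (default 5).
#' @param nStarts number of optimizer starts (default 3).
#' @param maxit,reltol Nelder-Mead control.
#' @return An [FbmFit-class]; `flagged` is TRUE when no start converged
#'   cleanly (the best point found is still returned).
#' @examples
#' tr <- corruptTrajectory(simulateFBM(150, 0.5, 1, 1, seed = 5), 0.1, 0.1, 5)
#' fit <- fitTrajectory(tr)
#' diffusionCoef(fit); anomalousExponent(fit)
#' @export
fitTrajectory <- function(traj, minPoints = 5L, nStarts = 3L, maxit = 500L,
                          reltol = 1e-7) {
  stopifnot(is(traj, "Trajectory"))
  if (nPoints(traj) - 1L < minPoints)
    stop("trajectory has fewer than ", minPoints,
         " usable displacements", call. = FALSE)
  cache <- .likCache(list(traj))
  d <- cache$d
  nll <- function(theta) {
    ll <- .cacheLogLik(cache, exp(theta[1L]), .toAlpha(theta[2L]),
                       matrix(theta[3:(2 + d)], 1L, d))
    if (is.finite(ll)) -ll else 1e12
  }
  mu0 <- colMeans(cache$Y)
  base <- .momentInit(traj)
  offsets <- list(c(0, 0), c(0.9, 0.7), c(-0.9, -0.7), c(1.8, -1.2),
                  c(-1.8, 1.2))
  # the moment-based start gets the full budget; perturbed restarts run a
  # short exploratory simplex and are polished only when they find a better
  # basin (deterministic, so refits are bit-identical)
  fits <- lapply(seq_len(max(1L, nStarts)), function(i) {
    start <- c(base + offsets[[((i - 1L) %% length(offsets)) + 1L]], mu0)
    optim(start, nll, method = "Nelder-Mead",
          control = list(maxit = if (i == 1L) maxit else maxit %/% 4L,
                         reltol = reltol))
  })
  for (i in seq_along(fits)[-1L]) {
    if (fits[[i]]$value < fits[[1L]]$value - 1e-2)
      fits[[i]] <- optim(fits[[i]]$par, nll, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = reltol))
  }
  vals <- vapply(fits, `[[`, 0, "value")
  alphas <- vapply(fits, function(f) .toAlpha(f$par[2L]), 0)
  best <- order(vals, alphas)[1L]
  f <- fits[[best]]
  new("FbmFit",
      params = DiffusionParams(exp(f$par[1L]), .toAlpha(f$par[2L]),
                               f$par[3:(2 + d)]),
      logPost = -f$value, convergence = as.integer(f$convergence),
      nUsed = cache$n,
      flagged = all(vapply(fits, `[[`, 0L, "convergence") != 0L),
      details = list(startValues = vals, startAlphas = alphas, best = best))
}

#' Metropolis-Hastings posterior sampling of diffusion parameters
#'
#' Random-walk MH in the unconstrained parameter space, one Gaussian proposal
#' per coordinate per sweep, targeting the posterior with flat priors in the
#' natural \eqn{(D, \alpha, \mu)} space (the change-of-variables Jacobian is
#' included explicitly). Proposal scales are adapted during burn-in toward
#' 20-40% per-coordinate acceptance and then frozen; the chain is fully
#' reproducible from `seed`.
#'
#' @param traj a [Trajectory-class].
#' @param nSamples sweeps kept after burn-in (default 10000).
#' @param burnIn discarded adaptation sweeps (default 2000).
#' @param seed integer seed.
#' @param mapFit optional [FbmFit-class] used to initialize; computed
#'   internally when missing.
#' @return A [PosteriorChain-class] with samples in natural units.
#' @export
samplePosterior <- function(traj, nSamples = 10000L, burnIn = 2000L,
                            seed = 1L, mapFit = NULL) {
  stopifnot(is(traj, "Trajectory"))
  if (is.null(mapFit)) mapFit <- fitTrajectory(traj)
  cache <- .likCache(list(traj))
  d <- cache$d
  p <- 2L + d
  logPost <- function(theta) {
    a <- .toAlpha(theta[2L])
    ll <- .cacheLogLik(cache, exp(theta[1L]), a,
                       matrix(theta[3:(2 + d)], 1L, d))
    if (!is.finite(ll)) return(-Inf)
    ll + theta[1L] + log(a * (2 - a) / 2)
  }
  theta <- c(log(mapFit@params@D), .fromAlpha(mapFit@params@alpha),
             mapFit@params@mu)
  scales <- c(0.15, 0.15, rep(0.1, d))
  set.seed(as.integer(seed))
  lp <- logPost(theta)
  nTot <- burnIn + nSamples
  keep <- matrix(NA_real_, nSamples, p)
  keepLp <- numeric(nSamples)
  accWin <- accTot <- numeric(p)
  nWin <- 0L
  nPost <- 0L
  for (it in seq_len(nTot)) {
    for (j in seq_len(p)) {
      prop <- theta
      prop[j] <- prop[j] + rnorm(1L, sd = scales[j])
      lpProp <- logPost(prop)
      if (is.finite(lpProp) && log(runif(1L)) < lpProp - lp) {
        theta <- prop; lp <- lpProp
        accWin[j] <- accWin[j] + 1
        if (it > burnIn) accTot[j] <- accTot[j] + 1
      }
    }
    nWin <- nWin + 1L
    if (it <= burnIn && nWin == 50L) {
      rate <- accWin / nWin
      scales <- .clip(scales * exp(rate - 0.3), 1e-4, 10)
      accWin[] <- 0; nWin <- 0L
    }
    if (it > burnIn) {
      nPost <- nPost + 1L
      keep[nPost, ] <- c(exp(theta[1L]), .toAlpha(theta[2L]),
                         theta[3:(2 + d)])
      keepLp[nPost] <- lp
    }
  }
  rate <- sum(accTot) / (as.numeric(nSamples) * p)
  if (rate <= 0 || rate >= 1) {
    warning("degenerate acceptance rate (", signif(rate, 3),
            "); chain flagged as divergent")
    rate <- .clip(rate, 1e-9, 1 - 1e-9)
  }
  colnames(keep) <- c("D", "alpha", paste0("mu.", seq_len(d)))
  new("PosteriorChain", samples = keep, logPost = keepLp,
      acceptanceRate = rate, burnIn = as.integer(burnIn),
      seed = as.integer(seed))
}

# thin a trajectory keeping the anchor; used by the staged ensemble optimizer
.thinTraj <- function(tr, by = 2L) {
  idx <- unique(c(1L, seq(1L, nPoints(tr), by = by)))
  Trajectory(times = tr@times[idx], coords = tr@coords[idx, , drop = FALSE],
             locErrors = tr@locErrors[idx, , drop = FALSE],
             trackId = tr@trackId, groupId = tr@groupId,
             frames = tr@frames[idx])
}

# empirical cross-MSD power-law start for the substrate parameters
.substrateInit <- function(trajs, fallbackD) {
  d <- nDims(trajs[[1L]])
  xs <- list(); ts <- list()
  K <- length(trajs)
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    ti <- trajs[[i]]; tj <- trajs[[j]]
    common <- intersect(ti@frames, tj@frames)
    if (length(common) < 10L) next
    ii <- match(common, ti@frames); jj <- match(common, tj@frames)
    yi <- sweep(ti@coords[ii, , drop = FALSE], 2L, ti@coords[ii[1L], ])
    yj <- sweep(tj@coords[jj, , drop = FALSE], 2L, tj@coords[jj[1L], ])
    tv <- ti@times[ii] - ti@times[ii[1L]]
    lag <- seq(2L, length(common), by = max(1L, length(common) %/% 12L))
    xs[[length(xs) + 1L]] <- rowSums(yi[lag, , drop = FALSE] *
                                       yj[lag, , drop = FALSE])
    ts[[length(ts) + 1L]] <- tv[lag]
  }
  cx <- unlist(xs); ct <- unlist(ts)
  ok <- is.finite(cx) & cx > 0 & ct > 0
  if (sum(ok) >= 3L) {
    fit <- lm(log(cx[ok]) ~ log(ct[ok]))
    aR <- .clip(coef(fit)[[2L]], 0.05, 1.95)
    DR <- exp(coef(fit)[[1L]]) / (2 * d)
    c(log(.clip(DR, 1e-6, 1e4)), .fromAlpha(aR))
  } else c(log(max(fallbackD, 1e-6)), 0)
}

#' Joint substrate-corrected fit of a particle ensemble
#'
#' Jointly maximizes the exact multi-particle GP likelihood in which each
#' observed trajectory is its own FBM plus one FBM substrate process common to
#' the group, over all particle parameters \eqn{(D_k, \alpha_k, \mu_k)} and
#' the substrate \eqn{(D_R, \alpha_R)}. Initialization comes from the
#' per-particle fits (also returned, as the uncorrected comparison) and an
#' empirical cross-correlation power-law fit for the substrate. For long
#' trajectories the simplex first runs on a 2x time-thinned ensemble and the
#' full-resolution data only polish that optimum.
#'
#' @param trajs list of 2-5 [Trajectory-class] objects with overlapping
#'   observation windows (same cell/group).
#' @param minPoints minimum usable displacements per trajectory.
#' @param maxit Nelder-Mead iteration cap for the joint stage (default scales
#'   with the number of parameters).
#' @param thinStage logical; use the thinned first stage for speed (default
#'   TRUE when the stacked size exceeds 320 points).
#' @return An [FbmEnsembleFit-class]. If the observation windows do not
#'   overlap the fit falls back to independent particles (warning, `flagged`).
#' @export
fitEnsemble <- function(trajs, minPoints = 5L, maxit = NULL,
                        thinStage = NULL) {
  stopifnot(is.list(trajs), length(trajs) >= 2L)
  if (length(trajs) > 5L)
    warning("ensembles beyond 5 particles are computationally heavy")
  K <- length(trajs)
  d <- nDims(trajs[[1L]])
  uncorrected <- lapply(trajs, fitTrajectory, minPoints = minPoints)

  lo <- vapply(trajs, function(tr) min(tr@times), 0)
  hi <- vapply(trajs, function(tr) max(tr@times), 0)
  if (max(lo) >= min(hi)) {
    warning("observation windows do not overlap; falling back to ",
            "independent per-particle fits")
    ens <- FbmEnsemble(trajs,
                       lapply(uncorrected, function(f) f@params),
                       DiffusionParams(1e-12, 1, rep(0, d)))
    return(new("FbmEnsembleFit", ensemble = ens, uncorrected = uncorrected,
               logPost = sum(vapply(uncorrected, function(f) f@logPost, 0)),
               convergence = 1L, flagged = TRUE,
               details = list(fallback = "no-overlap")))
  }

  idxD <- seq(1L, 2L * K, by = 2L)
  idxA <- idxD + 1L
  idxMu <- 2L * K + seq_len(K * d)
  p <- 2L * K + K * d + 2L
  makeNll <- function(cache) {
    function(theta) {
      ll <- .cacheLogLik(cache, exp(theta[idxD]), .toAlpha(theta[idxA]),
                         matrix(theta[idxMu], K, d, byrow = TRUE),
                         exp(theta[p - 1L]), .toAlpha(theta[p]), TRUE)
      if (is.finite(ll)) -ll else 1e12
    }
  }
  theta0 <- numeric(p)
  theta0[idxD] <- vapply(uncorrected, function(f) log(f@params@D), 0)
  theta0[idxA] <- vapply(uncorrected,
                         function(f) .fromAlpha(f@params@alpha), 0)
  theta0[idxMu] <- as.numeric(t(vapply(uncorrected,
                                       function(f) f@params@mu,
                                       numeric(d))))
  theta0[c(p - 1L, p)] <- .substrateInit(
    trajs, 0.2 * min(exp(theta0[idxD])))

  if (is.null(maxit)) maxit <- 250L + 40L * p
  nTot <- sum(vapply(trajs, nPoints, 0L)) - K
  if (is.null(thinStage)) thinStage <- nTot > 320L
  if (thinStage) {
    thinCache <- .likCache(lapply(trajs, .thinTraj))
    st1 <- optim(theta0, makeNll(thinCache), method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-7))
    theta0 <- st1$par
    maxitFull <- 150L + 8L * p
  } else maxitFull <- maxit
  fit <- optim(theta0, makeNll(.likCache(trajs)), method = "Nelder-Mead",
               control = list(maxit = maxitFull, reltol = 1e-7))

  th <- fit$par
  ens <- FbmEnsemble(
    trajs,
    lapply(seq_len(K), function(k)
      DiffusionParams(exp(th[idxD[k]]), .toAlpha(th[idxA[k]]),
                      th[idxMu[(k - 1L) * d + seq_len(d)]])),
    DiffusionParams(exp(th[p - 1L]), .toAlpha(th[p]), rep(0, d)))
  new("FbmEnsembleFit", ensemble = ens, uncorrected = uncorrected,
      logPost = -fit$value, convergence = as.integer(fit$convergence),
      flagged = FALSE,
      details = list(nParams = p, thinStage = thinStage,
                     counts = fit$counts))
}

.cholSolve <- function(ch, b) backsolve(ch, forwardsolve(t(ch), b))

#' GP interpolation of a trajectory with credible band
#'
#' Standard Gaussian-process conditioning under the FBM kernel: given fitted
#' (or supplied) diffusion parameters, returns the posterior mean path and
#' pointwise credible band of the latent (noise-free) position at arbitrary
#' query times at or after the anchor. At a noiselessly observed time the mean
#' passes through the observation with a zero-width band; at the anchor it
#' returns the anchor position.
#'
#' @param traj a [Trajectory-class].
#' @param params a [DiffusionParams-class] (e.g. `fittedParams(fitTrajectory(traj))`).
#' @param queryTimes numeric times (seconds), all `>= min(timePoints(traj))`.
#' @param level credible level (default 0.95, i.e. mean +- 1.96 sd).
#' @return An [InterpolatedPath-class].
#' @export
interpolateTrajectory <- function(traj, params, queryTimes, level = 0.95) {
  stopifnot(is(traj, "Trajectory"), is(params, "DiffusionParams"))
  t0 <- traj@times[1L]
  if (any(queryTimes < t0))
    stop("query times before the anchor time are outside the model domain",
         call. = FALSE)
  s <- traj@times[-1L] - t0
  q <- queryTimes - t0
  y <- sweep(traj@coords[-1L, , drop = FALSE], 2L, traj@coords[1L, ])
  sig2 <- traj@locErrors[-1L, , drop = FALSE]^2
  d <- ncol(y)
  mu <- params@mu
  if (length(mu) == 1L) mu <- rep(mu, d)
  K0 <- fbmCovariance(s, D = params@D, alpha = params@alpha)
  kq <- fbmCovariance(q, s, D = params@D, alpha = params@alpha)
  priorVar <- 2 * params@D * q^params@alpha
  m <- matrix(NA_real_, length(q), d)
  v <- matrix(NA_real_, length(q), d)
  shared <- d == 1L || all(sig2 == sig2[, 1L])
  for (j in seq_len(d)) {
    if (j == 1L || !shared) {
      Kj <- K0
      diag(Kj) <- diag(Kj) + sig2[, j] + .JITTER * max(diag(K0))
      ch <- chol(Kj)
      sol <- .cholSolve(ch, t(kq))
      vj <- pmax(priorVar - colSums(t(kq) * sol), 0)
    }
    m[, j] <- traj@coords[1L, j] + mu[j] +
      as.numeric(kq %*% .cholSolve(ch, y[, j] - mu[j]))
    v[, j] <- vj
  }
  hw <- qnorm((1 + level) / 2) * sqrt(v)
  new("InterpolatedPath", times = as.numeric(queryTimes), mean = m,
      lower = m - hw, upper = m + hw, level = level)
}

#' Reconstruct the shared substrate path of an ensemble
#'
#' Conditional mean and pointwise credible band of the substrate displacement
#' given all particle trajectories, evaluated on the times observed by every
#' particle: with per-particle (noise-inclusive) covariances
#' \eqn{\Sigma_k} and substrate covariance \eqn{\Sigma_R},
#' \deqn{\langle R \rangle = (\Sigma_R^{-1} + \sum_k \Sigma_k^{-1})^{-1}
#'   \sum_k \Sigma_k^{-1} (r_k - \mu_k),}
#' with covariance \eqn{(\Sigma_R^{-1} + \sum_k \Sigma_k^{-1})^{-1}}. The
#' returned path is the substrate displacement relative to the first common
#' time (where it is zero by construction).
#'
#' @param fit an [FbmEnsembleFit-class] or a parameterized
#'   [FbmEnsemble-class].
#' @param level credible level (default 0.95).
#' @return An [InterpolatedPath-class] on the common time grid.
#' @export
inferSubstratePath <- function(fit, level = 0.95) {
  ens <- if (is(fit, "FbmEnsembleFit")) fit@ensemble else fit
  stopifnot(is(ens, "FbmEnsemble"))
  trajs <- ens@trajectories
  K <- length(trajs)
  d <- nDims(trajs[[1L]])
  common <- Reduce(intersect, lapply(trajs, function(tr) tr@frames))
  if (length(common) < 3L)
    stop("particles share fewer than 3 common observation times",
         call. = FALSE)
  ref <- trajs[[1L]]
  idx1 <- match(common, ref@frames)
  gridTimes <- ref@times[idx1]
  s <- gridTimes[-1L] - gridTimes[1L]
  m <- length(s)
  prec <- matrix(0, m, m)
  b <- matrix(0, m, d)
  for (k in seq_len(K)) {
    tr <- trajs[[k]]
    ii <- match(common, tr@frames)
    y <- sweep(tr@coords[ii, , drop = FALSE], 2L, tr@coords[ii[1L], ])[-1L, ,
                                                                       drop = FALSE]
    mu <- ens@particleParams[[k]]@mu
    if (length(mu) == 1L) mu <- rep(mu, d)
    y <- sweep(y, 2L, mu)
    pk <- ens@particleParams[[k]]
    Sk <- fbmCovariance(s, D = pk@D, alpha = pk@alpha)
    diag(Sk) <- diag(Sk) + rowMeans(tr@locErrors[ii, , drop = FALSE]^2)[-1L] +
      .JITTER * max(diag(Sk))
    Pki <- chol2inv(chol(Sk))
    prec <- prec + Pki
    b <- b + Pki %*% y
  }
  SR <- fbmCovariance(s, D = ens@substrateParams@D,
                      alpha = ens@substrateParams@alpha)
  diag(SR) <- diag(SR) + .JITTER * max(max(diag(SR)), 1e-12)
  prec <- prec + chol2inv(chol(SR))
  cp <- chol(prec)
  mean <- .cholSolve(cp, b)
  vars <- pmax(diag(chol2inv(cp)), 0)
  hw <- qnorm((1 + level) / 2) * sqrt(vars)
  mean <- rbind(rep(0, d), mean)
  hwM <- rbind(rep(0, d), matrix(hw, m, d))
  new("InterpolatedPath", times = gridTimes, mean = mean,
      lower = mean - hwM, upper = mean + hwM, level = level)
}
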