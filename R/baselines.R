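# Reference estimators used to benchmark the GP approach: the classic
# sliding-window MSD power-law fit and a displacement-distribution (Rayleigh)
# likelihood fit. Both deliberately split trajectories into displacements and
# discard higher-order temporal correlations.

#' Sliding-window mean squared displacement
#'
#' \deqn{\langle r_n^2 \rangle = \frac{1}{N-n} \sum_i (r_{i+n} - r_i)^2}
#' summed over spatial dimensions, for step intervals up to a fraction of the
#' trajectory length (default the first 10%, where single-trajectory
#' correlations are weakest). Occluded frames are skipped: a pair contributes
#' to lag n only when both endpoints were observed. Lags with no valid pairs
#' are dropped with a warning.
#'
#' @param traj a [Trajectory-class] (>= 10 points).
#' @param maxLagFraction fraction of the frame span used as maximum lag
#'   (default 0.1); at least 3 lags are always attempted.
#' @return An [MSDCurve-class].
#' @examples
#' msdCurve(Trajectory(times = 0:2, coords = c(0, 1, 3)))
#' @export
msdCurve <- function(traj, maxLagFraction = 0.1) {
  stopifnot(is(traj, "Trajectory"))
  fr <- traj@frames
  span <- max(fr) - min(fr)
  dt <- stats::median(diff(traj@times) / diff(fr))
  maxLag <- max(3L, floor(maxLagFraction * (span + 1L)))
  maxLag <- min(maxLag, span)
  pos <- traj@coords
  lags <- integer(0); vals <- numeric(0); cnts <- integer(0)
  for (n in seq_len(maxLag)) {
    j <- match(fr + n, fr)
    ok <- which(!is.na(j))
    if (!length(ok)) next
    dsq <- rowSums((pos[j[ok], , drop = FALSE] - pos[ok, , drop = FALSE])^2)
    lags <- c(lags, n); vals <- c(vals, mean(dsq)); cnts <- c(cnts, length(ok))
  }
  if (length(lags) < maxLag)
    warning(maxLag - length(lags), " lag(s) had no observed pairs and were dropped")
  new("MSDCurve", lags = lags, taus = lags * dt, values = vals,
      counts = cnts, nDims = ncol(pos))
}

#' Fit diffusion parameters to an MSD curve
#'
#' Inverts the power law \eqn{\langle r^2 \rangle = 2 n_{dim} D t^\alpha +
#' 2\sigma^2} by ordinary least squares of \eqn{\log(\langle r^2\rangle -
#' 2\sigma^2)} on \eqn{\log t}: the slope is \eqn{\hat\alpha}, the intercept
#' gives \eqn{\hat D}. Lags whose noise-corrected MSD is non-positive are
#' excluded; fewer than 3 usable lags flags the estimate (attribute
#' `flagged`). A slope outside (0, 2) is clamped to the open interval and
#' also flagged.
#'
#' @param curve an [MSDCurve-class].
#' @param sigmaMean average localization error standard deviation (>= 0).
#' @return A [DiffusionParams-class] (`mu = 0`) with attribute `flagged`.
#' @export
fitMSD <- function(curve, sigmaMean = 0) {
  stopifnot(is(curve, "MSDCurve"), sigmaMean >= 0)
  y <- curve@values - 2 * sigmaMean^2
  ok <- which(y > 0 & curve@taus > 0)
  flagged <- FALSE
  if (length(ok) < 3L) {
    if (length(ok) < 2L)
      stop("fewer than 2 usable lags after noise correction", call. = FALSE)
    flagged <- TRUE
  }
  fit <- lm(log(y[ok]) ~ log(curve@taus[ok]))
  alpha <- coef(fit)[[2L]]
  if (alpha <= 0 || alpha >= 2) {
    alpha <- .clip(alpha, 1e-3, 2 - 1e-3)
    flagged <- TRUE
  }
  D <- exp(coef(fit)[[1L]]) / (2 * curve@nDims)
  out <- DiffusionParams(D, alpha, 0)
  attr(out, "flagged") <- flagged
  out
}

# displacement magnitudes of a 2D trajectory at frame lags 1..maxLag
.displacementSamples <- function(traj, maxLag) {
  fr <- traj@frames
  dt <- stats::median(diff(traj@times) / diff(fr))
  pos <- traj@coords
  out <- list()
  for (n in seq_len(maxLag)) {
    j <- match(fr + n, fr)
    ok <- which(!is.na(j))
    if (!length(ok)) next
    out[[length(out) + 1L]] <- list(
      tau = n * dt,
      r = sqrt(rowSums((pos[j[ok], , drop = FALSE] -
                          pos[ok, , drop = FALSE])^2)))
  }
  out
}

#' Displacement-distribution (Rayleigh) fit of diffusion parameters
#'
#' Pools sliding-window displacement magnitudes of a 2D trajectory at frame
#' lags 1..`maxLag` and maximizes the product over lags and displacements of
#' the radial displacement density
#' \deqn{\rho(r \mid t) = \frac{r}{2 D t^\alpha + \sigma^2}
#'   \exp\!\left(-\frac{r^2}{4 D t^\alpha + 2\sigma^2}\right)}
#' (flat priors in \eqn{(D, \alpha)}). The default is the unbinned
#' per-displacement likelihood, the zero-bin-width limit of a histogram fit;
#' `binned = TRUE` instead maximizes a multinomial likelihood over
#' Freedman-Diaconis histogram bins.
#'
#' @param traj a 2D [Trajectory-class] with at least 10 lag-1 displacements.
#' @param sigmaMean average localization error standard deviation.
#' @param maxLag largest frame lag pooled (default 10).
#' @param binned logical; use the binned multinomial variant.
#' @return A [DiffusionParams-class] (`mu = 0`) with attribute `flagged`.
#' @export
fitDDB <- function(traj, sigmaMean = 0, maxLag = 10L, binned = FALSE) {
  stopifnot(is(traj, "Trajectory"))
  if (nDims(traj) != 2L)
    stop("displacement-distribution fitting is defined for 2D trajectories",
         call. = FALSE)
  samp <- .displacementSamples(traj, maxLag)
  if (!length(samp) || length(samp[[1L]]$r) < 10L)
    stop("need at least 10 displacements at lag 1", call. = FALSE)
  init <- tryCatch({
    p <- suppressWarnings(fitMSD(msdCurve(traj), sigmaMean))
    c(log(p@D), .fromAlpha(p@alpha))
  }, error = function(e) c(log(max(mean(samp[[1L]]$r^2) /
                                     (4 * samp[[1L]]$tau), 1e-6)), 0))
  .ddbFitSamples(samp, sigmaMean, binned, init)
}

# core DDB optimizer on a list of per-lag displacement-magnitude samples
# (each element: list(tau, r)); separated so it can be driven directly with
# draws from the generative model
.ddbFitSamples <- function(samp, sigmaMean = 0, binned = FALSE,
                           init = c(0, 0)) {
  s2 <- sigmaMean^2
  if (binned) {
    samp <- lapply(samp, function(s) {
      br <- grDevices::nclass.FD(s$r)
      h <- graphics::hist(s$r, breaks = br, plot = FALSE)
      list(tau = s$tau, breaks = h$breaks, counts = h$counts)
    })
    nll <- function(theta) {
      D <- exp(theta[1L]); a <- .toAlpha(theta[2L])
      tot <- 0
      for (s in samp) {
        scale <- 2 * D * s$tau^a + s2
        pr <- diff(-exp(-s$breaks^2 / (2 * scale)))
        pr <- pmax(pr, 1e-300)
        tot <- tot - sum(s$counts * log(pr / sum(pr)))
      }
      if (is.finite(tot)) tot else 1e12
    }
  } else {
    nll <- function(theta) {
      D <- exp(theta[1L]); a <- .toAlpha(theta[2L])
      tot <- 0
      for (s in samp) {
        scale <- 2 * D * s$tau^a + s2
        tot <- tot + length(s$r) * log(scale) + sum(s$r^2) / (2 * scale)
      }
      if (is.finite(tot)) tot else 1e12
    }
  }
  fit <- optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = 600L, reltol = 1e-10))
  out <- DiffusionParams(exp(fit$par[1L]), .toAlpha(fit$par[2L]), 0)
  attr(out, "flagged") <- fit$convergence != 0L
  out
}

#' Benchmark the GP estimator against the MSD and DDB baselines
#'
#' Runs all three estimators on each record of a [benchmarkDataset()] and
#' tabulates signed relative errors against the generating parameters. The
#' baselines receive the true average localization error, mirroring their
#' standard usage where an error estimate is available.
#'
#' @param records list from [benchmarkDataset()].
#' @param verbose print a progress dot every 25 records.
#' @return A data.frame with columns `id`, `method` (`gp`, `msd`, `ddb`),
#'   `relErrD`, `relErrAlpha` and the generating parameters. Failed baseline
#'   fits yield NA rows.
#' @seealso [summarizeBenchmark()]
#' @export
benchmarkEstimators <- function(records, verbose = FALSE) {
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    if (verbose && i %% 25L == 0L) cat(".")
    sig <- sqrt(mean(rec$traj@locErrors^2))
    ests <- list(
      gp = tryCatch(fittedParams(fitTrajectory(rec$traj)),
                    error = function(e) NULL),
      msd = tryCatch(suppressWarnings(fitMSD(msdCurve(rec$traj), sig)),
                     error = function(e) NULL),
      ddb = tryCatch(suppressWarnings(fitDDB(rec$traj, sig)),
                     error = function(e) NULL))
    do.call(rbind, lapply(names(ests), function(m) {
      p <- ests[[m]]
      data.frame(id = i, method = m,
                 relErrD = if (is.null(p)) NA_real_ else
                   (p@D - rec$D) / rec$D,
                 relErrAlpha = if (is.null(p)) NA_real_ else
                   (p@alpha - rec$alpha) / rec$alpha,
                 D = rec$D, alpha = rec$alpha, dt = rec$dt,
                 sigma = rec$sigma, occlusion = rec$occlusion)
    }))
  })
  if (verbose) cat("\n")
  do.call(rbind, rows)
}

#' Median absolute relative errors per method
#'
#' @param bench data.frame from [benchmarkEstimators()].
#' @return A data.frame with one row per method and the median absolute
#'   relative errors of D and alpha.
#' @export
summarizeBenchmark <- function(bench) {
  agg <- aggregate(cbind(abs(relErrD), abs(relErrAlpha)) ~ method,
                   data = bench, FUN = median, na.action = stats::na.omit)
  names(agg) <- c("method", "medAbsRelErrD", "medAbsRelErrAlpha")
  agg[order(match(agg$method, c("gp", "msd", "ddb"))), , drop = FALSE]
}
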