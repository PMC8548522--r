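# Model-adequacy checks. FBM predicts a characteristic velocity
# autocorrelation and self-similar Gaussian displacements; these diagnostics
# are deliberately model-free (occluded pairs are dropped, never imputed).

#' Theoretical FBM velocity autocorrelation
#'
#' Normalized velocity autocorrelation of FBM for velocities discretized over
#' an interval \eqn{\epsilon}:
#' \deqn{C_\nu(\tau)/C_\nu(0) = \frac{(\tau+\epsilon)^\alpha - 2\tau^\alpha +
#'   |\tau-\epsilon|^\alpha}{2 \epsilon^\alpha}.}
#' Equals 1 at \eqn{\tau = 0}; for \eqn{\alpha = 1} it is the triangle
#' \eqn{1 - \tau/\epsilon} for \eqn{\tau < \epsilon} and 0 beyond; for
#' \eqn{\alpha < 1} it dips negative at \eqn{\tau = \epsilon}
#' (anti-persistence).
#'
#' @param alpha anomalous exponent in (0, 2).
#' @param tau lag time(s), >= 0 (vectorized).
#' @param epsilon velocity discretization interval (> 0).
#' @return Numeric vector of normalized autocorrelations.
#' @examples
#' theoreticalVACF(0.5, tau = c(0, 1, 2), epsilon = 1)
#' @export
theoreticalVACF <- function(alpha, tau, epsilon) {
  stopifnot(epsilon > 0, all(tau >= 0), alpha > 0, alpha < 2)
  ((tau + epsilon)^alpha - 2 * tau^alpha + abs(tau - epsilon)^alpha) /
    (2 * epsilon^alpha)
}

#' Empirical velocity autocorrelation of tracked particles
#'
#' Ensemble- and time-averaged autocorrelation of discrete velocities
#' \eqn{\nu(t) = [x(t+\epsilon) - x(t)]/\epsilon}, normalized by its value at
#' zero lag. Velocities are formed on the frame grid; any product whose four
#' endpoints are not all observed is skipped.
#'
#' @param trajs a [Trajectory-class] or list of them (regular frame grid).
#' @param epsilonFrames velocity interval in frames (default 1).
#' @param maxLag largest lag in units of `epsilonFrames` (default 10).
#' @return A [VACFCurve-class]; errors if no valid velocity pair exists.
#' @export
empiricalVACF <- function(trajs, epsilonFrames = 1L, maxLag = 10L) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L, epsilonFrames >= 1L)
  eps <- epsilonFrames
  sums <- numeric(maxLag + 1L)
  cnts <- integer(maxLag + 1L)
  dtv <- numeric(0)
  for (tr in trajs) {
    fr <- tr@frames
    dtv <- c(dtv, stats::median(diff(tr@times) / diff(fr)))
    pos <- tr@coords
    iEnd <- match(fr + eps, fr)
    for (lag in 0:maxLag) {
      i2 <- match(fr + lag * eps, fr)
      i2e <- match(fr + lag * eps + eps, fr)
      ok <- which(!is.na(iEnd) & !is.na(i2) & !is.na(i2e))
      if (!length(ok)) next
      prod <- rowSums((pos[i2e[ok], , drop = FALSE] -
                         pos[i2[ok], , drop = FALSE]) *
                        (pos[iEnd[ok], , drop = FALSE] -
                           pos[ok, , drop = FALSE]))
      sums[lag + 1L] <- sums[lag + 1L] + sum(prod)
      cnts[lag + 1L] <- cnts[lag + 1L] + length(ok)
    }
  }
  if (cnts[1L] == 0L)
    stop("no valid velocity pairs; check the frame grid", call. = FALSE)
  vals <- ifelse(cnts > 0L, sums / cnts, NA_real_)
  dt <- stats::median(dtv)
  new("VACFCurve", taus = (0:maxLag) * eps * dt, values = vals / vals[1L],
      epsilon = eps * dt, counts = cnts)
}

#' Self-similarity and Gaussianity check of displacements
#'
#' FBM displacements are Gaussian and self-similar: rescaling lag-n
#' displacements by \eqn{(n\,dt)^{-\alpha/2}} should collapse all lags onto
#' one normal distribution. Pools per-dimension displacements across
#' trajectories at the requested frame lags, rescales them with the supplied
#' exponent, and reports per-lag normality summaries (one-sample KS distance
#' against a fitted normal, excess kurtosis) plus a cross-lag collapse
#' statistic (maximum pairwise two-sample KS distance and its smallest
#' p-value). No single test statistic is privileged; both are reported.
#'
#' @param trajs a [Trajectory-class] or list of them.
#' @param lags integer frame lags (>= 2 of them for the collapse statistic).
#' @param alphaHat anomalous exponent used for rescaling.
#' @param minSamples per-lag sample size below which the report is marked
#'   inconclusive (default 50).
#' @return A list with elements `perLag` (data.frame: lag, n, sd, ksStat,
#'   excessKurtosis), `collapse` (list: maxKS, minPvalue; NULL with a single
#'   usable lag), and `conclusive` (logical).
#' @export
selfSimilarityCheck <- function(trajs, lags = c(1L, 2L, 4L, 8L), alphaHat,
                                minSamples = 50L) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  stopifnot(alphaHat > 0, alphaHat < 2, length(lags) >= 1L)
  pool <- list()
  for (n in sort(unique(as.integer(lags)))) {
    z <- numeric(0)
    for (tr in trajs) {
      fr <- tr@frames
      dt <- stats::median(diff(tr@times) / diff(fr))
      j <- match(fr + n, fr)
      ok <- which(!is.na(j))
      if (!length(ok)) next
      disp <- tr@coords[j[ok], , drop = FALSE] - tr@coords[ok, , drop = FALSE]
      z <- c(z, as.numeric(disp) / (n * dt)^(alphaHat / 2))
    }
    if (length(z)) pool[[as.character(n)]] <- z
  }
  if (!length(pool)) stop("no displacements at the requested lags",
                          call. = FALSE)
  perLag <- do.call(rbind, lapply(names(pool), function(nm) {
    z <- pool[[nm]]
    ks <- suppressWarnings(ks.test(z, "pnorm", mean(z), sd(z)))
    data.frame(lag = as.integer(nm), n = length(z), sd = sd(z),
               ksStat = unname(ks$statistic),
               excessKurtosis = mean((z - mean(z))^4) / var(z)^2 - 3)
  }))
  conclusive <- all(perLag$n >= minSamples)
  collapse <- NULL
  if (nrow(perLag) >= 2L) {
    maxKS <- 0; minP <- 1
    nm <- names(pool)
    for (i in seq_len(length(nm) - 1L)) for (j in (i + 1L):length(nm)) {
      ks <- suppressWarnings(ks.test(pool[[nm[i]]], pool[[nm[j]]]))
      maxKS <- max(maxKS, unname(ks$statistic))
      minP <- min(minP, ks$p.value)
    }
    collapse <- list(maxKS = maxKS, minPvalue = minP)
  }
  list(perLag = perLag, collapse = collapse, conclusive = conclusive)
}

#' Inter- versus intra-group variance decomposition
#'
#' Splits the total population variance of a per-track statistic (e.g. fitted
#' D or alpha values grouped by cell) by the law of total variance:
#' \deqn{var(x) = \langle var(x \mid g) \rangle + var(\langle x \mid g
#' \rangle).}
#' Population (denominator N) variances and member-weighted group means are
#' used so the identity holds exactly for any group sizes. Groups with a
#' single member are excluded with a warning.
#'
#' @param values numeric vector of the statistic.
#' @param groups group labels, same length.
#' @return A [VarianceDecomposition-class]; proportions are NA (with a
#'   warning) when the total variance is zero.
#' @examples
#' varianceDecomposition(c(1, 3, 5, 7), c("a", "a", "b", "b"))
#' @export
varianceDecomposition <- function(values, groups) {
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  groups <- as.character(groups)
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    single <- names(sizes)[sizes < 2L]
    warning("excluding ", length(single), " singleton group(s)")
    keep <- !groups %in% single
    values <- values[keep]; groups <- groups[keep]
  }
  gl <- split(values, groups)
  if (length(gl) < 2L)
    stop("need at least two groups with two or more members", call. = FALSE)
  N <- length(values)
  popvar <- function(x) mean((x - mean(x))^2)
  ng <- lengths(gl)
  means <- vapply(gl, mean, 0)
  intra <- sum(ng * vapply(gl, popvar, 0)) / N
  grand <- mean(values)
  inter <- sum(ng * (means - grand)^2) / N
  total <- popvar(values)
  props <- c(intra = intra / total, inter = inter / total)
  if (total == 0) {
    warning("total variance is zero; proportions undefined")
    props <- c(intra = NA_real_, inter = NA_real_)
  }
  new("VarianceDecomposition", total = total, intra = intra, inter = inter,
      proportions = props, nGroups = length(gl))
}
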