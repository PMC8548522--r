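# Independent dense oracles built only from base R linear algebra (explicit
# solve() and determinant()), never from the package's kernel/likelihood code
# paths.

# FBM kernel entry, written out directly
oracleKernel <- function(ta, tb, D, alpha) {
  D * (abs(outer(ta^alpha, rep(1, length(tb)))) +
         outer(rep(1, length(ta)), tb^alpha) -
         abs(outer(ta, tb, "-"))^alpha)
}

# dense multivariate-normal log-density of an anchored trajectory, explicit
# inverse and determinant
oracleLogLik <- function(traj, D, alpha, mu) {
  times <- timePoints(traj)
  pos <- coords(traj)
  sig <- locErrors(traj)
  n <- length(times) - 1L
  d <- ncol(pos)
  if (length(mu) == 1L) mu <- rep(mu, d)
  s <- times[-1L] - times[1L]
  K0 <- oracleKernel(s, s, D, alpha)
  ll <- 0
  for (j in seq_len(d)) {
    Kj <- K0 + diag(sig[-1L, j]^2, n)
    Kj <- Kj + diag(1e-10 * max(diag(Kj)), n)
    y <- pos[-1L, j] - pos[1L, j] - mu[j]
    ll <- ll - 0.5 * drop(t(y) %*% solve(Kj) %*% y) -
      0.5 * as.numeric(determinant(Kj)$modulus) - n / 2 * log(2 * pi)
  }
  ll
}

# joint density of two substrate-coupled particles, assembled from the
# first-principles construction r_i = a_i + R: the covariance of independent
# sums is the sum of covariances (block-diagonal particle kernels plus the
# substrate kernel in every block)
oracleEnsembleLogLik <- function(trajs, Ds, alphas, mus, DR, aR) {
  K <- length(trajs)
  d <- nDims(trajs[[1L]])
  ys <- list(); ss <- list(); sigs <- list()
  for (k in seq_len(K)) {
    tr <- trajs[[k]]
    ys[[k]] <- sweep(coords(tr)[-1L, , drop = FALSE], 2L, coords(tr)[1L, ])
    ss[[k]] <- timePoints(tr)[-1L] - timePoints(tr)[1L]
    sigs[[k]] <- locErrors(tr)[-1L, , drop = FALSE]
  }
  nTot <- sum(lengths(ss))
  ll <- 0
  for (j in seq_len(d)) {
    C <- matrix(0, nTot, nTot)
    off <- c(0, cumsum(lengths(ss)))
    for (k in seq_len(K)) {
      ii <- (off[k] + 1):off[k + 1]
      C[ii, ii] <- oracleKernel(ss[[k]], ss[[k]], Ds[k], alphas[k]) +
        diag(sigs[[k]][, j]^2, length(ii))
      for (l in seq_len(K)) {
        jj <- (off[l] + 1):off[l + 1]
        C[ii, jj] <- C[ii, jj] + oracleKernel(ss[[k]], ss[[l]], DR, aR)
      }
    }
    C <- C + diag(1e-10 * max(diag(C)), nTot)
    y <- unlist(lapply(seq_len(K), function(k) ys[[k]][, j] - mus[[k]][j]))
    ll <- ll - 0.5 * drop(t(y) %*% solve(C) %*% y) -
      0.5 * as.numeric(determinant(C)$modulus) - nTot / 2 * log(2 * pi)
  }
  ll
}

# random small noisy trajectory for oracle comparisons
randomTrajectory <- function(maxPoints = 10L, d = 2L) {
  n <- sample(3:maxPoints, 1L)
  times <- c(0, cumsum(runif(n, 0.1, 1)))
  Trajectory(times, matrix(rnorm((n + 1L) * d), n + 1L, d),
             locErrors = matrix(runif((n + 1L) * d, 0, 0.2), n + 1L, d))
}
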