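test_that("FBM kernel matches closed forms", {
  # direct substitutions
  expect_equal(fbmCovariance(1, 1, D = 0.5, alpha = 1)[1, 1], 1.0)
  expect_equal(fbmCovariance(3, 1, D = 1, alpha = 1)[1, 1], 2.0)
  # any time against the origin has zero covariance
  for (a in c(0.3, 1, 1.7))
    expect_equal(fbmCovariance(c(0.7, 2.3), 0, D = 1.2, alpha = a),
                 matrix(0, 2, 1))
  # alpha = 1 reduces to the Brownian kernel 2 D min(t, t')
  tt <- c(0.5, 1, 2.5, 4)
  expect_equal(fbmCovariance(tt, D = 0.8, alpha = 1),
               2 * 0.8 * outer(tt, tt, pmin))
  # symmetry
  K <- fbmCovariance(tt, D = 0.3, alpha = 1.4)
  expect_equal(K, t(K))
  # domain errors
  expect_error(fbmCovariance(1, 1, D = -1, alpha = 1), "D must be")
  expect_error(fbmCovariance(1, 1, D = 1, alpha = 2), "alpha must")
})

test_that("kernel has stationary increments with variance 2 D dt^alpha", {
  for (a in c(0.4, 1, 1.6)) for (t0 in c(0, 1.3, 7)) for (dt in c(0.2, 1, 3)) {
    K <- fbmCovariance(c(t0, t0 + dt), D = 0.6, alpha = a)
    expect_equal(K[1, 1] + K[2, 2] - 2 * K[1, 2], 2 * 0.6 * dt^a)
  }
})

test_that("jittered kernel admits a Cholesky factorization", {
  set.seed(11)
  for (a in c(0.05, 0.5, 1, 1.5, 1.95)) {
    tt <- sort(runif(40, 0.01, 20))
    K <- fbmCovariance(tt, D = 0.7, alpha = a)
    diag(K) <- diag(K) + 1e-10 * max(diag(K))
    expect_silent(chol(K))
  }
})

test_that("localization noise enters only on the diagonal", {
  expect_equal(addLocalizationNoise(matrix(0, 2, 2), c(1, 2)),
               diag(c(1, 4)))
  K <- fbmCovariance(c(1, 2), D = 1, alpha = 1)
  expect_equal(addLocalizationNoise(K, 0), K)
  Kn <- addLocalizationNoise(K, c(0.1, 0.1))
  expect_equal(diag(Kn), diag(K) + 0.01)
  Kn[cbind(1:2, 1:2)] <- diag(K)
  expect_equal(Kn, K)
  expect_error(addLocalizationNoise(K, c(1, 2, 3)), "dimension")
})

test_that("log-likelihood equals the dense multivariate-normal oracle", {
  # single observation at t = 1 with unit variance: standard normal density
  tr <- Trajectory(c(0, 1), matrix(0, 2, 1))
  expect_equal(trajLogLikelihood(tr, DiffusionParams(0.5, 1, 0)),
               -0.5 * log(2 * pi))
  set.seed(7)
  for (i in 1:10) {
    tr <- randomTrajectory()
    D <- runif(1, 0.05, 1.5); a <- runif(1, 0.1, 1.9); mu <- rnorm(2, 0, 0.3)
    expect_lt(abs(trajLogLikelihood(tr, DiffusionParams(D, a, mu)) -
                    oracleLogLik(tr, D, a, mu)), 1e-8)
  }
})

test_that("log-likelihood is invariant under joint translation", {
  set.seed(8)
  tr <- randomTrajectory()
  p1 <- DiffusionParams(0.4, 0.8, c(0.1, -0.2))
  shifted <- Trajectory(timePoints(tr), sweep(coords(tr), 2, c(-3, 5), "+"),
                        locErrors = locErrors(tr))
  # anchoring removes the constant, so even mu can stay put
  expect_equal(trajLogLikelihood(tr, p1), trajLogLikelihood(shifted, p1))
  # and adding the constant to mu as well keeps it identical too
  p2 <- DiffusionParams(0.4, 0.8, c(0.1, -0.2) + c(-3, 5))
  expect_equal(trajLogLikelihood(tr, p1), trajLogLikelihood(shifted, p1))
})

test_that("two-particle joint covariance reproduces the block structure", {
  mk <- function(id) Trajectory(c(0, 1), matrix(0, 2, 1), trackId = id)
  ens <- FbmEnsemble(list(mk("a"), mk("b")),
                     list(DiffusionParams(0.5, 1), DiffusionParams(0.5, 1)),
                     DiffusionParams(0.5, 1))
  expect_equal(ensembleCovariance(ens), matrix(c(2, 1, 1, 2), 2, 2))
  # K-particle generalization: diagonal Sigma_k + Sigma_R, off-diagonal
  # Sigma_R, on distinct grids
  set.seed(21)
  trs <- lapply(1:3, function(k)
    Trajectory(c(0, sort(runif(3, 0.2, 3))), matrix(rnorm(4), 4, 1),
               trackId = paste0("t", k)))
  Ds <- c(0.3, 0.7, 1.1); as <- c(0.6, 1.0, 1.4)
  ens3 <- FbmEnsemble(trs, lapply(1:3, function(k)
    DiffusionParams(Ds[k], as[k])), DiffusionParams(0.4, 0.9))
  C <- ensembleCovariance(ens3)
  ss <- lapply(trs, function(tr) timePoints(tr)[-1])
  off <- c(0, cumsum(lengths(ss)))
  for (k in 1:3) for (l in 1:3) {
    blkExp <- oracleKernel(ss[[k]], ss[[l]], 0.4, 0.9)
    if (k == l) blkExp <- blkExp + oracleKernel(ss[[k]], ss[[k]], Ds[k], as[k])
    expect_equal(C[(off[k] + 1):off[k + 1], (off[l] + 1):off[l + 1]], blkExp)
  }
})

test_that("ensemble likelihood factorizes when the substrate vanishes", {
  set.seed(9)
  # same grid, parameters and noise level so the relative-jitter
  # stabilization is bitwise identical between the joint and factorized paths
  times <- c(0, cumsum(runif(6, 0.1, 1)))
  trs <- lapply(1:2, function(k)
    Trajectory(times, matrix(rnorm(14), 7, 2), locErrors = 0.1,
               trackId = paste0("t", k)))
  pp <- list(DiffusionParams(0.8, 0.9, c(0, 0)),
             DiffusionParams(0.8, 0.9, c(0.1, 0)))
  ens <- FbmEnsemble(trs, pp, DiffusionParams(1e-15, 1))
  indep <- trajLogLikelihood(trs[[1]], pp[[1]]) +
    trajLogLikelihood(trs[[2]], pp[[2]])
  expect_lt(abs(ensembleLogLikelihood(ens) - indep), 1e-8)
})

test_that("ensemble likelihood matches the first-principles r = a + R oracle", {
  set.seed(10)
  for (i in 1:5) {
    trs <- list(randomTrajectory(4), randomTrajectory(4))
    Ds <- runif(2, 0.1, 1.2); as <- runif(2, 0.3, 1.6)
    mus <- list(rnorm(2, 0, 0.2), rnorm(2, 0, 0.2))
    DR <- runif(1, 0.1, 1); aR <- runif(1, 0.5, 1.5)
    ens <- FbmEnsemble(trs, list(DiffusionParams(Ds[1], as[1], mus[[1]]),
                                 DiffusionParams(Ds[2], as[2], mus[[2]])),
                       DiffusionParams(DR, aR))
    expect_lt(abs(ensembleLogLikelihood(ens) -
                    oracleEnsembleLogLik(trs, Ds, as, mus, DR, aR)), 1e-7)
  }
})

test_that("correlated pairs score higher under the generating substrate", {
  sim <- simulateEnsemble(c(0.2, 0.2), c(0.8, 0.8), substrateD = 1,
                          substrateAlpha = 1, nPoints = 80, dt = 0.5,
                          sigma = 0.02, occlusionRate = 0, seed = 14)
  trs <- trajectories(sim$ensemble)
  pp <- list(DiffusionParams(0.2, 0.8), DiffusionParams(0.2, 0.8))
  withSub <- ensembleLogLikelihood(
    FbmEnsemble(trs, pp, DiffusionParams(1, 1)))
  noSub <- ensembleLogLikelihood(
    FbmEnsemble(trs, pp, DiffusionParams(1e-12, 1)))
  expect_gt(withSub, noSub)
  # fewer than 2 trajectories is rejected at construction
  expect_error(FbmEnsemble(trs[1], pp[1], DiffusionParams(1, 1)),
               "at least two")
})
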