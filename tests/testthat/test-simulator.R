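test_that("simulation is deterministic and validates its spec", {
  a <- simulateFBM(nPoints = 50, dt = 0.3, D = 0.7, alpha = 1.2, seed = 99)
  b <- simulateFBM(nPoints = 50, dt = 0.3, D = 0.7, alpha = 1.2, seed = 99)
  expect_identical(coords(a), coords(b))
  expect_equal(timePoints(a), (0:49) * 0.3)
  expect_equal(coords(a)[1, ], c(0, 0))
  expect_error(simulateFBM(D = 0), "D must be")
  expect_error(simulateFBM(alpha = 2.4), "alpha")
  expect_error(simulateFBM(nPoints = 1), "nPoints")
  expect_error(simulateFBM(dt = 0), "dt")
})

test_that("single-step variance matches the kernel diagonal", {
  x <- vapply(1:800, function(s)
    coords(simulateFBM(3, dt = 0.4, D = 0.7, alpha = 0.8, nDims = 1,
                       seed = s))[2, 1], 0)
  v <- var(x)
  expected <- 2 * 0.7 * 0.4^0.8
  se <- expected * sqrt(2 / length(x))   # var of a chi^2_1-type estimate
  expect_lt(abs(v - expected), 3 * se)
})

test_that("corruption preserves the anchor and removes the stated count", {
  tr <- simulateFBM(nPoints = 250, dt = 0.5, D = 1, alpha = 1, seed = 3)
  same <- corruptTrajectory(tr, sigma = 0, occlusionRate = 0, seed = 1)
  expect_equal(coords(same), coords(tr))
  expect_equal(timePoints(same), timePoints(tr))
  occ <- corruptTrajectory(tr, sigma = 0, occlusionRate = 0.1, seed = 1)
  expect_equal(nPoints(occ), 225)           # round(0.1 * 249) removed
  expect_equal(timePoints(occ)[1], 0)       # anchor kept
  expect_true(all(timePoints(occ) %in% timePoints(tr)))
  expect_error(corruptTrajectory(tr, sigma = -1), "sigma")
  expect_error(corruptTrajectory(tr, occlusionRate = 0.9), "occlusionRate")
})

test_that("localization noise is Gaussian with the requested sd", {
  tr <- simulateFBM(nPoints = 5000, dt = 0.5, D = 0.5, alpha = 1, nDims = 2,
                    seed = 8)
  noisy <- corruptTrajectory(tr, sigma = 0.2, occlusionRate = 0, seed = 12)
  diffs <- as.numeric(coords(noisy) - coords(tr))
  expect_lt(abs(sd(diffs) - 0.2) / 0.2, 0.05)
  ks <- suppressWarnings(ks.test(diffs / 0.2, "pnorm"))
  expect_gt(ks$p.value, 1e-4)
  expect_equal(unique(as.numeric(locErrors(noisy))), 0.2)
})

test_that("ensemble additivity holds exactly and occlusion grids differ", {
  sim <- simulateEnsemble(c(0.5, 0.9), c(0.6, 1.1), substrateD = 0.4,
                          substrateAlpha = 1.3, nPoints = 60, dt = 0.5,
                          sigma = 0.1, occlusionRate = 0.2, seed = 5)
  for (k in 1:2)
    expect_equal(coords(sim$truth$observedClean[[k]]),
                 coords(sim$truth$particles[[k]]) +
                   coords(sim$truth$substrate))
  expect_error(simulateEnsemble(0.5, 0.6, 1, 1, seed = 1), "at least two")
  expect_error(simulateEnsemble(c(0.5, 1), c(0.6, 1), 0, 1, seed = 1),
               "D must be")
  # near-zero substrate keeps particles empirically uncorrelated
  xs <- vapply(1:400, function(s) {
    sm <- simulateEnsemble(c(0.5, 0.5), c(1, 1), 1e-12, 1, nPoints = 3,
                           dt = 0.5, sigma = 0, occlusionRate = 0,
                           nDims = 1, seed = s)
    c(coords(trajectories(sm$ensemble)[[1]])[3, 1],
      coords(trajectories(sm$ensemble)[[2]])[3, 1])
  }, numeric(2))
  expect_lt(abs(cor(xs[1, ], xs[2, ])), 3 / sqrt(400))
})

test_that("cross-covariance of an ensemble matches the substrate kernel", {
  xs <- vapply(1:600, function(s) {
    sm <- simulateEnsemble(c(0.4, 0.8), c(0.7, 1.2), 0.6, 1.0, nPoints = 3,
                           dt = 0.5, sigma = 0, occlusionRate = 0, nDims = 1,
                           seed = s)
    c(coords(trajectories(sm$ensemble)[[1]])[2:3, 1],
      coords(trajectories(sm$ensemble)[[2]])[2:3, 1])
  }, numeric(4))
  # off-diagonal block: Cov[r1(t), r2(t')] = Sigma_R(t, t')
  SR <- oracleKernel(c(0.5, 1), c(0.5, 1), 0.6, 1.0)
  S1 <- oracleKernel(c(0.5, 1), c(0.5, 1), 0.4, 0.7)
  emp <- cov(t(xs))
  n <- 600
  for (i in 1:2) for (j in 1:2) {
    se <- sqrt((emp[i, i] * emp[2 + j, 2 + j] + SR[i, j]^2) / n)
    expect_lt(abs(emp[i, 2 + j] - SR[i, j]), 4 * se)
    # particle 1 marginal: Sigma_1 + Sigma_R
    seD <- sqrt((emp[i, i] * emp[j, j] + emp[i, j]^2) / n)
    expect_lt(abs(emp[i, j] - (S1[i, j] + SR[i, j])), 4 * seD)
  }
})

test_that("benchmark datasets are reproducible with uniform parameter draws", {
  r1 <- benchmarkDataset(3, nPoints = 30, seed = 42)
  r2 <- benchmarkDataset(3, nPoints = 30, seed = 42)
  expect_identical(coords(r1[[2]]$traj), coords(r2[[2]]$traj))
  expect_identical(r1[[3]]$D, r2[[3]]$D)
  # default length is 250 points before occlusion
  r3 <- benchmarkDataset(1, seed = 7)
  expect_equal(nPoints(r3[[1]]$clean), 250)
  expect_error(benchmarkDataset(2, ranges = list(D = 1), seed = 1), "ranges")
  # parameter draws are uniform over the stated ranges
  big <- benchmarkDataset(400, nPoints = 2, seed = 11)
  for (p in c("D", "alpha", "dt", "sigma", "occlusion")) {
    x <- vapply(big, `[[`, 0, p)
    rg <- benchmarkRanges()[[p]]
    ks <- suppressWarnings(ks.test((x - rg[1]) / (rg[2] - rg[1]), "punif"))
    expect_gt(ks$p.value, 1e-4)
  }
})
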