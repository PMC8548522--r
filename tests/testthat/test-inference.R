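test_that("MAP estimation is deterministic and respects the alpha bound", {
  tr <- corruptTrajectory(simulateFBM(120, 0.5, 0.8, 1.8, seed = 31),
                          sigma = 0.05, occlusionRate = 0, seed = 31)
  f1 <- fitTrajectory(tr)
  f2 <- fitTrajectory(tr)
  expect_identical(diffusionCoef(f1), diffusionCoef(f2))
  expect_identical(anomalousExponent(f1), anomalousExponent(f2))
  expect_lt(anomalousExponent(f1), 2)
  expect_gt(anomalousExponent(f1), 0)
  expect_error(fitTrajectory(Trajectory(0:3, matrix(rnorm(8), 4, 2))),
               "fewer than")
})

test_that("MAP estimates are invariant to rigid translation", {
  tr <- corruptTrajectory(simulateFBM(100, 0.4, 0.6, 0.9, seed = 17),
                          sigma = 0.1, occlusionRate = 0.1, seed = 17)
  shifted <- Trajectory(timePoints(tr), sweep(coords(tr), 2, c(12, -7), "+"),
                        locErrors = locErrors(tr), frames = frameIndex(tr))
  f0 <- fitTrajectory(tr); f1 <- fitTrajectory(shifted)
  expect_equal(diffusionCoef(f1), diffusionCoef(f0), tolerance = 1e-6)
  expect_equal(anomalousExponent(f1), anomalousExponent(f0),
               tolerance = 1e-6)
})

test_that("time rescaling maps D by c^(-alpha)", {
  tr <- simulateFBM(100, 0.5, 0.7, 1.1, seed = 23)
  f0 <- fitTrajectory(tr)
  cs <- 4
  scaled <- Trajectory(timePoints(tr) * cs, coords(tr),
                       frames = frameIndex(tr))
  f1 <- fitTrajectory(scaled)
  expect_equal(anomalousExponent(f1), anomalousExponent(f0),
               tolerance = 1e-3)
  expect_equal(diffusionCoef(f1),
               diffusionCoef(f0) * cs^(-anomalousExponent(f0)),
               tolerance = 1e-3)
})

test_that("posterior chains are reproducible with sane acceptance", {
  tr <- corruptTrajectory(simulateFBM(60, 0.5, 0.8, 0.9, seed = 41),
                          sigma = 0.05, occlusionRate = 0, seed = 41)
  map <- fitTrajectory(tr)
  ch1 <- samplePosterior(tr, nSamples = 600, burnIn = 300, seed = 5,
                         mapFit = map)
  ch2 <- samplePosterior(tr, nSamples = 600, burnIn = 300, seed = 5,
                         mapFit = map)
  expect_identical(chainSamples(ch1), chainSamples(ch2))
  expect_gt(acceptanceRate(ch1), 0.1)
  expect_lt(acceptanceRate(ch1), 0.6)
  # split-chain stability of the D samples
  x <- chainSamples(ch1)[, "D"]
  h <- length(x) %/% 2
  expect_lt(abs(mean(x[1:h]) - mean(x[-(1:h)])), 0.75 * sd(x))
  # posterior mode region contains the MAP: the MAP log-posterior density in
  # theta space should not be beaten by much anywhere in the chain
  ci <- credibleIntervals(ch1)
  expect_gt(diffusionCoef(map), ci["D", "lower"] * 0.8)
  expect_lt(diffusionCoef(map), ci["D", "upper"] * 1.2)
})

test_that("GP interpolation is exact at noiseless observations", {
  tr <- simulateFBM(40, 0.5, 0.5, 1.2, seed = 51)
  p <- DiffusionParams(0.5, 1.2, c(0, 0))
  path <- interpolateTrajectory(tr, p, timePoints(tr))
  expect_equal(pathMean(path), coords(tr), tolerance = 1e-6)
  width <- pathUpper(path) - pathLower(path)
  expect_lt(max(width), 1e-3)
  # anchor query: exact position, zero-width band
  anch <- interpolateTrajectory(tr, p, 0)
  expect_equal(pathMean(anch)[1, ], coords(tr)[1, ])
  expect_equal(pathUpper(anch)[1, ], pathLower(anch)[1, ])
  expect_error(interpolateTrajectory(tr, p, -1), "anchor")
  # interpolated band at a hidden time has positive width
  mid <- interpolateTrajectory(tr, p, 0.75)
  expect_true(all(pathUpper(mid) > pathLower(mid)))
})

test_that("substrate-corrected fits beat uncorrected ones on a strong substrate", {
  sim <- simulateEnsemble(c(0.3, 0.6), c(0.5, 0.8), substrateD = 0.8,
                          substrateAlpha = 1.2, nPoints = 150, dt = 0.5,
                          sigma = 0.1, occlusionRate = 0.1, seed = 61)
  fit <- fitEnsemble(trajectories(sim$ensemble))
  errC <- abs(vapply(particleParams(fit), diffusionCoef, 0) -
                c(0.3, 0.6)) / c(0.3, 0.6)
  errU <- abs(vapply(uncorrectedFits(fit), diffusionCoef, 0) -
                c(0.3, 0.6)) / c(0.3, 0.6)
  expect_lt(mean(errC), mean(errU))
  expect_gt(diffusionCoef(substrateParams(fit)), 0.1)
})

test_that("a near-static substrate leaves corrected close to uncorrected", {
  sim <- simulateEnsemble(c(0.5, 0.9), c(0.8, 1.0), substrateD = 1e-6,
                          substrateAlpha = 1, nPoints = 120, dt = 0.5,
                          sigma = 0.05, occlusionRate = 0, seed = 71)
  fit <- fitEnsemble(trajectories(sim$ensemble))
  for (k in 1:2) {
    expect_equal(diffusionCoef(particleParams(fit)[[k]]),
                 diffusionCoef(uncorrectedFits(fit)[[k]]), tolerance = 0.15)
    expect_equal(anomalousExponent(particleParams(fit)[[k]]),
                 anomalousExponent(uncorrectedFits(fit)[[k]]),
                 tolerance = 0.15)
  }
})

test_that("non-overlapping tracks fall back to independent fits", {
  t1 <- simulateFBM(30, 0.5, 0.5, 1, seed = 81, trackId = "a")
  t2raw <- simulateFBM(30, 0.5, 0.5, 1, seed = 82, trackId = "b")
  t2 <- Trajectory(timePoints(t2raw) + 100, coords(t2raw), trackId = "b",
                   frames = frameIndex(t2raw) + 1000L)
  expect_warning(fit <- fitEnsemble(list(t1, t2)), "overlap")
  expect_true(fit@flagged)
  expect_equal(diffusionCoef(particleParams(fit)[[1]]),
               diffusionCoef(uncorrectedFits(fit)[[1]]))
})

test_that("substrate path reconstruction has the correct sign and tracks truth", {
  # simulation oracle for the conditional-mean sign: against its negation,
  # the implemented mean must have the smaller error vs the true substrate
  mses <- matrix(NA_real_, 6, 2)
  cors <- numeric(6)
  for (i in 1:6) {
    sim <- simulateEnsemble(c(0.05, 0.05), c(0.9, 0.9), substrateD = 1,
                            substrateAlpha = 1.1, nPoints = 80, dt = 0.5,
                            sigma = 0.02, occlusionRate = 0, seed = 100 + i)
    path <- inferSubstratePath(sim$ensemble)
    truth <- coords(sim$truth$substrate)
    est <- pathMean(path)
    mses[i, ] <- c(mean((est - truth)^2), mean((-est - truth)^2))
    cors[i] <- cor(as.numeric(est), as.numeric(truth))
  }
  expect_true(all(mses[, 1] < mses[, 2]))
  expect_true(all(cors > 0.8))
})

test_that("duplicated near-static particles pin the substrate path", {
  sim <- simulateEnsemble(c(0.01, 0.01), c(1, 1), substrateD = 1,
                          substrateAlpha = 1, nPoints = 60, dt = 0.5,
                          sigma = 0.01, occlusionRate = 0, seed = 121)
  path <- inferSubstratePath(sim$ensemble)
  shared <- sweep(coords(trajectories(sim$ensemble)[[1]]), 2,
                  coords(trajectories(sim$ensemble)[[1]])[1, ])
  expect_gt(cor(as.numeric(pathMean(path)), as.numeric(shared)), 0.99)
})

test_that("substrate recovery improves with the substrate-to-particle ratio", {
  corFor <- function(DR, seed) {
    sim <- simulateEnsemble(c(0.3, 0.3), c(0.9, 0.9), substrateD = DR,
                            substrateAlpha = 1, nPoints = 80, dt = 0.5,
                            sigma = 0.05, occlusionRate = 0, seed = seed)
    path <- inferSubstratePath(sim$ensemble)
    cor(as.numeric(pathMean(path)), as.numeric(coords(sim$truth$substrate)))
  }
  weak <- mean(vapply(1:5, function(s) corFor(0.05, 200 + s), 0))
  strong <- mean(vapply(1:5, function(s) corFor(1.5, 200 + s), 0))
  expect_gt(strong, weak)
})
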