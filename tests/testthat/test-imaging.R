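test_that("noiseless spot render-and-refit recovers all parameters", {
  truth <- list(center = c(5.3, 4.6), size = c(1.8, 1.3), theta = 0.35,
                intensity = 2.4, background = 0.2)
  patch <- simulateSpotPatch(11, 11, center = truth$center,
                             size = truth$size, theta = truth$theta,
                             intensity = truth$intensity,
                             background = truth$background)
  fit <- refineSpot(patch)
  expect_true(fit@converged)
  expect_equal(fit@center, truth$center, tolerance = 1e-3)
  expect_equal(fit@size, truth$size, tolerance = 1e-3)
  expect_equal(fit@theta, truth$theta, tolerance = 1e-2)
  expect_equal(fit@intensity, truth$intensity, tolerance = 1e-3)
  expect_equal(fit@background, truth$background, tolerance = 1e-2)
})

test_that("isotropic spot center equals the intensity centroid", {
  patch <- simulateSpotPatch(13, 13, center = c(6.25, 5.75),
                             size = c(1.6, 1.6), theta = 0, intensity = 1,
                             background = 0)
  fit <- refineSpot(patch)
  xg <- matrix(rep(0:12, each = 13), 13, 13)
  yg <- matrix(rep(0:12, 13), 13, 13)
  centroid <- c(sum(patch * xg), sum(patch * yg)) / sum(patch)
  expect_equal(fit@center, centroid, tolerance = 0.01)
})

test_that("spot refinement is equivariant under integer shifts", {
  p0 <- simulateSpotPatch(15, 15, center = c(6.4, 7.2), size = c(1.5, 1.9),
                          theta = -0.2, intensity = 1.5, background = 0.1)
  f0 <- refineSpot(p0)
  shifted <- simulateSpotPatch(15, 15, center = c(6.4 + 2, 7.2 - 1),
                               size = c(1.5, 1.9), theta = -0.2,
                               intensity = 1.5, background = 0.1)
  f1 <- refineSpot(shifted)
  expect_equal(f1@center - f0@center, c(2, -1), tolerance = 1e-3)
})

test_that("flat patches and noisy fits are flagged sensibly", {
  expect_false(refineSpot(matrix(1, 11, 11))@converged)
  patch <- simulateSpotPatch(11, 11, size = c(1.4, 1.4), intensity = 1,
                             background = 0.1, noiseSd = 0.05, seed = 2)
  fit <- refineSpot(patch)
  expect_true(fit@converged)
  expect_true(all(fit@locError > 0))
})

test_that("MH localization error calibrates against the true center scatter", {
  truth <- c(5.0, 5.0)
  fits <- lapply(1:80, function(s) {
    patch <- simulateSpotPatch(11, 11, center = truth, size = c(1.5, 1.5),
                               intensity = 1, background = 0.1,
                               noiseSd = 0.1, seed = s)
    refineSpot(patch, nMH = 800, seed = s)
  })
  errs <- vapply(fits, function(f) f@center[1] - truth[1], 0)
  reported <- vapply(fits, function(f) f@locError[1], 0)
  expect_lt(abs(sd(errs) - mean(reported)) / sd(errs), 0.45)
})

test_that("alignment composition reduces to the expected special cases", {
  # identity for every rotation center
  for (cc in list(c(0, 0), c(32, 32), c(10, 50))) {
    A <- ChannelAlignment(width = 64, height = 64, center = cc)
    expect_equal(composeAlignment(A), diag(3))
  }
  # pure translation
  A <- ChannelAlignment(translation = c(5, -3), width = 64, height = 64)
  expect_equal(composeAlignment(A),
               matrix(c(1, 0, 5, 0, 1, -3, 0, 0, 1), 3, 3, byrow = TRUE))
  # numeric round trip through the inverse on a coordinate grid
  A2 <- ChannelAlignment(scale = c(1.02, 0.97), translation = c(3.5, -2.2),
                         theta = 0.03, width = 64, height = 64)
  M <- composeAlignment(A2)
  pts <- rbind(runif(50, 0, 63), runif(50, 0, 63), 1)
  back <- solve(M) %*% (M %*% pts)
  expect_lt(max(abs(back - pts)), 1e-10)
})

test_that("image resampling honors identity and integer-shift round trips", {
  set.seed(5)
  img <- simulateSpotPatch(32, 32, center = c(15, 17), size = c(4, 4),
                           intensity = 1, background = 0.2)
  expect_equal(applyAlignment(img, diag(3)), img)
  sh <- composeAlignment(ChannelAlignment(translation = c(1, 0),
                                          width = 32, height = 32))
  un <- composeAlignment(ChannelAlignment(translation = c(-1, 0),
                                          width = 32, height = 32))
  round2 <- applyAlignment(applyAlignment(img, sh), un)
  inner <- 3:30
  expect_equal(round2[inner, inner], img[inner, inner], tolerance = 1e-9)
})

test_that("alignment transform round trip keeps smooth images intact", {
  img <- simulateSpotPatch(48, 48, center = c(22, 25), size = c(6, 5),
                           theta = 0.2, intensity = 1, background = 0.2)
  A <- ChannelAlignment(scale = c(1.01, 0.99), translation = c(1.5, -0.8),
                        theta = 0.02, width = 48, height = 48)
  fwd <- applyAlignment(img, composeAlignment(A))
  back <- applyAlignment(fwd, solve(composeAlignment(A)))
  inner <- 6:43
  mse <- mean((back[inner, inner] - img[inner, inner])^2)
  psnr <- 10 * log10(max(img)^2 / mse)
  expect_gt(psnr, 40)
})

# smooth synthetic two-blob scene rendered analytically at transformed
# coordinates, so both channels are exact (no interpolation in the truth)
.renderScene <- function(W, H, A = diag(3)) {
  x <- rep(0:(W - 1), each = H); y <- rep(0:(H - 1), W)
  px <- A[1, 1] * x + A[1, 2] * y + A[1, 3]
  py <- A[2, 1] * x + A[2, 2] * y + A[2, 3]
  val <- exp(-((px - 20)^2 + (py - 25)^2) / (2 * 16)) +
    0.8 * exp(-((px - 42)^2 + (py - 38)^2) / (2 * 25)) +
    0.5 * exp(-((px - 30)^2 + (py - 12)^2) / (2 * 9))
  matrix(val, H, W)
}

test_that("channel alignment recovers identity, shifts and rotations", {
  W <- 64; H <- 64
  I1 <- .renderScene(W, H)
  # identical channels
  same <- estimateAlignment(I1, I1)
  expect_equal(same@scale, c(1, 1), tolerance = 1e-3)
  expect_equal(same@translation, c(0, 0), tolerance = 1e-3)
  expect_equal(same@theta, 0, tolerance = 1e-3)
  # known sub-pixel shift: channel 2 renders the scene displaced, so the
  # fitted transform (which maps channel-2 coordinates onto channel 1) must
  # recover the displacement itself
  Ash <- ChannelAlignment(translation = c(3.5, -2.25), width = W, height = H)
  I2 <- .renderScene(W, H, solve(composeAlignment(Ash)))
  est <- estimateAlignment(I1, I2)
  expect_equal(est@translation, c(3.5, -2.25), tolerance = 0.1)
  # 2 degree rotation about the center
  Arot <- ChannelAlignment(theta = 2 * pi / 180, width = W, height = H)
  I3 <- .renderScene(W, H, solve(composeAlignment(Arot)))
  est2 <- estimateAlignment(I1, I3)
  expect_lt(abs(est2@theta - 2 * pi / 180), 0.1 * pi / 180)
  # structureless images are flagged
  expect_warning(estimateAlignment(matrix(1, 16, 16), matrix(1, 16, 16)),
                 "low-confidence")
})
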