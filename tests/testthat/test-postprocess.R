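test_that("grayscale adjustment maps quantile endpoints and gamma", {
  # full-span channel, no saturation, gamma 1 -> identity
  v <- seq(0, 1, length.out = 64)
  img <- gray_rgb(matrix(v, 8, 8))
  expect_equal(adjust_gray_range(img, 0, 1, 1), img)
  # endpoint mapping and mid-value gamma
  out <- adjust_gray_range(img, 0, 1, 0.9)
  expect_equal(out[img == 0], rep(0, 3))
  expect_equal(out[img == 1], rep(1, 3))
  expect_equal(adjust_gray_range(gray_rgb(matrix(c(0, 0.5, 0.5, 1), 2, 2)),
                                 0, 1, 0.9)[1, 2, 1],
               0.5^0.9)
  # constant channel left unchanged
  flat <- gray_rgb(matrix(0.3, 4, 4))
  expect_equal(adjust_gray_range(flat), flat)
})

test_that("quantile saturation clips the stretched tails", {
  set.seed(61)
  x <- matrix(runif(400, 0.2, 0.8), 20, 20)
  x[1, 1] <- 0; x[20, 20] <- 1   # outliers the quantiles should ignore
  out <- adjust_gray_range(gray_rgb(x), 0.05, 0.95, 1)
  qs <- quantile(x, c(0.05, 0.95), names = FALSE)
  inside <- x > qs[1] & x < qs[2]
  expected <- ((x - qs[1]) / diff(qs))[inside]
  expect_equal(out[, , 1][inside], expected)
  expect_equal(out[1, 1, 1], 0)
  expect_equal(out[20, 20, 1], 1)
})

test_that("the denoiser is a no-op at zero noise and when disabled", {
  y <- rand_plane(20, 20, seed = 62)
  expect_identical(bm3d_denoise_plane(y, denoise_params(sigma_noise = 0)), y)
  expect_identical(bm3d_denoise_plane(y, denoise_params(enabled = FALSE)), y)
  flat <- matrix(0.5, 24, 24)   # estimated noise is zero on a constant plane
  expect_identical(bm3d_denoise_plane(flat), flat)
})

test_that("noise-sd estimation recovers the true sigma on flat + noise", {
  set.seed(63)
  y <- matrix(0.5 + rnorm(64 * 64, sd = 0.05), 64, 64)
  est <- relight:::estimate_noise_sd(y)
  expect_lt(abs(est - 0.05) / 0.05, 0.15)
})

test_that("collaborative filtering shrinks flat-region noise strongly", {
  set.seed(64)
  sigma <- 0.05
  clean <- matrix(0.5, 48, 48)
  noisy <- relight:::clamp01(clean + matrix(rnorm(48 * 48, sd = sigma),
                                            48, 48))
  den <- bm3d_denoise_plane(noisy, denoise_params(sigma_noise = sigma))
  expect_lt(sd(den), 0.4 * sd(noisy))
  expect_gt(psnr(den, clean), psnr(noisy, clean))
})

test_that("a noisy step edge keeps its location after denoising", {
  set.seed(65)
  clean <- matrix(0.2, 48, 48); clean[, 25:48] <- 0.8
  noisy <- relight:::clamp01(clean + matrix(rnorm(48 * 48, sd = 0.04),
                                            48, 48))
  den <- bm3d_denoise_plane(noisy, denoise_params(sigma_noise = 0.04))
  profile <- colMeans(den)
  edge <- which.max(abs(diff(profile)))
  expect_lte(abs(edge - 24), 1)
  expect_gt(psnr(den, clean), psnr(noisy, clean))
})

test_that("illumination-balanced recombination blends raw and denoised", {
  set.seed(66)
  r <- rand_rgb(24, 24, seed = 66)
  p <- denoise_params(sigma_noise = 0.05)
  yuv <- rgb_to_yuv(r)
  rd <- yuv_to_rgb(bm3d_denoise_plane(yuv$y, p), yuv$u, yuv$v)
  ones <- matrix(1, 24, 24)
  expect_equal(denoise_recombine(r, ones, p), r)
  expect_equal(denoise_recombine(r, ones * 0, p), rd)
  half <- denoise_recombine(r, ones * 0.5, p)
  expect_equal(half, relight:::clamp01((r + rd) / 2), tolerance = 1e-12)
  # always a pixelwise convex combination of raw and denoised
  t <- rand_plane(24, 24, seed = 67)
  mixed <- denoise_recombine(r, t, p)
  expect_true(all(mixed >= pmin(r, rd) - 1e-12))
  expect_true(all(mixed <= pmax(r, rd) + 1e-12))
})
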