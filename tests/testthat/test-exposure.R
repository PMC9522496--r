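test_that("luminance is the per-pixel channel maximum", {
  img <- array(0, c(1, 1, 3)); img[1, 1, ] <- c(0.2, 0.5, 0.3)
  img2 <- array(0.4, c(2, 2, 3))
  expect_error(luminance(img))  # below minimum size
  expect_equal(luminance(img2), matrix(0.4, 2, 2))
  r <- rand_rgb(7, 9, seed = 11)
  lum <- luminance(r)
  for (i in 1:7) for (j in 1:9)
    expect_identical(lum[i, j], max(r[i, j, ]))
  expect_equal(luminance(r, method = "mean"),
               (r[, , 1] + r[, , 2] + r[, , 3]) / 3)
})

test_that("image entropy matches closed-form histogram cases", {
  expect_equal(image_entropy(matrix(0.5, 4, 4)), 0)
  half <- matrix(c(rep(0.1, 8), rep(0.9, 8)), 4, 4)
  expect_equal(image_entropy(half), 1)
  quarters <- matrix(rep(c(0.1, 0.3, 0.6, 0.9), each = 4), 4, 4)
  expect_equal(image_entropy(quarters), 2)
  # value 1 falls in the right-closed last bin, no error
  expect_equal(image_entropy(matrix(1, 3, 3)), 0)
  # permutation invariance
  v <- rand_plane(6, 6, seed = 12)
  set.seed(13)
  perm <- matrix(sample(v), 6, 6)
  expect_equal(image_entropy(v), image_entropy(perm))
  expect_error(image_entropy(numeric(0)), "empty")
})

test_that("BTF evaluates its closed form and degenerates correctly", {
  cam <- camera_model()
  p <- rand_rgb(5, 5, seed = 14)
  expect_equal(btf_apply(p, 1, cam), p)
  expect_equal(btf_apply(array(0, c(2, 2, 3)), 3, cam),
               array(0, c(2, 2, 3)))
  # frozen high-precision scalar evaluation of exp(b(1-2^a)) * 0.5^(2^a)
  expect_equal(btf_apply(matrix(0.5, 2, 2), 2, cam)[1, 1],
               0.72474086026101703, tolerance = 1e-14)
  expect_error(btf_apply(p, 0, cam), "positive")
  expect_error(btf_apply(p, -1, cam), "positive")
  expect_error(camera_model(a = 0), "non-zero")
})

test_that("BTF composition law and monotonicity hold", {
  p <- rand_rgb(8, 8, seed = 15, lo = 0.01, hi = 0.5)
  cam <- camera_model()
  set.seed(16)
  for (rep in 1:5) {
    k1 <- runif(1, 0.5, 2); k2 <- runif(1, 0.5, 2)
    lhs <- btf_apply(btf_apply(p, k1, cam, clamp = FALSE), k2, cam,
                     clamp = FALSE)
    rhs <- btf_apply(p, k1 * k2, cam, clamp = FALSE)
    expect_lt(max(abs(lhs - rhs)), 1e-12)
  }
  x <- seq(0, 1, length.out = 64)
  for (k in c(0.3, 2, 5)) {
    y <- btf_apply(matrix(x, 8, 8), k, cam)
    expect_true(all(diff(as.vector(y)) >= 0))
  }
})

test_that("optimal exposure search agrees with an exhaustive grid oracle", {
  cfg <- pipeline_config()
  cam <- camera_model()
  img <- make_scene(fixture_spec(seed = 21, size = 96, scene = "mixed"))
  dark <- btf_apply(img, 0.25, cam)
  est <- find_optimal_exposure(dark, cam, cfg)
  # darkening by k0 = 0.25 is inverted at k = 4 (composition law)
  expect_lt(abs(est$k_hat - 4) / 4, 0.15)
  # entropy at k_hat >= 200-point log-spaced grid maximum (within 1e-3 bits)
  b <- relight:::clamp01(relight:::resize_bilinear(luminance(dark), 50L, 50L))
  grid <- exp(seq(log(cfg$k_lo), log(cfg$k_hi), length.out = 200))
  grid_ent <- vapply(grid, function(k)
    image_entropy(btf_apply(b, k, cam), cfg$n_bins), numeric(1))
  expect_gte(est$entropy, max(grid_ent) - 1e-3)
})

test_that("well-exposed and degenerate images return k_hat near 1", {
  img <- make_scene(fixture_spec(seed = 22, size = 96, scene = "gradient"))
  est <- find_optimal_exposure(img)
  expect_lt(est$k_hat, 1.3)
  expect_warning(est0 <- find_optimal_exposure(array(0.5, c(16, 16, 3))),
                 "constant")
  expect_equal(est0$k_hat, 1)
  expect_equal(est0$entropy, 0)
})
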