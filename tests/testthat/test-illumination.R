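test_that("initial illumination is the floored channel maximum", {
  r <- rand_rgb(6, 8, seed = 31)
  t0 <- initial_illumination(r)
  for (i in 1:6) for (j in 1:8)
    expect_identical(t0[i, j], max(max(r[i, j, ]), 1e-3))
  dark <- array(0, c(4, 4, 3))
  expect_equal(initial_illumination(dark), matrix(1e-3, 4, 4))
  g <- gray_rgb(matrix(0.42, 3, 3))
  expect_equal(initial_illumination(g), matrix(0.42, 3, 3))
})

test_that("forward-difference gradients match the elementwise oracle", {
  expect_equal(gradients(matrix(0.7, 5, 5)),
               list(h = matrix(0, 5, 5), v = matrix(0, 5, 5)))
  ramp <- matrix(rep(0.1 * (0:4), each = 4), 4, 5)
  g <- gradients(ramp)
  expect_equal(g$h[, 1:4], matrix(0.1, 4, 4))
  expect_equal(g$h[, 5], rep(0, 4))
  expect_equal(g$v, matrix(0, 4, 5))
  t4 <- rand_plane(4, 4, seed = 32)
  expect_equal(gradients(t4), grad_oracle(t4))
})

test_that("gradient weights match the brute-force windowed-sum oracle", {
  p <- solver_params()
  for (seed in 33:35) {
    t6 <- rand_plane(6, 6, seed = seed)
    w <- gradient_weights(t6, p)
    o <- gradient_weights_oracle(t6, p)
    expect_lt(max(abs(w$w_h - o$w_h)), 1e-10)
    expect_lt(max(abs(w$w_v - o$w_v)), 1e-10)
  }
  # distinct numerator bandwidth still matches
  p2 <- solver_params(sigma = 1.3, sigma_num = 2.6, window_radius = 1)
  t6 <- rand_plane(6, 7, seed = 36)
  w <- gradient_weights(t6, p2)
  o <- gradient_weights_oracle(t6, p2)
  expect_lt(max(abs(w$w_h - o$w_h)), 1e-10)
  expect_lt(max(abs(w$w_v - o$w_v)), 1e-10)
})

test_that("flat maps give the zero-gradient weight limit 1/epsilon", {
  p <- solver_params(epsilon = 1e-3, window_radius = 2)
  w <- gradient_weights(matrix(0.5, 10, 10), p)
  # interior pixels: normalized kernel sums to 1, denominator is epsilon
  expect_equal(w$w_h[3:8, 3:8], matrix(1e3, 6, 6))
  expect_equal(w$w_v[3:8, 3:8], matrix(1e3, 6, 6))
  expect_true(all(w$w_h > 0) && all(w$w_v > 0))
})

test_that("weights are small across a strong edge, large in flat areas", {
  t8 <- matrix(0.1, 8, 8)
  t8[, 5:8] <- 0.9             # vertical edge between columns 4 and 5
  w <- gradient_weights(t8, solver_params())
  expect_lt(w$w_h[4, 4], w$w_h[4, 1] / 10)
  o <- gradient_weights_oracle(t8, solver_params())
  expect_lt(max(abs(w$w_h - o$w_h)), 1e-10)
})

test_that("illumination refinement matches the dense direct solve", {
  p <- solver_params(alpha = 0.15)
  for (dims in list(c(5, 5), c(7, 4), c(12, 12))) {
    t0 <- rand_plane(dims[1], dims[2], seed = sum(dims), lo = 0.05,
                     hi = 0.95)
    w <- gradient_weights(t0, p)
    expect_lt(max(abs(refine_illumination(t0, w, p) -
                        refine_oracle(t0, w, p))), 1e-8)
  }
})

test_that("refinement limits: alpha = 0 and constant maps are fixed points", {
  t0 <- rand_plane(6, 6, seed = 41, lo = 0.05, hi = 0.95)
  p0 <- solver_params(alpha = 0)
  expect_equal(refine_illumination(t0, gradient_weights(t0, p0), p0), t0)
  const <- matrix(0.6, 7, 7)
  p <- solver_params(alpha = 0.15)
  expect_equal(refine_illumination(const, gradient_weights(const, p), p),
               const, tolerance = 1e-10)
})

test_that("smoothing is monotone in alpha and decreases the objective", {
  t0 <- rand_plane(10, 10, seed = 42, lo = 0.05, hi = 0.95)
  tv <- function(t) { g <- gradients(t); sum(abs(g$h)) + sum(abs(g$v)) }
  alphas <- c(0.01, 0.05, 0.15, 0.5, 2)
  tvs <- vapply(alphas, function(a) {
    p <- solver_params(alpha = a)
    tv(refine_illumination(t0, gradient_weights(t0, p), p))
  }, numeric(1))
  expect_true(all(diff(tvs) <= 1e-10))
  p <- solver_params(alpha = 0.15)
  w <- gradient_weights(t0, p)
  sol <- refine_illumination(t0, w, p)
  expect_lte(refine_objective(sol, t0, w, p),
             refine_objective(t0, t0, w, p))
})
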