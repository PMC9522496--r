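# Shared fixtures and independent brute-force oracles. Every oracle here
# is written as plain loops over the defining formulas, deliberately not
# reusing the package's vectorized/sparse code paths.

rand_rgb <- function(h, w, seed, lo = 0, hi = 1) {
  set.seed(seed)
  array(runif(h * w * 3, lo, hi), c(h, w, 3L))
}

rand_plane <- function(h, w, seed, lo = 0, hi = 1) {
  set.seed(seed)
  matrix(runif(h * w, lo, hi), h, w)
}

gray_rgb <- function(mat) array(rep(mat, 3L), c(dim(mat), 3L))

# Forward differences by explicit loops (Neumann boundary).
grad_oracle <- function(t) {
  H <- nrow(t); W <- ncol(t)
  dh <- matrix(0, H, W); dv <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    if (j < W) dh[i, j] <- t[i, j + 1] - t[i, j]
    if (i < H) dv[i, j] <- t[i + 1, j] - t[i, j]
  }
  list(h = dh, v = dv)
}

# Windowed Gaussian gradient pooling by double loop over pixels and
# window members (window clipped at the image border); the kernel is the
# truncated Gaussian normalized to unit sum over the full window.
gradient_weights_oracle <- function(t_hat, p) {
  H <- nrow(t_hat); W <- ncol(t_hat)
  g <- grad_oracle(t_hat)
  r <- p$window_radius
  offs <- expand.grid(di = -r:r, dj = -r:r)
  gfun <- function(sig) {
    v <- exp(-(offs$di^2 + offs$dj^2) / (2 * sig^2))
    v / sum(v)
  }
  kn <- gfun(p$sigma_num); kd <- gfun(p$sigma)
  w_h <- matrix(0, H, W); w_v <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    num <- 0; dh <- 0; dv <- 0
    for (m in seq_len(nrow(offs))) {
      yi <- i + offs$di[m]; yj <- j + offs$dj[m]
      if (yi >= 1 && yi <= H && yj >= 1 && yj <= W) {
        num <- num + kn[m]
        dh <- dh + kd[m] * g$h[yi, yj]
        dv <- dv + kd[m] * g$v[yi, yj]
      }
    }
    w_h[i, j] <- num / (abs(dh) + p$epsilon)
    w_v[i, j] <- num / (abs(dv) + p$epsilon)
  }
  list(w_h = w_h, w_v = w_v)
}

# Dense direct solve of the refinement system, with the difference
# operators assembled entry by entry.
refine_oracle <- function(t_hat, w, p) {
  H <- nrow(t_hat); W <- ncol(t_hat); n <- H * W
  idx <- function(i, j) i + (j - 1) * H
  Dh <- matrix(0, n, n); Dv <- matrix(0, n, n)
  for (i in 1:H) for (j in 1:W) {
    r <- idx(i, j)
    if (j < W) { Dh[r, r] <- -1; Dh[r, idx(i, j + 1)] <- 1 }
    if (i < H) { Dv[r, r] <- -1; Dv[r, idx(i + 1, j)] <- 1 }
  }
  g <- grad_oracle(t_hat)
  wth <- as.vector(w$w_h / (abs(g$h) + p$epsilon))
  wtv <- as.vector(w$w_v / (abs(g$v) + p$epsilon))
  A <- diag(n) + p$alpha * (t(Dh) %*% diag(wth) %*% Dh +
                              t(Dv) %*% diag(wtv) %*% Dv)
  tv <- solve(A, as.vector(t_hat))
  matrix(pmin(pmax(tv, 1e-3), 1), H, W)
}

# Relaxed smoothing objective: ||t - t_hat||_F^2 + alpha * sum_d w~_d (grad_d t)^2
refine_objective <- function(t, t_hat, w, p) {
  g0 <- grad_oracle(t_hat)
  gt <- grad_oracle(t)
  wth <- w$w_h / (abs(g0$h) + p$epsilon)
  wtv <- w$w_v / (abs(g0$v) + p$epsilon)
  sum((t - t_hat)^2) + p$alpha * (sum(wth * gt$h^2) + sum(wtv * gt$v^2))
}

# Exhaustive pair enumeration of the lightness order error at full
# resolution (no downsampling), on the channel-max lightness planes.
loe_oracle <- function(enhanced, reference) {
  q <- as.vector(pmax(enhanced[, , 1], enhanced[, , 2], enhanced[, , 3]))
  qr <- as.vector(pmax(reference[, , 1], reference[, , 2], reference[, , 3]))
  m <- length(q)
  tot <- 0
  for (x in 1:m) for (y in 1:m)
    tot <- tot + xor(q[x] >= q[y], qr[x] >= qr[y])
  tot / m
}

# Straight-line pixel-domain VIF: loops over pixels for every windowed
# moment, mirrored borders, 4 dyadic scales, scalar GSM accumulation.
vif_oracle <- function(enh_mat, ref_mat, sigma_nsq = 2) {
  reflect <- function(n, r) {
    idx <- (1 - r):(n + r)
    idx <- ifelse(idx < 1, 1 - idx, idx)
    idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
    pmin(pmax(idx, 1), n)
  }
  filt <- function(x, kern) {
    r <- (nrow(kern) - 1) / 2
    xp <- x[reflect(nrow(x), r), reflect(ncol(x), r), drop = FALSE]
    H <- nrow(x); W <- ncol(x)
    out <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W)
      out[i, j] <- sum(kern * xp[i:(i + 2 * r), j:(j + 2 * r)])
    out
  }
  ref <- ref_mat * 255; dist <- enh_mat * 255
  num <- 0; den <- 0
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    r <- (N - 1) / 2
    d <- (-r):r
    kern <- exp(-outer(d^2, d^2, `+`) / (2 * (N / 5)^2))
    kern <- kern / sum(kern)
    if (scale > 1) {
      ref <- filt(ref, kern)[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2),
                             drop = FALSE]
      dist <- filt(dist, kern)[seq(1, nrow(dist), 2), seq(1, ncol(dist), 2),
                               drop = FALSE]
      if (min(dim(ref)) < 2) break
    }
    mu1 <- filt(ref, kern); mu2 <- filt(dist, kern)
    s1 <- pmax(filt(ref * ref, kern) - mu1^2, 0)
    s2 <- pmax(filt(dist * dist, kern) - mu2^2, 0)
    s12 <- filt(ref * dist, kern) - mu1 * mu2
    for (i in seq_along(s1)) {
      if (s1[i] > 0) { g <- s12[i] / s1[i]; sv <- s2[i] - g * s12[i] }
      else { g <- 0; sv <- s2[i] }
      if (g < 0) { sv <- s2[i]; g <- 0 }
      sv <- max(sv, 0)
      num <- num + log2(1 + g^2 * s1[i] / (sv + sigma_nsq))
      den <- den + log2(1 + s1[i] / sigma_nsq)
    }
  }
  num / den
}
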