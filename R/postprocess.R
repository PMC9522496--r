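#' Quantile-based grayscale range adjustment
#'
#' Per channel, stretches the intensity range between the `q_low` and
#' `q_high` quantiles to `[0, 1]` (saturating 1% at each tail by default)
#' and applies a gamma curve, `x -> clip((x - lo)/(hi - lo), 0, 1)^gamma`.
#' A gamma slightly below 1 (default 0.9) lifts mid-tones. Channels whose
#' quantiles coincide (constant channels) are returned unchanged.
#'
#' @param img an `H x W x 3` RGB array in `[0, 1]`.
#' @param q_low,q_high saturation quantiles, `0 <= q_low < q_high <= 1`.
#' @param gamma positive gamma exponent.
#' @return The adjusted RGB image.
#' @export
adjust_gray_range <- function(img, q_low = 0.01, q_high = 0.99, gamma = 0.9) {
  assert_rgb(img)
  stopifnot(q_low >= 0, q_high <= 1, q_low < q_high, gamma > 0)
  out <- img
  for (c in 1:3) {
    x <- img[, , c]
    qs <- stats::quantile(x, c(q_low, q_high), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
    if (hi <= lo) next
    out[, , c] <- clamp01((x - lo) / (hi - lo))^gamma
  }
  out
}

# Orthonormal DCT-II matrix (rows are basis functions).
dct_matrix <- function(n) {
  j <- seq_len(n)
  m <- sqrt(2 / n) * cos(pi * outer(seq_len(n) - 1, 2 * j - 1) / (2 * n))
  m[1, ] <- sqrt(1 / n)
  m
}

# Orthonormal Haar matrix; n must be a power of two.
haar_matrix <- function(n) {
  stopifnot(n >= 1, bitwAnd(n, n - 1L) == 0L)
  h <- matrix(1, 1, 1)
  while (nrow(h) < n) {
    m <- nrow(h)
    h <- rbind(kronecker(h, matrix(c(1, 1) / sqrt(2), 1, 2)),
               kronecker(diag(m), matrix(c(1, -1) / sqrt(2), 1, 2)))
  }
  h
}

# All sliding bs x bs blocks of y as columns (column-major within block);
# column index is bi + (bj - 1) * nbi for top-left corner (bi, bj).
block_patches <- function(y, bs) {
  H <- nrow(y); W <- ncol(y)
  nbi <- H - bs + 1L; nbj <- W - bs + 1L
  P <- matrix(0, bs * bs, nbi * nbj)
  for (dj in 0:(bs - 1L)) {
    for (di in 0:(bs - 1L)) {
      P[di + dj * bs + 1L, ] <-
        as.vector(y[(1L + di):(nbi + di), (1L + dj):(nbj + dj)])
    }
  }
  P
}

# Robust noise-sd estimate from the finest diagonal detail coefficients
# (2x2 Haar HH band); exact for additive white Gaussian noise.
estimate_noise_sd <- function(y) {
  H <- nrow(y); W <- ncol(y)
  if (H < 2L || W < 2L) return(0)
  d <- (y[-H, -W] - y[-1, -W] - y[-H, -1] + y[-1, -1]) / 2
  stats::median(abs(d)) / 0.6745
}

# One collaborative-filtering pass. y_noisy supplies the coefficients to
# filter; y_match the image blocks are matched on (the noisy input in the
# basic stage, the basic estimate in the final stage). When wiener_ref is
# non-NULL its coefficient energies drive empirical Wiener shrinkage,
# otherwise coefficients are hard-thresholded at ht_threshold * sigma.
bm3d_stage <- function(y_noisy, y_match, sigma, p, wiener_ref = NULL) {
  H <- nrow(y_noisy); W <- ncol(y_noisy)
  bs <- min(p$block_size, H, W)
  nbi <- H - bs + 1L; nbj <- W - bs + 1L
  Pn <- block_patches(y_noisy, bs)
  Pm <- if (identical(y_match, y_noisy)) Pn else block_patches(y_match, bs)
  K <- kronecker(dct_matrix(bs), dct_matrix(bs))
  Tn <- K %*% Pn
  Tb <- if (!is.null(wiener_ref)) K %*% block_patches(wiener_ref, bs)
  refs_i <- unique(c(seq(1L, nbi, by = p$step), nbi))
  refs_j <- unique(c(seq(1L, nbj, by = p$step), nbj))
  nm_max <- min(p$max_matches,
                (2L * p$search_radius + 1L)^2)
  haar_cache <- lapply(0:floor(log2(nm_max)), function(e) haar_matrix(2^e))
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  thr <- p$ht_threshold * sigma
  for (rj in refs_j) {
    cj <- max(1L, rj - p$search_radius):min(nbj, rj + p$search_radius)
    cj_off <- (cj - 1L) * nbi
    for (ri in refs_i) {
      ci <- max(1L, ri - p$search_radius):min(nbi, ri + p$search_radius)
      cand <- as.vector(outer(ci, cj_off, `+`))
      refcol <- ri + (rj - 1L) * nbi
      dmat <- Pm[, cand, drop = FALSE] - Pm[, refcol]
      d <- colSums(dmat * dmat)
      nm <- 2^floor(log2(min(p$max_matches, length(cand))))
      sel <- cand[order(d)[seq_len(nm)]]
      Hm <- haar_cache[[log2(nm) + 1L]]
      if (is.null(wiener_ref)) {
        coef <- Tn[, sel, drop = FALSE] %*% t(Hm)
        keep <- abs(coef) > thr
        keep[1L, 1L] <- TRUE          # always keep the group DC
        coef[!keep] <- 0
        wgt <- 1 / max(sum(keep), 1L)
        est_t <- coef %*% Hm
      } else {
        cb <- Tb[, sel, drop = FALSE] %*% t(Hm)
        cn <- Tn[, sel, drop = FALSE] %*% t(Hm)
        shrink <- cb^2 / (cb^2 + sigma^2)
        wgt <- 1 / (sum(shrink^2) + 1e-12)
        est_t <- (shrink * cn) %*% Hm
      }
      est <- crossprod(K, est_t)       # inverse 2-D DCT
      for (m in seq_len(nm)) {
        pos <- sel[m]
        bi <- ((pos - 1L) %% nbi) + 1L
        bj <- ((pos - 1L) %/% nbi) + 1L
        ridx <- bi:(bi + bs - 1L); cidx <- bj:(bj + bs - 1L)
        num[ridx, cidx] <- num[ridx, cidx] + wgt * matrix(est[, m], bs, bs)
        den[ridx, cidx] <- den[ridx, cidx] + wgt
      }
    }
  }
  num / pmax(den, 1e-12)
}

#' Denoise a single plane with two-stage block-matching 3D filtering
#'
#' A compact BM3D: sliding blocks are grouped by L2 similarity within a
#' search window, the group is transformed by a separable orthonormal
#' 2-D DCT (spatial) plus 1-D Haar (along the stack), coefficients are
#' shrunk, and overlapping estimates are aggregated with per-group
#' weights. Stage one hard-thresholds at `ht_threshold * sigma_noise` to
#' form a basic estimate; stage two re-matches on the basic estimate and
#' applies empirical Wiener shrinkage using the basic estimate's
#' coefficient energies. Deterministic given its inputs. A no-op when
#' `sigma_noise = 0` (or estimated zero) or when denoising is disabled.
#'
#' @param y numeric matrix with values in `[0, 1]`.
#' @param p a [denoise_params()]; when `p$sigma_noise` is `NULL` the noise
#'   level is estimated from the finest diagonal detail band.
#' @return The denoised plane, clamped to `[0, 1]`.
#' @export
bm3d_denoise_plane <- function(y, p = denoise_params()) {
  assert_plane(y, "y")
  if (min(y) < 0 || max(y) > 1)
    stop("plane values must lie in [0, 1]", call. = FALSE)
  if (!p$enabled) return(y)
  sigma <- if (is.null(p$sigma_noise)) estimate_noise_sd(y) else p$sigma_noise
  if (sigma <= 0) return(y)
  basic <- bm3d_stage(y, y, sigma, p)
  final <- bm3d_stage(y, basic, sigma, p, wiener_ref = basic)
  clamp01(final)
}

#' Illumination-balanced denoising of an RGB image
#'
#' Converts to YUV, denoises only the luma channel with
#' [bm3d_denoise_plane()], rebuilds the image with the original chroma,
#' and blends the raw and denoised images by the illumination map:
#' `R_f = R * T + R_d * (1 - T)`. Bright regions (high T) keep the raw
#' rendition to avoid over-smoothing; dark regions — where enhancement
#' amplified noise the most — take the denoised one.
#'
#' @param r RGB image to balance-denoise.
#' @param t illumination map in `[0, 1]`, same spatial shape.
#' @param p a [denoise_params()].
#' @return The recombined RGB image in `[0, 1]`.
#' @export
denoise_recombine <- function(r, t, p = denoise_params()) {
  assert_rgb(r, "r"); assert_plane(t, "t")
  if (!all(dim(t) == dim(r)[1:2]))
    stop("illumination map shape must match the image", call. = FALSE)
  if (min(t) < 0 || max(t) > 1)
    stop("illumination map must lie in [0, 1]", call. = FALSE)
  if (!p$enabled) return(clamp01(r))
  yuv <- rgb_to_yuv(r)
  yd <- bm3d_denoise_plane(yuv$y, p)
  rd <- yuv_to_rgb(yd, yuv$u, yuv$v)
  out <- r
  for (c in 1:3) out[, , c] <- r[, , c] * t + rd[, , c] * (1 - t)
  clamp01(out)
}
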