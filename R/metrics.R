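# Nearest-neighbor downsample of a matrix to s x s (sampling at cell
# centers); never interpolates, so no new intensity orderings are created.
nn_downsample <- function(mat, s) {
  H <- nrow(mat); W <- ncol(mat)
  si <- min(s, H); sj <- min(s, W)
  ri <- pmin(floor((seq_len(si) - 0.5) * H / si) + 1L, H)
  cj <- pmin(floor((seq_len(sj) - 0.5) * W / sj) + 1L, W)
  mat[ri, cj, drop = FALSE]
}

#' Lightness order error (LOE)
#'
#' Measures how much an enhancement disturbs the relative lightness order
#' of the scene, a proxy for naturalness. Lightness is the per-pixel
#' channel maximum; both lightness planes are downsampled (nearest
#' neighbor) to at most `eval_size` pixels per side, and over all ordered
#' pixel pairs (x, y) the indicator `U(p, q) = 1 iff p >= q` is compared
#' between the two images:
#' `LOE = (1/m) * sum_x sum_y [U(Q(x), Q(y)) XOR U(Q_r(x), Q_r(y))]`
#' with `m` the number of evaluated pixels. Zero means the order is fully
#' preserved; lower is better.
#'
#' @param enhanced,reference RGB arrays of identical shape.
#' @param eval_size evaluation side length (default 100); the double sum
#'   is quadratic in `eval_size^2`.
#' @param normalization `"m"` (default) divides by the pixel count, as the
#'   definition states; `"m2"` divides by the number of pairs, yielding a
#'   disagreement fraction in `[0, 1]`.
#' @return A non-negative scalar.
#' @export
lightness_order_error <- function(enhanced, reference, eval_size = 100L,
                                  normalization = c("m", "m2")) {
  assert_rgb(enhanced, "enhanced"); assert_rgb(reference, "reference")
  assert_same_shape(enhanced, reference, "images")
  normalization <- match.arg(normalization)
  stopifnot(eval_size >= 2)
  q <- as.vector(nn_downsample(luminance(enhanced), eval_size))
  qr <- as.vector(nn_downsample(luminance(reference), eval_size))
  m <- length(q)
  total <- 0
  chunk <- 1024L
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    u <- outer(q[idx], q, `>=`)
    ur <- outer(qr[idx], qr, `>=`)
    total <- total + sum(u != ur)
  }
  total / if (normalization == "m") m else m^2
}

#' Visual information fidelity (VIF), pixel domain
#'
#' Ratio of the mutual information a model visual system can extract from
#' the test image versus the reference image under a scalar
#' Gaussian-scale-mixture signal model: the reference's local variance
#' `sigma_C^2` carries the information, the test image is modeled as a
#' local gain `g` on the reference plus distortion noise `sigma_V^2`, and
#' both channels see additive visual noise `sigma_N^2 = 2` (on the 0-255
#' intensity scale). Computed at four dyadic scales in the pixel domain
#' with Gaussian windows (window side 2^(5 - scale) + 1, sd = side/5),
#' accumulating `sum log2(1 + g^2 sigma_C^2 / (sigma_V^2 + sigma_N^2))`
#' over `sum log2(1 + sigma_C^2 / sigma_N^2)`. All filtering uses
#' same-size convolution with mirrored borders, so images as small as
#' 2 x 2 are handled; scales are dropped once decimation leaves fewer
#' than 2 pixels per side. Equals 1 exactly when the images are
#' identical; decreases as distortion grows; can exceed 1 for
#' contrast-enhanced images.
#'
#' @param enhanced,reference RGB arrays (or matrices, taken as luminance
#'   directly) of identical shape.
#' @param sigma_nsq visual noise variance on the 0-255 scale (default 2).
#' @return A scalar, typically in `[0, 1]` for degradations.
#' @export
visual_information_fidelity <- function(enhanced, reference, sigma_nsq = 2) {
  to_luma <- function(x)
    if (is.matrix(x)) x else rgb_to_yuv(x)$y
  if (!is.matrix(enhanced)) assert_rgb(enhanced, "enhanced")
  if (!is.matrix(reference)) assert_rgb(reference, "reference")
  assert_same_shape(enhanced, reference, "images")
  ref <- to_luma(reference) * 255
  dist <- to_luma(enhanced) * 255
  if (stats::var(as.vector(ref)) == 0)
    stop("zero-variance reference: fidelity undefined", call. = FALSE)
  num <- 0; den <- 0; used <- 0L
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    win <- gaussian_kernel((N - 1L) %/% 2L, N / 5)
    if (scale > 1) {
      ref <- conv2_same(ref, win, pad = "reflect")
      dist <- conv2_same(dist, win, pad = "reflect")
      ref <- ref[seq(1L, nrow(ref), 2L), seq(1L, ncol(ref), 2L), drop = FALSE]
      dist <- dist[seq(1L, nrow(dist), 2L), seq(1L, ncol(dist), 2L),
                   drop = FALSE]
      if (min(dim(ref)) < 2L) break
    }
    mu1 <- conv2_same(ref, win, pad = "reflect")
    mu2 <- conv2_same(dist, win, pad = "reflect")
    s1 <- pmax(conv2_same(ref * ref, win, pad = "reflect") - mu1 * mu1, 0)
    s2 <- pmax(conv2_same(dist * dist, win, pad = "reflect") - mu2 * mu2, 0)
    s12 <- conv2_same(ref * dist, win, pad = "reflect") - mu1 * mu2
    g <- ifelse(s1 > 0, s12 / s1, 0)
    sv <- s2 - g * s12
    neg <- g < 0
    sv[neg] <- s2[neg]
    g[neg] <- 0
    sv <- pmax(sv, 0)
    num <- num + sum(log2(1 + g * g * s1 / (sv + sigma_nsq)))
    den <- den + sum(log2(1 + s1 / sigma_nsq))
    used <- used + 1L
  }
  if (used == 0L || den <= 0)
    stop("images too small or too flat for the VIF model", call. = FALSE)
  num / den
}
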