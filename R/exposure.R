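#' Luminance plane of an RGB image
#'
#' Per-pixel maximum over the three channels, matching the convention used
#' for the initial illumination map. Set `method = "mean"` for the channel
#' average instead.
#'
#' @param img an `H x W x 3` RGB array in `[0, 1]`.
#' @param method `"max"` (default) or `"mean"`.
#' @return An `H x W` matrix.
#' @export
luminance <- function(img, method = c("max", "mean")) {
  assert_rgb(img)
  method <- match.arg(method)
  if (method == "max")
    pmax(img[, , 1L], img[, , 2L], img[, , 3L])
  else
    (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
}

#' Shannon entropy of an intensity plane
#'
#' Entropy in bits of the normalized histogram of `b` over `n_bins`
#' uniform bins on `[0, 1]` (the last bin is right-closed, so a value of
#' exactly 1 falls in bin `n_bins`). Empty bins contribute zero.
#'
#' @param b numeric matrix or vector with values in `[0, 1]`.
#' @param n_bins number of histogram bins (default 256).
#' @return Entropy in bits, in `[0, log2(n_bins)]`.
#' @export
image_entropy <- function(b, n_bins = 256L) {
  if (length(b) == 0L) stop("empty intensity map", call. = FALSE)
  stopifnot(n_bins >= 2)
  v <- as.vector(b)
  if (min(v) < 0 || max(v) > 1)
    stop("intensity values must lie in [0, 1]", call. = FALSE)
  bin <- pmin(floor(v * n_bins) + 1L, as.integer(n_bins))
  p <- tabulate(bin, nbins = as.integer(n_bins)) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Apply the brightness transfer function
#'
#' Simulates re-exposing an image by the ratio `k` through the parametric
#' camera response model `g(P, k) = exp(b * (1 - k^a)) * P^(k^a)`; `k > 1`
#' brightens under the default parameters, `k < 1` darkens, and `k = 1` is
#' the identity. The same parameters apply to all channels, since typical
#' camera response curves are nearly channel-independent.
#'
#' @param x RGB array or single-channel matrix with values in `[0, 1]`.
#' @param k exposure ratio, `k > 0`.
#' @param cam a [camera_model()].
#' @param clamp clamp the result to `[0, 1]` (default `TRUE`). Disable to
#'   study the exact algebra of the model (it satisfies the composition
#'   law `g(g(P, k1), k2) = g(P, k1 * k2)` only before clamping).
#' @return Object of the same shape as `x`.
#' @export
btf_apply <- function(x, k, cam = camera_model(), clamp = TRUE) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("exposure ratio `k` must be a single positive number", call. = FALSE)
  stopifnot(inherits(cam, "camera_model"))
  ka <- k^cam$a
  out <- exp(cam$b * (1 - ka)) * x^ka
  if (clamp) out <- clamp01(out)
  out
}

#' Find the entropy-optimal exposure ratio
#'
#' Searches for the exposure ratio whose BTF-re-exposed luminance has
#' maximal histogram entropy. The luminance is first resized to 50 x 50
#' (bilinear) for speed; the search combines a log-spaced grid over
#' `[k_lo, k_hi]` with a golden-section refinement around the best grid
#' point, guarding against non-unimodality of the entropy curve.
#'
#' @param img an `H x W x 3` RGB array in `[0, 1]`.
#' @param cam a [camera_model()].
#' @param cfg a [pipeline_config()] supplying `k_lo`, `k_hi`, `n_bins`.
#' @param n_grid number of seeding grid points.
#' @return An object of class `exposure_estimate`: a list with `k_hat`,
#'   `entropy` (bits at `k_hat`), `search_lo`, `search_hi`.
#' @export
find_optimal_exposure <- function(img, cam = camera_model(),
                                  cfg = pipeline_config(), n_grid = 101L) {
  assert_rgb(img)
  stopifnot(inherits(cfg, "pipeline_config"))
  b <- clamp01(resize_bilinear(luminance(img), 50L, 50L))
  if (diff(range(b)) < 1e-12) {
    warning("constant image: entropy is flat, returning k_hat = 1")
    return(structure(list(k_hat = 1, entropy = 0,
                          search_lo = cfg$k_lo, search_hi = cfg$k_hi),
                     class = "exposure_estimate"))
  }
  obj <- function(k) image_entropy(btf_apply(b, k, cam), cfg$n_bins)
  ks <- exp(seq(log(cfg$k_lo), log(cfg$k_hi), length.out = n_grid))
  ent <- vapply(ks, obj, numeric(1))
  i <- which.max(ent)
  lo <- ks[max(i - 1L, 1L)]
  hi <- ks[min(i + 1L, length(ks))]
  best_k <- ks[i]; best_e <- ent[i]
  if (hi > lo) {
    op <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE,
                          tol = 1e-4)
    if (op$objective >= best_e) {
      best_k <- op$maximum; best_e <- op$objective
    }
  }
  structure(list(k_hat = best_k, entropy = best_e,
                 search_lo = cfg$k_lo, search_hi = cfg$k_hi),
            class = "exposure_estimate")
}

#' @export
print.exposure_estimate <- function(x, ...) {
  cat(sprintf("exposure estimate: k_hat = %.4f (entropy %.4f bits, search [%g, %g])\n",
              x$k_hat, x$entropy, x$search_lo, x$search_hi))
  invisible(x)
}

# Bilinear resize of a single-channel matrix via EBImage.
resize_bilinear <- function(mat, h, w) {
  if (nrow(mat) == h && ncol(mat) == w) return(mat)
  # EBImage images are (x, y) = (width, height)
  img <- EBImage::Image(t(mat))
  t(EBImage::imageData(EBImage::resize(img, w = w, h = h)))
}
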