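#' Fusion weight from the refined illumination map
#'
#' Per-pixel weight `W = T^mu` given to the original image when blending
#' it with the synthesized exposure. Well-lit pixels (T near 1) keep the
#' original; dark pixels (T small) take the brightened rendition. `mu = 1`
#' uses the illumination directly; `mu = 0` disables fusion (original
#' kept everywhere).
#'
#' @param t illumination map with values in `[1e-3, 1]`.
#' @param mu non-negative exponent.
#' @return An `H x W` weight matrix in `(0, 1]`.
#' @export
fusion_weight <- function(t, mu = 1) {
  assert_plane(t, "t")
  stopifnot(mu >= 0)
  if (min(t) < EPS_T - 1e-12 || max(t) > 1)
    stop("illumination map must lie in [1e-3, 1]", call. = FALSE)
  t^mu
}

#' Fuse the original image with the synthesized exposure
#'
#' Per-channel convex combination `R_c = W * P_c + (1 - W) * P_syn_c`,
#' so the result lies pixelwise between the two inputs; the weight map is
#' broadcast over channels. Clamped to `[0, 1]`.
#'
#' @param p original RGB image.
#' @param p_syn synthesized dual-exposure RGB image of the same shape.
#' @param w weight matrix in `[0, 1]` with the images' spatial shape.
#' @return The fused RGB image.
#' @export
fuse <- function(p, p_syn, w) {
  assert_rgb(p, "p"); assert_rgb(p_syn, "p_syn"); assert_plane(w, "w")
  assert_same_shape(p, p_syn, "images")
  if (!all(dim(w) == dim(p)[1:2]))
    stop("weight map shape must match the images", call. = FALSE)
  if (min(w) < 0 || max(w) > 1)
    stop("fusion weights must lie in [0, 1]", call. = FALSE)
  out <- p
  for (c in 1:3) out[, , c] <- w * p[, , c] + (1 - w) * p_syn[, , c]
  clamp01(out)
}
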