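#' Camera response model parameters
#'
#' The brightness transfer function (BTF) relating two renditions of the
#' same scene at exposures differing by a ratio `k` is
#' `g(P, k) = exp(b * (1 - k^a)) * P^(k^a)`. The defaults are generic
#' camera-response constants that fit most consumer cameras.
#'
#' @param a curvature parameter of the BTF; must be non-zero.
#' @param b gain parameter of the BTF.
#' @return An object of class `camera_model`.
#' @seealso [btf_apply()]
#' @export
camera_model <- function(a = -0.3293, b = 1.1258) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L,
            is.finite(a), is.finite(b))
  if (a == 0) stop("camera parameter `a` must be non-zero (k^a degenerates)",
                   call. = FALSE)
  structure(list(a = a, b = b), class = "camera_model")
}

#' Parameters of the structure-aware illumination solver
#'
#' @param alpha smoothness weight balancing fidelity to the initial map
#'   against gradient sparsity; `alpha = 0` returns the initial map.
#' @param epsilon small positive constant guarding denominators in the
#'   gradient weights.
#' @param sigma spatial scale (pixels) of the Gaussian window used when
#'   pooling gradients around each pixel.
#' @param sigma_num bandwidth of the numerator kernel; equal to `sigma`
#'   by default (a single Gaussian window).
#' @param window_radius half-width of the pooling window, so the window is
#'   `(2 * window_radius + 1)^2` pixels.
#' @return An object of class `solver_params`.
#' @export
solver_params <- function(alpha = 0.15, epsilon = 1e-3, sigma = 2,
                          sigma_num = sigma, window_radius = 2L) {
  stopifnot(alpha >= 0, epsilon > 0, sigma > 0, sigma_num > 0,
            window_radius >= 1)
  structure(list(alpha = alpha, epsilon = epsilon, sigma = sigma,
                 sigma_num = sigma_num,
                 window_radius = as.integer(window_radius)),
            class = "solver_params")
}

#' Parameters of the two-stage BM3D luminance denoiser
#'
#' @param sigma_noise assumed noise standard deviation on the `[0, 1]`
#'   intensity scale; `NULL` (default) estimates it from the median
#'   absolute deviation of the finest diagonal detail coefficients.
#' @param block_size patch side in pixels.
#' @param search_radius block-matching search half-width in pixels.
#' @param max_matches maximum number of similar blocks stacked per group
#'   (rounded down to a power of two for the orthonormal Haar transform).
#' @param ht_threshold hard-threshold multiplier applied to
#'   `sigma_noise` in the first (basic) stage.
#' @param step stride between reference blocks; smaller is slower and
#'   slightly higher quality.
#' @param enabled logical; `FALSE` turns the denoising stage into a no-op.
#' @return An object of class `denoise_params`.
#' @export
denoise_params <- function(sigma_noise = NULL, block_size = 8L,
                           search_radius = 16L, max_matches = 16L,
                           ht_threshold = 2.7, step = 4L, enabled = TRUE) {
  stopifnot(block_size >= 4, max_matches >= 1, search_radius >= 1,
            ht_threshold >= 0, step >= 1,
            is.null(sigma_noise) || sigma_noise >= 0)
  structure(list(sigma_noise = sigma_noise,
                 block_size = as.integer(block_size),
                 search_radius = as.integer(search_radius),
                 max_matches = as.integer(max_matches),
                 ht_threshold = ht_threshold,
                 step = as.integer(step),
                 enabled = isTRUE(enabled)),
            class = "denoise_params")
}

#' Full pipeline configuration
#'
#' Collects every free parameter of the enhancement pipeline in one
#' object. All stages read their knobs from here, so a single config
#' captures a reproducible run.
#'
#' @param mu exponent of the fusion weight `W = T^mu`; `mu = 0` keeps the
#'   original image everywhere, larger values trust the synthesized
#'   exposure more in dark regions.
#' @param gamma_adjust gamma of the grayscale-range adjustment.
#' @param q_low,q_high saturation quantiles of the contrast stretch.
#' @param n_bins histogram bins used by the image entropy.
#' @param k_lo,k_hi exposure-ratio search interval; the method only
#'   brightens, so the default interval is `[1, 10]`.
#' @param loe_size evaluation side length for the lightness order error.
#' @param camera a [camera_model()].
#' @param solver a [solver_params()].
#' @param denoise a [denoise_params()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mu = 1, gamma_adjust = 0.9,
                            q_low = 0.01, q_high = 0.99, n_bins = 256L,
                            k_lo = 1, k_hi = 10, loe_size = 100L,
                            camera = camera_model(),
                            solver = solver_params(),
                            denoise = denoise_params()) {
  stopifnot(mu >= 0, gamma_adjust > 0,
            q_low >= 0, q_high <= 1, q_low < q_high,
            n_bins >= 2, k_lo > 0, k_lo < k_hi, loe_size >= 2)
  stopifnot(inherits(camera, "camera_model"),
            inherits(solver, "solver_params"),
            inherits(denoise, "denoise_params"))
  structure(list(mu = mu, gamma_adjust = gamma_adjust,
                 q_low = q_low, q_high = q_high, n_bins = as.integer(n_bins),
                 k_lo = k_lo, k_hi = k_hi, loe_size = as.integer(loe_size),
                 camera = camera, solver = solver, denoise = denoise),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults. Nested
#' sections `camera`, `solver` and `denoise` override fields of the
#' corresponding parameter objects.
#'
#' @param path path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  top <- c("mu", "gamma_adjust", "q_low", "q_high", "n_bins",
           "k_lo", "k_hi", "loe_size", "camera", "solver", "denoise")
  unknown <- setdiff(names(raw), top)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  build <- function(ctor, section) {
    args <- raw[[section]]
    if (is.null(args)) return(ctor())
    do.call(ctor, args)
  }
  args <- raw[setdiff(names(raw), c("camera", "solver", "denoise"))]
  args$camera <- build(camera_model, "camera")
  args$solver <- build(solver_params, "solver")
  args$denoise <- build(denoise_params, "denoise")
  do.call(pipeline_config, args)
}
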