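clamp01 <- function(x) pmin(pmax(x, 0), 1)

assert_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 numeric array", arg), call. = FALSE)
  d <- dim(img)
  if (d[1] < 2L || d[2] < 2L)
    stop(sprintf("`%s` must be at least 2 x 2 pixels", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  if (min(img) < 0 || max(img) > 1)
    stop(sprintf("`%s` values must lie in [0, 1]", arg), call. = FALSE)
  invisible(img)
}

assert_plane <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(x)
}

assert_same_shape <- function(a, b, what = "inputs") {
  da <- dim(a); db <- dim(b)
  if (length(da) != length(db) || !all(da == db))
    stop(sprintf("%s must have identical dimensions (%s vs %s)",
                 what, paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

# Run `code` with a private RNG stream; the caller's .Random.seed is
# restored afterwards so library randomness never leaks into user state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# 2-D correlation of `x` with an odd-sized kernel, output same size as x.
# pad = "zero" treats pixels outside the image as absent (window clipped
# to the image domain); pad = "reflect" mirrors the image at its borders.
conv2_same <- function(x, kern, pad = c("zero", "reflect")) {
  pad <- match.arg(pad)
  kh <- nrow(kern); kw <- ncol(kern)
  stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
  rh <- (kh - 1L) %/% 2L; rw <- (kw - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  if (pad == "zero") {
    xp <- matrix(0, H + 2L * rh, W + 2L * rw)
    xp[(rh + 1L):(rh + H), (rw + 1L):(rw + W)] <- x
  } else {
    xp <- x[reflect_idx(H, rh), reflect_idx(W, rw), drop = FALSE]
  }
  out <- matrix(0, H, W)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      kij <- kern[i, j]
      if (kij != 0)
        out <- out + kij * xp[i:(i + H - 1L), j:(j + W - 1L)]
    }
  }
  out
}

# Indices implementing whole-sample symmetric reflection with a margin r
# on each side of 1..n (1,2,..,n with 0 -> 1, -1 -> 2, n+1 -> n, ...).
reflect_idx <- function(n, r) {
  idx <- (1L - r):(n + r)
  idx <- ifelse(idx < 1L, 1L - idx, idx)
  idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
  pmin(pmax(idx, 1L), n)
}

# Isotropic Gaussian kernel on a (2r+1)^2 grid, normalized to sum to 1.
gaussian_kernel <- function(radius, sigma) {
  stopifnot(radius >= 0, sigma > 0)
  d <- (-radius):radius
  g <- exp(-outer(d^2, d^2, `+`) / (2 * sigma^2))
  g / sum(g)
}

#' Peak signal-to-noise ratio of an image or plane against a reference
#'
#' @param x,ref numeric arrays of identical shape with values in `[0, 1]`.
#' @return PSNR in decibels (`Inf` when the inputs are identical).
#' @export
psnr <- function(x, ref) {
  assert_same_shape(x, ref, "psnr inputs")
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}
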