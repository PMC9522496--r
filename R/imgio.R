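#' Read a raster image into the internal representation
#'
#' Loads an 8- or 16-bit PNG, JPEG or TIFF file and returns a plain
#' numeric `H x W x 3` array with values in `[0, 1]` (channel order
#' R, G, B). Integer samples are divided by the maximum representable
#' value of the file's bit depth. Grayscale images are replicated to
#' three channels; an alpha channel is dropped.
#'
#' @param path path to a PNG, JPEG or TIFF file.
#' @return An `H x W x 3` numeric array in `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop("failed to read image '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  dat <- EBImage::imageData(img)
  d <- dim(dat)
  if (length(d) == 2L) {
    dat <- array(rep(dat, 3L), c(d, 3L))
  } else if (length(d) == 3L) {
    if (d[3] == 2L) {            # gray + alpha
      dat <- array(rep(dat[, , 1L], 3L), c(d[1:2], 3L))
    } else if (d[3] >= 4L) {     # drop alpha / extra samples
      dat <- dat[, , 1:3, drop = FALSE]
    } else if (d[3] == 1L) {
      dat <- array(rep(dat[, , 1L], 3L), c(d[1:2], 3L))
    }
  } else {
    stop("unsupported image layout in '", path, "'", call. = FALSE)
  }
  # EBImage stores (x, y, channel); internal layout is (row, col, channel).
  out <- aperm(dat, c(2L, 1L, 3L))
  if (any(dim(out)[1:2] < 2L))
    stop("image '", path, "' is smaller than 2 x 2 pixels", call. = FALSE)
  if (!all(is.finite(out)))
    stop("image '", path, "' contains non-finite samples", call. = FALSE)
  clamp01(out)
}

#' Write an image to disk
#'
#' Values are clamped to `[0, 1]`, quantized to 8 bits and written in the
#' format implied by the file extension (png, jpg/jpeg, tif/tiff).
#'
#' @param img an `H x W x 3` array in `[0, 1]`.
#' @param path destination path; the extension selects the codec.
#' @return Invisibly, `path`.
#' @export
save_image <- function(img, path) {
  assert_rgb(clamp01(img))
  q <- round(clamp01(img) * 255) / 255
  ebi <- EBImage::Image(aperm(q, c(2L, 1L, 3L)), colormode = "Color")
  ok <- tryCatch({ EBImage::writeImage(ebi, path); TRUE },
                 error = function(e)
                   stop("failed to write image '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  invisible(path)
}

# Full-range BT.601 RGB -> YUV matrix; rows sum to (1, 0, 0) so gray maps
# to (g, 0, 0) exactly, and chroma is centered at 0 with range [-0.5, 0.5].
.yuv_mat <- rbind(c( 0.299,     0.587,     0.114),
                  c(-0.168736, -0.331264,  0.5),
                  c( 0.5,      -0.418688, -0.081312))
.yuv_inv <- solve(.yuv_mat)

#' Convert an RGB image to YUV planes
#'
#' Full-range BT.601 transform. Luma `Y` lies in `[0, 1]`; the chroma
#' planes are centered at zero with range `[-0.5, 0.5]`.
#'
#' @param img an `H x W x 3` RGB array in `[0, 1]`.
#' @return A list with matrices `y`, `u`, `v`.
#' @export
rgb_to_yuv <- function(img) {
  assert_rgb(img)
  m <- .yuv_mat
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  list(y = m[1, 1] * r + m[1, 2] * g + m[1, 3] * b,
       u = m[2, 1] * r + m[2, 2] * g + m[2, 3] * b,
       v = m[3, 1] * r + m[3, 2] * g + m[3, 3] * b)
}

#' Convert YUV planes back to an RGB image
#'
#' Exact algebraic inverse of [rgb_to_yuv()] up to floating-point
#' round-off; the result is clamped to `[0, 1]`.
#'
#' @param y,u,v numeric matrices of identical shape.
#' @return An `H x W x 3` RGB array in `[0, 1]`.
#' @export
yuv_to_rgb <- function(y, u, v) {
  assert_plane(y, "y"); assert_plane(u, "u"); assert_plane(v, "v")
  assert_same_shape(y, u, "YUV planes")
  assert_same_shape(y, v, "YUV planes")
  m <- .yuv_inv
  out <- array(0, c(dim(y), 3L))
  out[, , 1L] <- m[1, 1] * y + m[1, 2] * u + m[1, 3] * v
  out[, , 2L] <- m[2, 1] * y + m[2, 2] * u + m[2, 3] * v
  out[, , 3L] <- m[3, 1] * y + m[3, 2] * u + m[3, 3] * v
  clamp01(out)
}
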