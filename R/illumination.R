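#' Initial illumination map
#'
#' Max-RGB style initial estimate: the per-pixel maximum over the R, G, B
#' channels (the illumination at a pixel is at least the largest channel
#' response there), floored at a small constant so downstream divisions
#' and blends are well defined.
#'
#' @param img an `H x W x 3` RGB array in `[0, 1]`.
#' @return An `H x W` matrix with values in `[1e-3, 1]`.
#' @export
initial_illumination <- function(img) {
  assert_rgb(img)
  pmax(pmax(img[, , 1L], img[, , 2L], img[, , 3L]), EPS_T)
}

#' Forward-difference gradients of a plane
#'
#' Horizontal gradient `t[i, j+1] - t[i, j]` and vertical gradient
#' `t[i+1, j] - t[i, j]`, with zeros in the last column/row (Neumann
#' boundary). The same stencil is used by the sparse difference operators
#' of the illumination solver, so both agree exactly.
#'
#' @param t numeric matrix.
#' @return A list with matrices `h` and `v`.
#' @export
gradients <- function(t) {
  assert_plane(t, "t")
  H <- nrow(t); W <- ncol(t)
  dh <- matrix(0, H, W)
  dv <- matrix(0, H, W)
  if (W >= 2L) dh[, 1:(W - 1L)] <- t[, 2:W] - t[, 1:(W - 1L)]
  if (H >= 2L) dv[1:(H - 1L), ] <- t[2:H, ] - t[1:(H - 1L), ]
  list(h = dh, v = dv)
}

#' Structure-aware gradient weights
#'
#' For each direction d in \{h, v\} and pixel x, pools the initial map's
#' gradients over a Gaussian-weighted window centered at x:
#' `W_d(x) = (sum_y G(x, y)) / (|sum_y G(x, y) * grad_d(y)| + epsilon)`,
#' with the truncated Gaussian kernel normalized to unit sum and windows
#' clipped at the image border. Weights are large in flat regions (the
#' pooled gradient is small) and small across salient edges, so the
#' subsequent smoothing flattens texture while preserving structure.
#'
#' @param t_hat initial illumination map (matrix).
#' @param p a [solver_params()].
#' @return An object of class `gradient_weights`: list with strictly
#'   positive matrices `w_h` and `w_v`.
#' @export
gradient_weights <- function(t_hat, p = solver_params()) {
  assert_plane(t_hat, "t_hat")
  stopifnot(inherits(p, "solver_params"))
  g <- gradients(t_hat)
  kern_num <- gaussian_kernel(p$window_radius, p$sigma_num)
  kern_den <- gaussian_kernel(p$window_radius, p$sigma)
  num <- conv2_same(matrix(1, nrow(t_hat), ncol(t_hat)), kern_num,
                    pad = "zero")
  w_h <- num / (abs(conv2_same(g$h, kern_den, pad = "zero")) + p$epsilon)
  w_v <- num / (abs(conv2_same(g$v, kern_den, pad = "zero")) + p$epsilon)
  structure(list(w_h = w_h, w_v = w_v), class = "gradient_weights")
}

# Sparse forward-difference operators on the column-major vectorization
# of an H x W plane, matching gradients() including the zero last row/col.
diff_operators <- function(H, W) {
  n <- H * W
  idx <- function(i, j) i + (j - 1L) * H
  # horizontal: rows for j < W
  ii <- as.vector(outer(seq_len(H), seq_len(W - 1L), idx))
  Dh <- Matrix::sparseMatrix(i = c(ii, ii),
                             j = c(ii, ii + H),
                             x = c(rep(-1, length(ii)), rep(1, length(ii))),
                             dims = c(n, n))
  # vertical: rows for i < H
  jj <- as.vector(outer(seq_len(H - 1L), seq_len(W), idx))
  Dv <- Matrix::sparseMatrix(i = c(jj, jj),
                             j = c(jj, jj + 1L),
                             x = c(rep(-1, length(jj)), rep(1, length(jj))),
                             dims = c(n, n))
  list(h = Dh, v = Dv)
}

#' Refine the illumination map
#'
#' Solves the relaxed structure-aware smoothing problem: minimize
#' `||T - T_hat||_F^2 + alpha * sum_d w~_d (grad_d T)^2` where
#' `w~_d(x) = W_d(x) / (|grad_d T_hat(x)| + epsilon)` re-weights the
#' quadratic penalty so it approximates the sparse (1-norm) gradient
#' penalty at the initial map. The stationarity condition is the sparse
#' symmetric positive-definite linear system
#' `(I + alpha * sum_d D_d' Diag(w~_d) D_d) t = t_hat`,
#' solved directly by sparse Cholesky factorization (deterministic, no
#' random state). The result is clamped to `[1e-3, 1]`.
#'
#' @param t_hat initial illumination map (matrix).
#' @param w a [gradient_weights()] object of matching shape.
#' @param p a [solver_params()].
#' @return Refined illumination map, same shape as `t_hat`.
#' @export
refine_illumination <- function(t_hat, w = NULL, p = solver_params()) {
  assert_plane(t_hat, "t_hat")
  stopifnot(inherits(p, "solver_params"))
  if (is.null(w)) w <- gradient_weights(t_hat, p)
  stopifnot(inherits(w, "gradient_weights"))
  assert_same_shape(t_hat, w$w_h, "map and weights")
  H <- nrow(t_hat); W <- ncol(t_hat)
  if (p$alpha == 0)
    return(pmin(pmax(t_hat, EPS_T), 1))
  g <- gradients(t_hat)
  wt_h <- as.vector(w$w_h / (abs(g$h) + p$epsilon))
  wt_v <- as.vector(w$w_v / (abs(g$v) + p$epsilon))
  D <- diff_operators(H, W)
  A <- Matrix::Diagonal(H * W) +
    p$alpha * (Matrix::t(D$h) %*% Matrix::Diagonal(x = wt_h) %*% D$h +
               Matrix::t(D$v) %*% Matrix::Diagonal(x = wt_v) %*% D$v)
  A <- Matrix::forceSymmetric(A)
  t_vec <- tryCatch(
    as.vector(Matrix::solve(A, as.vector(t_hat))),
    error = function(e)
      stop("illumination solve failed (", conditionMessage(e),
           "); alpha = ", p$alpha, ", size = ", H, "x", W, call. = FALSE))
  if (!all(is.finite(t_vec)))
    stop("illumination solve produced non-finite values", call. = FALSE)
  pmin(pmax(matrix(t_vec, H, W), EPS_T), 1)
}
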