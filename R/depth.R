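#' Per-layer singular-value depth weights
#'
#' Measurement sensitivity decays roughly exponentially with depth, so an
#' unweighted reconstruction is biased toward the surface.  Splitting the
#' sensing matrix into its n_z contiguous depth-layer blocks A_1 ... A_{n_z},
#' the weight of layer i is w_i = (theta(A_{n_z}) / theta(A_i))^p with
#' theta(.) the maximum singular value: the deepest layer keeps weight 1 and
#' shallower (more sensitive) layers are suppressed, equalizing sensitivity
#' across depth.  `p = 1` is the standard compensation; `p = 0` turns it off.
#'
#' @param A a [build_sensing_matrix()] object (the grid supplies the layer
#'   structure), or a bare matrix with `grid` given.
#' @param p compensation power (>= 0).
#' @param grid voxel grid when `A` is a bare matrix.
#' @return object of class `layer_weights`: `theta` (per-layer maximum
#'   singular values), `w` (per-layer weights), `p`, `n_layers`, and
#'   `w_col` (weight expanded to every column).
#' @export
layer_weights <- function(A, p = 1, grid = NULL) {
  W <- sensing_values(A)
  if (is.null(grid)) {
    if (!inherits(A, "sensing_matrix"))
      stop("supply 'grid' when A is a bare matrix", call. = FALSE)
    grid <- A$grid
  }
  nz <- grid$n_layers
  theta <- vapply(seq_len(nz), function(i) {
    B <- W[, layer_columns(grid, i), drop = FALSE]
    if (all(B == 0)) stop("layer ", i, " block is identically zero", call. = FALSE)
    svd(B, nu = 0L, nv = 0L)$d[1]
  }, numeric(1))
  w <- (theta[nz] / theta)^p
  structure(
    list(theta = theta, w = w, p = p, n_layers = nz,
         w_col = w[layer_of(grid)]),
    class = "layer_weights")
}

#' @export
print.layer_weights <- function(x, ...) {
  cat(sprintf("Layer weights (p = %g): %d layers, w in [%.3g, %.3g]\n",
              x$p, x$n_layers, min(x$w), max(x$w)))
  invisible(x)
}

#' Apply / undo depth compensation
#'
#' `apply_depth_compensation` rescales every column of the sensing matrix by
#' its layer weight, giving the equalized matrix A~ whose reconstruction
#' x-hat is depth-localized.  `undo_depth_compensation` converts x-hat back
#' to physical absorption units, x~_k = w_layer(k) * x-hat_k, which is the
#' inverse diagonal-weight correction that restores quantification: the
#' identity A~ x-hat = A x~ holds exactly.
#'
#' @param A sensing matrix object or bare matrix.
#' @param lw a [layer_weights()] result.
#' @return `apply_depth_compensation`: object of the same kind as `A` with
#'   rescaled columns; `undo_depth_compensation`: corrected voxel vector.
#' @export
apply_depth_compensation <- function(A, lw) {
  stopifnot(inherits(lw, "layer_weights"))
  if (inherits(A, "sensing_matrix")) {
    if (ncol(A$W) != length(lw$w_col))
      stop("weights and matrix are not conformable", call. = FALSE)
    A$W <- sweep(A$W, 2L, lw$w_col, "*")
    A$depth_weights <- lw
    A
  } else {
    if (ncol(A) != length(lw$w_col))
      stop("weights and matrix are not conformable", call. = FALSE)
    sweep(A, 2L, lw$w_col, "*")
  }
}

#' @rdname apply_depth_compensation
#' @param x_hat solution of the depth-compensated system.
#' @export
undo_depth_compensation <- function(x_hat, lw) {
  stopifnot(inherits(lw, "layer_weights"))
  if (length(x_hat) != length(lw$w_col))
    stop("weights and image are not conformable", call. = FALSE)
  out <- as.numeric(x_hat) * lw$w_col
  attributes(out) <- attributes(x_hat)
  out
}
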