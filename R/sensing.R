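#' Build the linearized CW sensing matrix
#'
#' Assembles the dense Jacobian A of the Rytov-linearized continuous-wave
#' forward model y = A x: row (d, s) and column k carry the sensitivity of the
#' log-fluence measured at detector d from source s to an absorption increase
#' in voxel k,
#'   A[(d,s), k] = (h^3 / D) * G(r_s, r_k) * G(r_k, r_d) / G(r_s, r_d),
#' with G the semi-infinite-medium Green's function ([greens_fn()]), h the
#' voxel edge, and both optode roles placed at the effective transport depth
#' z0 = 1/(mua + musp) below their surface points (the source as a buried
#' isotropic point, the detector as the adjoint sampling location; exchanging
#' the roles of a bifurcated pair then gives an identical measurement row, as
#' optical reciprocity demands).  All entries are nonnegative
#' under this sign convention, so a measurement vector y is the positive Rytov
#' perturbation -log(Phi/Phi0) and x >= 0 corresponds to an absorption
#' increase.  Optode-to-voxel distances below h/2 are clamped to h/2 to
#' regularize the near-field singularity.
#'
#' @param layout an [make_layout()] object.
#' @param grid an [make_grid()] object.
#' @param bg an [optical_background()].
#' @return Object of class `sensing_matrix`: `W` (mq x n dense matrix),
#'   `row_map` (data frame detector/source per row), `layout`, `grid`, `bg`.
#' @export
build_sensing_matrix <- function(layout, grid, bg = optical_background()) {
  stopifnot(inherits(layout, "optode_layout"), inherits(grid, "voxel_grid"),
            inherits(bg, "optical_background"))
  h <- grid$voxel_size
  vc <- voxel_centers(grid)
  # both optode roles are modeled one transport depth z0 below their surface
  # point: the source as the standard buried isotropic point, the detector as
  # the adjoint sampling location -- which makes bifurcated source/detector
  # exchange an exact row symmetry (optical reciprocity)
  src <- layout$sources
  src[, 3] <- src[, 3] + bg$z0
  det <- layout$detectors
  det[, 3] <- det[, 3] + bg$z0
  dmin <- h / 2

  Gs <- greens_pairs(src, vc, bg, dmin = dmin)          # m x n
  Gd <- greens_pairs(det, vc, bg, dmin = dmin)          # q x n
  Gsd <- greens_pairs(src, det, bg, dmin = dmin)        # m x q

  p <- layout$pairs
  W <- (h^3 / bg$D) * Gs[p[, 2], , drop = FALSE] *
    Gd[p[, 1], , drop = FALSE] / Gsd[cbind(p[, 2], p[, 1])]
  W[W < 0] <- 0   # guard: clamping can leave tiny negatives near optodes

  structure(
    list(W = W,
         row_map = data.frame(detector = p[, 1], source = p[, 2]),
         layout = layout, grid = grid, bg = bg),
    class = "sensing_matrix")
}

#' @export
print.sensing_matrix <- function(x, ...) {
  cat(sprintf("Sensing matrix: %d measurements x %d voxels (%s, %d layers)\n",
              nrow(x$W), ncol(x$W), x$layout$variant, x$grid$n_layers))
  invisible(x)
}

#' @export
dim.sensing_matrix <- function(x) dim(x$W)

#' @export
as.matrix.sensing_matrix <- function(x, ...) x$W

# accept either a sensing_matrix or a bare matrix
sensing_values <- function(A) if (inherits(A, "sensing_matrix")) A$W else A
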