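#' Full-width-half-maximum mask of a reconstruction
#'
#' Voxels at or above half of the global maximum.  The FWHM convention turns
#' a smooth reconstruction into an object boundary comparable with the known
#' truth.
#'
#' @param recon voxel vector (any positive scale).
#' @return logical vector; all-`FALSE` (with a warning) when the image has no
#'   positive values.
#' @export
fwhm_mask <- function(recon) {
  m <- max(recon)
  if (m <= 0) {
    warning("reconstruction has no positive values; empty FWHM mask")
    return(rep(FALSE, length(recon)))
  }
  recon >= 0.5 * m
}

#' Connected components of a voxel mask (26-connectivity)
#'
#' Labels the mask's connected components treating voxels that touch by face,
#' edge or corner as neighbours — the convention used to count how many
#' distinct objects a reconstruction resolves.
#'
#' @param mask logical voxel vector.
#' @param grid the [make_grid()] grid the mask lives on.
#' @return list: `n` (component count), `labels` (integer vector, 0 outside
#'   the mask).
#' @export
connected_components <- function(mask, grid) {
  labels <- integer(grid$n)
  idx <- which(mask)
  if (length(idx) == 0L) return(list(n = 0L, labels = labels))
  sub <- grid_subscripts(grid, idx)
  id_of <- integer(grid$n)
  id_of[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
               (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]  # half-space
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(sub, 2L, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid$shape[1] &
          nb[, 2] >= 1 & nb[, 2] <= grid$shape[2] &
          nb[, 3] >= 1 & nb[, 3] <= grid$shape[3]
    if (!any(ok)) next
    nf <- grid_index(grid, nb[ok, 1], nb[ok, 2], nb[ok, 3])
    hit <- id_of[nf] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], id_of[nf[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(n = comp$no, labels = labels)
}

#' Distinct objects on a depth slice
#'
#' Counts connected components of the FWHM mask restricted to one x-y plane
#' (default: the slice through the truth's or reconstruction's intensity
#' centroid).  Cross-sectional views are how multi-object reconstructions are
#' read in practice: with limited-view probes the 3-D mask can fuse distinct
#' objects through a poorly resolved deep bridge that the in-plane view
#' separates cleanly.
#'
#' @param recon reconstructed voxel vector.
#' @param grid the [make_grid()] grid.
#' @param slice_depth slice depth (cm); default uses the reconstruction's
#'   intensity centroid depth.
#' @return number of in-plane connected components (8-connectivity).
#' @export
slice_components <- function(recon, grid, slice_depth = NULL) {
  if (is.null(slice_depth)) slice_depth <- centroid_depth(recon, grid)
  iz <- max(1L, min(grid$n_layers,
                    floor((slice_depth - grid$origin[3]) / grid$voxel_size) + 1L))
  m <- fwhm_mask(recon)
  sel <- rep(FALSE, grid$n)
  sel[layer_columns(grid, iz)] <- TRUE
  connected_components(m & sel, grid)$n
}

truth_values <- function(truth, grid) {
  if (inherits(truth, "phantom_scene")) voxelize_scene(truth, grid)
  else as.numeric(truth)
}

#' Area ratio (AR) on a depth slice
#'
#' Ratio of the FWHM-mask cross-section area of the reconstruction to the
#' true object's cross-section, on the x-y plane at `slice_depth` (default:
#' the depth layer of the truth's centroid).
#'
#' @param recon reconstructed voxel vector.
#' @param truth true voxel vector or a [phantom_scene()].
#' @param grid the shared [make_grid()] grid.
#' @param slice_depth slice depth in cm (snapped to the containing layer).
#' @return AR (dimensionless).
#' @export
area_ratio <- function(recon, truth, grid, slice_depth = NULL) {
  xt <- truth_values(truth, grid)
  if (all(xt == 0)) stop("truth has no object", call. = FALSE)
  if (is.null(slice_depth)) {
    vc <- voxel_centers(grid)
    slice_depth <- sum(vc[, 3] * xt) / sum(xt)
  }
  iz <- max(1L, min(grid$n_layers,
                    floor((slice_depth - grid$origin[3]) / grid$voxel_size) + 1L))
  cols <- layer_columns(grid, iz)
  a_t <- sum(xt[cols] > 0)
  if (a_t == 0) stop("true object has zero area on the requested slice",
                     call. = FALSE)
  sum(fwhm_mask(recon)[cols]) / a_t
}

#' Volume ratio (VR)
#'
#' FWHM volume of the reconstruction over the true object volume (both in
#' voxels of the same grid, so the ratio is in physical cm^3 terms too).
#'
#' @inheritParams area_ratio
#' @return VR (dimensionless).
#' @export
volume_ratio <- function(recon, truth, grid) {
  xt <- truth_values(truth, grid)
  v_t <- sum(xt > 0)
  if (v_t == 0) stop("truth has no object", call. = FALSE)
  sum(fwhm_mask(recon)) / v_t
}

#' Contrast ratio (CR)
#'
#' Mean reconstructed value inside the true object boundary over the mean in
#' the background (everything outside).  A perfect reconstruction has an
#' exactly zero background, for which `Inf` is returned.
#'
#' @inheritParams area_ratio
#' @return CR (dimensionless, possibly `Inf`).
#' @export
contrast_ratio <- function(recon, truth, grid) {
  xt <- truth_values(truth, grid)
  roi <- xt > 0
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  if (all(roi)) stop("ROI covers the whole grid: no background", call. = FALSE)
  bg <- mean(recon[!roi])
  if (bg == 0) return(Inf)
  mean(recon[roi]) / bg
}

#' Intensity-weighted centroid depth of the FWHM mask
#'
#' @param recon reconstructed voxel vector with a positive maximum.
#' @param grid the [make_grid()] grid.
#' @return depth (cm) of the reconstructed object center.
#' @export
centroid_depth <- function(recon, grid) {
  m <- fwhm_mask(recon)
  if (!any(m)) stop("empty FWHM mask", call. = FALSE)
  z <- voxel_centers(grid)[, 3]
  sum(z[m] * recon[m]) / sum(recon[m])
}

#' Quantification recovery (%)
#'
#' Mean reconstructed perturbation inside the true object over the true
#' contrast, in percent: 100% means the absorption increase is fully
#' recovered in amplitude.
#'
#' @inheritParams area_ratio
#' @return percentage.
#' @export
recovery_pct <- function(recon, truth, grid) {
  xt <- truth_values(truth, grid)
  roi <- xt > 0
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  100 * mean(recon[roi]) / mean(xt[roi])
}

#' Full image-quality report
#'
#' Computes AR, VR, CR, centroid depth, quantification recovery and the
#' number of connected FWHM components of a reconstruction against the known
#' truth.
#'
#' @inheritParams area_ratio
#' @return object of class `quality_report`.
#' @export
quality_report <- function(recon, truth, grid) {
  xt <- truth_values(truth, grid)
  mask <- fwhm_mask(recon)
  structure(
    list(AR = area_ratio(recon, xt, grid),
         VR = volume_ratio(recon, xt, grid),
         CR = contrast_ratio(recon, xt, grid),
         centroid_depth = if (any(mask)) centroid_depth(recon, grid) else NA_real_,
         recovery_pct = recovery_pct(recon, xt, grid),
         n_components = connected_components(mask, grid)$n),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "AR = %.3f  VR = %.3f  CR = %s  centroid depth = %.2f cm  recovery = %.1f%%  components = %d\n",
    x$AR, x$VR, if (is.infinite(x$CR)) "Inf" else sprintf("%.2f", x$CR),
    x$centroid_depth, x$recovery_pct, x$n_components))
  invisible(x)
}
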