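#' Phantom scenes: absorbing inclusions in a homogeneous medium
#'
#' A scene is a list of simple absorbing inclusions — z-axis cylinders or
#' spheres — each with a positive absorption contrast delta_mua (cm^-1) over
#' the background.  Scenes mimic the solid objects suspended in intralipid
#' phantom experiments.
#'
#' @param ... inclusions created with [inclusion()].
#' @return object of class `phantom_scene` (a list of inclusions).
#' @export
phantom_scene <- function(...) {
  incl <- list(...)
  if (length(incl) == 1L && is.list(incl[[1]]) && is.null(incl[[1]]$shape))
    incl <- incl[[1]]
  stopifnot(all(vapply(incl, inherits, TRUE, "dot_inclusion")))
  structure(incl, class = "phantom_scene")
}

#' @rdname phantom_scene
#' @param shape `"cylinder_z"` (axis along depth) or `"sphere"`.
#' @param center inclusion center (cm).
#' @param diameter diameter (cm).
#' @param length cylinder length along z (cm); ignored for spheres.
#' @param delta_mua absorption contrast (cm^-1), must be positive.
#' @export
inclusion <- function(shape = c("cylinder_z", "sphere"), center, diameter,
                      length = NULL, delta_mua = 0.2) {
  shape <- match.arg(shape)
  if (delta_mua <= 0)
    stop("'delta_mua' must be positive (absorption increase)", call. = FALSE)
  if (shape == "cylinder_z" && is.null(length))
    stop("cylinders need a 'length'", call. = FALSE)
  structure(list(shape = shape, center = as.numeric(center),
                 diameter = diameter, length = length,
                 delta_mua = delta_mua),
            class = "dot_inclusion")
}

#' Built-in phantom scenes from the reference experiments
#'
#' Named scenes matching the package's benchmark phantom geometries.  Centers
#' assume the [default_grid()] of the matching layout (`fig1_disk` under the
#' 5 x 5 arrays; the `fig7*` scenes under the transrectal probe).
#'
#' \describe{
#'   \item{fig1_disk}{cylindrical disk, 1.1 cm diameter, 0.4 cm thick, center
#'     depth 1.5 cm, centered in x-y.}
#'   \item{fig7a_B}{sphere, 0.9 cm diameter, depth 1.8 cm.}
#'   \item{fig7b_Cs}{small cylinder, 0.2 cm diameter, 0.3 cm long, depth 1.5 cm.}
#'   \item{fig7c_dualC1}{two identical cylinders (0.85 cm diameter, 0.62 cm
#'     long) at depth 1.5 cm, centers 1.5 cm apart.}
#'   \item{fig7d_C1C2}{cylinders of 0.85/0.62 and 0.65/0.45 cm
#'     (diameter/length) at depth 1.5 cm, centers 1 cm apart.}
#' }
#'
#' @param name scene name.
#' @param delta_mua contrast (cm^-1) given to every inclusion.
#' @return a [phantom_scene()].
#' @export
scene_library <- function(name = c("fig1_disk", "fig7a_B", "fig7b_Cs",
                                   "fig7c_dualC1", "fig7d_C1C2"),
                          delta_mua = 0.2) {
  name <- match.arg(name)
  switch(name,
    fig1_disk = phantom_scene(
      inclusion("cylinder_z", c(2, 2, 1.5), 1.1, 0.4, delta_mua)),
    fig7a_B = phantom_scene(
      inclusion("sphere", c(3, 2, 1.8), 0.9, delta_mua = delta_mua)),
    fig7b_Cs = phantom_scene(
      inclusion("cylinder_z", c(3, 2, 1.5), 0.2, 0.3, delta_mua)),
    fig7c_dualC1 = phantom_scene(
      inclusion("cylinder_z", c(2.25, 2, 1.5), 0.85, 0.62, delta_mua),
      inclusion("cylinder_z", c(3.75, 2, 1.5), 0.85, 0.62, delta_mua)),
    fig7d_C1C2 = phantom_scene(
      inclusion("cylinder_z", c(2.5, 2, 1.5), 0.85, 0.62, delta_mua),
      inclusion("cylinder_z", c(3.5, 2, 1.5), 0.65, 0.45, delta_mua)))
}

#' Rasterize a phantom scene onto a voxel grid
#'
#' A voxel takes the delta_mua of each inclusion whose analytic shape contains
#' the voxel center (no partial-volume weighting); overlapping inclusions sum.
#' An inclusion smaller than a voxel (no center inside it) is assigned to the
#' single voxel nearest its center so that sub-voxel objects are not lost.
#'
#' @param scene a [phantom_scene()].
#' @param grid a [make_grid()] grid.
#' @return numeric vector of length `grid$n` (flat, layer-major order) of
#'   per-voxel absorption perturbations (cm^-1), with the grid attached as
#'   attribute `grid`.
#' @export
voxelize_scene <- function(scene, grid) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(grid, "voxel_grid"))
  vc <- voxel_centers(grid)
  x <- numeric(grid$n)
  lo <- grid$origin
  hi <- grid$origin + grid$shape * grid$voxel_size
  for (inc in scene) {
    r <- inc$diameter / 2
    ext <- if (inc$shape == "sphere") c(r, r, r) else c(r, r, inc$length / 2)
    if (any(inc$center - ext < lo - 1e-9) || any(inc$center + ext > hi + 1e-9))
      stop("inclusion extends outside the voxel grid", call. = FALSE)
    dx <- vc[, 1] - inc$center[1]
    dy <- vc[, 2] - inc$center[2]
    dz <- vc[, 3] - inc$center[3]
    inside <- if (inc$shape == "sphere") {
      dx^2 + dy^2 + dz^2 <= r^2
    } else {
      (dx^2 + dy^2 <= r^2) & (abs(dz) <= inc$length / 2)
    }
    # sub-voxel object: fall back to the voxel holding the inclusion center
    if (!any(inside)) inside <- which.min(dx^2 + dy^2 + dz^2)
    x[inside] <- x[inside] + inc$delta_mua
  }
  attr(x, "grid") <- grid
  x
}

#' Simulate noisy Rytov measurements of a phantom
#'
#' Computes y = A x + e with e i.i.d. zero-mean Gaussian of standard deviation
#' `noise_level` times the root-mean-square of the clean data A x.
#'
#' @param A a [build_sensing_matrix()] object or bare matrix.
#' @param x_true flat voxel image of absorption perturbations.
#' @param noise_level noise standard deviation as a fraction of RMS(A x).
#' @param seed integer seed making the draw reproducible (`NULL` to use the
#'   current RNG stream).
#' @return object of class `measurement_set`: `y`, `sigma2` (the true noise
#'   variance used), `noise_level`, `seed` and the `A` references.
#' @export
simulate_measurements <- function(A, x_true, noise_level = 0.02, seed = NULL) {
  W <- sensing_values(A)
  if (length(x_true) != ncol(W))
    stop("length(x_true) must equal the number of voxels (columns of A)",
         call. = FALSE)
  if (noise_level < 0)
    stop("'noise_level' must be nonnegative", call. = FALSE)
  y0 <- as.numeric(W %*% x_true)
  sigma <- noise_level * sqrt(mean(y0^2))
  if (!is.null(seed)) set.seed(seed)
  e <- if (sigma > 0) stats::rnorm(length(y0), 0, sigma) else numeric(length(y0))
  structure(
    list(y = y0 + e, sigma2 = sigma^2, noise_level = noise_level, seed = seed,
         layout = if (inherits(A, "sensing_matrix")) A$layout else NULL,
         grid = if (inherits(A, "sensing_matrix")) A$grid else NULL),
    class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("Measurement set: %d channels, noise sd = %.3g (sigma2 = %.3g)\n",
              length(x$y), sqrt(x$sigma2), x$sigma2))
  invisible(x)
}

#' Estimate the measurement-noise variance from repeated acquisitions
#'
#' DOT systems sample fast enough that many repeats of the same measurement
#' are cheap; the per-channel sample variances over those repeats, averaged
#' across channels, estimate the noise variance sigma^2 that the
#' regularization-parameter selector needs.
#'
#' @param replicates a list of equal-length measurement vectors, or a matrix
#'   with one column per replicate.
#' @return pooled noise variance estimate (scalar).
#' @export
estimate_noise_variance <- function(replicates) {
  Y <- if (is.list(replicates)) do.call(cbind, replicates) else as.matrix(replicates)
  if (ncol(Y) < 2L)
    stop("need at least 2 replicate measurement vectors", call. = FALSE)
  mean(apply(Y, 1L, stats::var))
}
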