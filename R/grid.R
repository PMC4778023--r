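#' Define a voxel grid for the imaging volume
#'
#' The imaging volume sits directly below the optode plane (z = 0), with z
#' increasing downwards into the medium.  Voxels are cubes of edge `voxel_size`
#' (cm).  The flat (column) index is layer-major: all voxels of depth layer 1
#' first, then layer 2, and so on, so that the columns of a sensing matrix
#' belonging to one depth layer are contiguous.
#'
#' @param origin numeric length-3, position (cm) of the grid corner with the
#'   smallest coordinates; `origin[3]` is the depth of the top face (usually 0).
#' @param shape integer length-3, number of voxels along x, y, z.
#' @param voxel_size voxel edge length h in cm.
#' @return An object of class `voxel_grid` with elements `origin`, `shape`,
#'   `voxel_size`, `n` (total voxel count) and `n_layers` (= `shape[3]`).
#' @examples
#' g <- make_grid(c(0, 0, 0), c(20, 20, 13), 0.2)
#' g$n  # 5200
#' @export
make_grid <- function(origin = c(0, 0, 0), shape, voxel_size) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three positive voxel counts", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("'voxel_size' must be a positive length (cm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be a finite position (cm)", call. = FALSE)
  structure(
    list(origin = as.numeric(origin), shape = shape,
         voxel_size = as.numeric(voxel_size),
         n = prod(shape), n_layers = shape[3]),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid: %d x %d x %d = %d voxels, h = %g cm\n",
              x$shape[1], x$shape[2], x$shape[3], x$n, x$voxel_size))
  cat(sprintf("  extent: %g x %g x %g cm below z = %g\n",
              x$shape[1] * x$voxel_size, x$shape[2] * x$voxel_size,
              x$shape[3] * x$voxel_size, x$origin[3]))
  invisible(x)
}

# flat index <-> (ix, iy, iz) with layer-major ordering:
# flat = (iz-1)*nx*ny + (iy-1)*nx + ix
grid_index <- function(grid, ix, iy, iz) {
  nx <- grid$shape[1]; ny <- grid$shape[2]
  (iz - 1L) * nx * ny + (iy - 1L) * nx + ix
}

grid_subscripts <- function(grid, flat) {
  nx <- grid$shape[1]; ny <- grid$shape[2]
  f0 <- flat - 1L
  iz <- f0 %/% (nx * ny)
  r <- f0 %% (nx * ny)
  cbind(ix = r %% nx + 1L, iy = r %/% nx + 1L, iz = iz + 1L)
}

#' Voxel-center coordinates
#'
#' @param grid a `voxel_grid`.
#' @return n x 3 matrix of voxel-center positions (cm), rows in flat
#'   (layer-major) order.
#' @export
voxel_centers <- function(grid) {
  h <- grid$voxel_size
  cx <- grid$origin[1] + (seq_len(grid$shape[1]) - 0.5) * h
  cy <- grid$origin[2] + (seq_len(grid$shape[2]) - 0.5) * h
  cz <- grid$origin[3] + (seq_len(grid$shape[3]) - 0.5) * h
  # layer-major: z slowest, then y, then x
  cbind(x = rep(cx, times = grid$shape[2] * grid$shape[3]),
        y = rep(rep(cy, each = grid$shape[1]), times = grid$shape[3]),
        z = rep(cz, each = grid$shape[1] * grid$shape[2]))
}

# columns (flat indices) belonging to depth layer iz
layer_columns <- function(grid, iz) {
  per <- grid$shape[1] * grid$shape[2]
  ((iz - 1L) * per + 1L):(iz * per)
}

# depth layer of each flat index
layer_of <- function(grid, flat = seq_len(grid$n)) {
  per <- grid$shape[1] * grid$shape[2]
  (flat - 1L) %/% per + 1L
}
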