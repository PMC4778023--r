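#' Read and write measurement vectors as CSV
#'
#' Measurements are stored as plain CSV with columns `detector_id`,
#' `source_id`, `value`, one row per (detector, source) channel, values
#' printed with 17 significant digits so a write/read round trip is
#' bit-exact for doubles.
#'
#' @param meas a `measurement_set` (or list with `y` and a layout's pair
#'   rows).
#' @param row_map data frame with `detector` and `source` columns (taken from
#'   the measurement set's layout when omitted).
#' @param path output file.
#' @return `read_measurements_csv` returns a data frame with attributes
#'   `sigma2` (if recorded) attached.
#' @export
write_measurements_csv <- function(meas, path, row_map = NULL) {
  y <- if (inherits(meas, "measurement_set")) meas$y else as.numeric(meas)
  if (is.null(row_map)) {
    if (inherits(meas, "measurement_set") && !is.null(meas$layout)) {
      p <- meas$layout$pairs
      row_map <- data.frame(detector = p[, 1], source = p[, 2])
    } else {
      row_map <- data.frame(detector = seq_along(y), source = seq_along(y))
    }
  }
  df <- data.frame(detector_id = row_map$detector, source_id = row_map$source,
                   value = sprintf("%.17g", y))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("integer", "integer", "numeric"))
  names(df) <- c("detector_id", "source_id", "value")
  df
}

#' Write / read a voxel volume as NIfTI
#'
#' Volumes are stored in NIfTI-1 with the voxel edge recorded in the header
#' (cm written as mm x 10, the native NIfTI unit).  Values are float32;
#' reading back preserves them to single precision.
#'
#' @param x flat voxel vector (layer-major) or 3-D array.
#' @param grid the [make_grid()] grid.
#' @param path output `.nii` / `.nii.gz` file.
#' @export
write_volume_nifti <- function(x, grid, path) {
  arr <- array(as.numeric(x), dim = grid$shape)
  img <- RNifti::asNifti(arr, internal = FALSE)
  RNifti::pixdim(img) <- rep(grid$voxel_size * 10, 3)  # cm -> mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_volume_nifti
#' @return `read_volume_nifti`: list with `values` (flat voxel vector) and
#'   `voxel_size` (cm).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = as.numeric(img),
       voxel_size = RNifti::pixdim(img)[1] / 10,
       shape = dim(img))
}

#' Load an experiment configuration
#'
#' YAML (or JSON) files describe a full synthetic experiment: geometry
#' (layout variant, pitch, voxel size), optics (mua, musp, refractive index,
#' boundary factor), the scene (library name or inline inclusions), the noise
#' block (level, seed) and solver settings (tau, alpha grid, tolerance,
#' depth compensation).  Unknown fields are ignored; missing ones take the
#' package defaults.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return object of class `experiment_config` (a named list with filled
#'   defaults).
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- list(
    geometry = list(variant = "SD-I", pitch_cm = 1, voxel_cm = 0.2),
    optics = list(mua = 0.03, musp = 10, n_index = 1.33, A_bnd = 2),
    scene = list(name = "fig1_disk", delta_mua = 0.2),
    noise = list(level = 0.02, seed = 1),
    solver = list(tau = 0.96, tol = 1e-5, max_iter = 2000, admm_mu = 1,
                  depth_comp = TRUE, p = 1))
  for (blk in names(defaults)) {
    if (is.null(cfg[[blk]])) cfg[[blk]] <- list()
    cfg[[blk]] <- utils::modifyList(defaults[[blk]], cfg[[blk]])
  }
  structure(cfg, class = "experiment_config")
}

#' Assemble the simulation pieces described by a config
#'
#' @param cfg an [read_config()] object (or a path to one).
#' @return list: `layout`, `grid`, `bg`, `scene`, `x_true`, `A`.
#' @export
build_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  layout <- make_layout(cfg$geometry$variant, pitch = cfg$geometry$pitch_cm)
  grid <- default_grid(cfg$geometry$variant, voxel_size = cfg$geometry$voxel_cm)
  bg <- optical_background(mua = cfg$optics$mua, musp = cfg$optics$musp,
                           refractive_index = cfg$optics$n_index,
                           A_bnd = cfg$optics$A_bnd)
  scene <- if (!is.null(cfg$scene$name)) {
    scene_library(cfg$scene$name, delta_mua = cfg$scene$delta_mua)
  } else {
    phantom_scene(lapply(cfg$scene$inclusions, function(i)
      inclusion(i$shape, unlist(i$center), i$diameter, i$length,
                if (is.null(i$delta_mua)) cfg$scene$delta_mua else i$delta_mua)))
  }
  A <- build_sensing_matrix(layout, grid, bg)
  list(layout = layout, grid = grid, bg = bg, scene = scene,
       x_true = voxelize_scene(scene, grid), A = A)
}
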