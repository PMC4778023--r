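#' Source-detector optode layouts on the measurement surface
#'
#' Generates the standard optode geometries used by the package's phantom
#' experiments, all on the z = 0 plane:
#' \describe{
#'   \item{SD-I}{5 x 5 grid of bifurcated optodes (each position both sends
#'     and receives), spacing `pitch`.}
#'   \item{SD-II}{5 x 5 grid with sources and detectors alternating in a
#'     checkerboard (no bifurcation): 13 sources, 12 detectors.}
#'   \item{SD-III}{SD-I with the last row removed, alternating roles: 4 x 5
#'     positions, 10 sources, 10 detectors.}
#'   \item{SD-IV}{SD-I with three rows removed (two rows remain), alternating
#'     roles: 5 sources, 5 detectors.}
#'   \item{transrectal}{two rows 2 cm apart, 9 sources and 9 detectors placed
#'     alternately at 0.5 cm spacing within each row (81 measurement pairs) —
#'     the spatially constrained probe geometry of trans-rectal prostate
#'     imaging.}
#' }
#'
#' Measurement rows are every ordered (detector, source) pair; for bifurcated
#' layouts the co-located pairs (detector at the source position) are excluded
#' by default since their perturbation datum is degenerate.
#'
#' @param variant one of `"SD-I"`, `"SD-II"`, `"SD-III"`, `"SD-IV"`,
#'   `"transrectal"`.
#' @param pitch optode spacing in cm (SD grids; the transrectal in-row spacing
#'   is `pitch/2` of its 1 cm default, i.e. 0.5 cm when `pitch = 1`).
#' @param center x-y position (cm) of the array center on the surface.
#' @param include_colocated keep co-located (d = s) pairs of bifurcated
#'   layouts.
#' @return Object of class `optode_layout`: `sources` and `detectors`
#'   (matrices of positions, z = 0), `pairs` (two-column integer matrix of
#'   (detector, source) indices, one row per measurement), `bifurcated`,
#'   `variant`.
#' @examples
#' make_layout("transrectal")$pairs |> nrow()  # 81
#' @export
make_layout <- function(variant = c("SD-I", "SD-II", "SD-III", "SD-IV",
                                    "transrectal"),
                        pitch = 1, center = c(2, 2),
                        include_colocated = FALSE) {
  variant <- match.arg(variant)
  if (!is.numeric(pitch) || pitch <= 0)
    stop("'pitch' must be a positive spacing (cm)", call. = FALSE)

  sd_rows <- switch(variant, "SD-I" = 5L, "SD-II" = 5L, "SD-III" = 4L,
                    "SD-IV" = 2L, NA_integer_)

  if (variant == "transrectal") {
    if (missing(center)) center <- c(3, 2)
    xs <- (0:8) * (pitch / 2)
    xs <- xs - mean(xs) + center[1]
    ys <- center[2] + c(-1, 1)          # rows 2 cm apart
    pos <- rbind(cbind(xs, ys[1], 0), cbind(xs, ys[2], 0))
    # roles alternate along each row, offset between rows -> 9 + 9
    role_src <- c(rep(c(TRUE, FALSE), length.out = 9),
                  rep(c(FALSE, TRUE), length.out = 9))
    sources <- pos[role_src, , drop = FALSE]
    detectors <- pos[!role_src, , drop = FALSE]
    bifurcated <- FALSE
  } else {
    xs <- (0:4) * pitch
    xs <- xs - mean(xs) + center[1]
    ys_full <- (0:4) * pitch
    ys_full <- ys_full - mean(ys_full) + center[2]
    ys <- ys_full[seq_len(sd_rows)]
    gx <- rep(seq_along(xs), times = length(ys))
    gy <- rep(seq_along(ys), each = length(xs))
    pos <- cbind(xs[gx], ys[gy], 0)
    if (variant == "SD-I") {
      sources <- pos
      detectors <- pos
      bifurcated <- TRUE
    } else {
      role_src <- (gx + gy) %% 2L == 0L   # checkerboard
      sources <- pos[role_src, , drop = FALSE]
      detectors <- pos[!role_src, , drop = FALSE]
      bifurcated <- FALSE
    }
  }

  m <- nrow(sources); q <- nrow(detectors)
  pairs <- cbind(detector = rep(seq_len(q), times = m),
                 source = rep(seq_len(m), each = q))
  if (bifurcated && !include_colocated) {
    colocated <- rowSums((detectors[pairs[, 1], , drop = FALSE] -
                          sources[pairs[, 2], , drop = FALSE])^2) == 0
    pairs <- pairs[!colocated, , drop = FALSE]
  }
  colnames(sources) <- colnames(detectors) <- c("x", "y", "z")
  structure(
    list(variant = variant, sources = sources, detectors = detectors,
         pairs = pairs, bifurcated = bifurcated, pitch = pitch),
    class = "optode_layout")
}

#' @export
print.optode_layout <- function(x, ...) {
  cat(sprintf("Optode layout %s: %d sources, %d detectors, %d measurements%s\n",
              x$variant, nrow(x$sources), nrow(x$detectors), nrow(x$pairs),
              if (x$bifurcated) " (bifurcated)" else ""))
  invisible(x)
}

#' Default imaging volume for a layout variant
#'
#' The 4 x 4 x 2.5 cm volume under the 5 x 5 arrays, or 6 x 4 x 2.5 cm under
#' the transrectal probe, discretized at `voxel_size`.
#'
#' @param variant layout variant name.
#' @param voxel_size voxel edge (cm).
#' @return a [make_grid()] object.
#' @export
default_grid <- function(variant = "SD-I", voxel_size = 0.2) {
  wide <- identical(variant, "transrectal")
  ext <- if (wide) c(6, 4, 2.5) else c(4, 4, 2.5)
  make_grid(c(0, 0, 0), ceiling(ext / voxel_size - 1e-9), voxel_size)
}
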