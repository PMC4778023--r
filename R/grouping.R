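#' Group correlated sensing-matrix columns (Step-1 basis)
#'
#' Because photon sensitivity varies smoothly in space, columns of the sensing
#' matrix belonging to nearby voxels are highly correlated.  A greedy sweep in
#' column order exploits this: the first unassigned column seeds a group, all
#' unassigned columns whose Pearson correlation with the seed is at least
#' `tau` join it, and the sweep repeats on the remainder until every column is
#' assigned.  Each group is represented by its seed (first member).  The
#' result is a low-resolution voxel basis with n# << n groups on which
#' support recovery is cheap.
#'
#' Correlation is invariant to positive per-column rescaling, so the grouping
#' is identical before and after depth compensation.  Zero-variance columns
#' (possible only for degenerate geometries) get singleton groups with a
#' warning.
#'
#' @param A sensing matrix ([build_sensing_matrix()]) or bare matrix.
#' @param tau correlation threshold in (0, 1].
#' @param method `"pearson"` (centered, the default) or `"cosine"`
#'   (uncentered) column similarity.
#' @return object of class `column_grouping`: `group_of` (length-n integer),
#'   `representative` (group -> column index), `members` (list), `n_groups`,
#'   `tau`, `method`.
#' @export
group_columns <- function(A, tau = 0.96, method = c("pearson", "cosine")) {
  W <- sensing_values(A)
  method <- match.arg(method)
  if (!is.numeric(tau) || tau <= 0 || tau > 1)
    stop("'tau' must be in (0, 1]", call. = FALSE)
  n <- ncol(W)

  Z <- if (method == "pearson") sweep(W, 2L, colMeans(W)) else W
  nrm <- sqrt(colSums(Z^2))
  degenerate <- nrm == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance column(s) assigned singleton groups")
    nrm[degenerate] <- 1   # their Z stays 0: correlation 0 with everything
  }
  Z <- sweep(Z, 2L, nrm, "/")

  group_of <- integer(n)
  reps <- integer(0)
  remaining <- rep(TRUE, n)
  eps <- 1e-12
  while (any(remaining)) {
    s <- which.max(remaining)           # first unassigned column
    if (degenerate[s]) {
      members <- s
    } else {
      cr <- as.numeric(crossprod(Z, Z[, s]))
      members <- which(remaining & cr >= tau - eps)
      if (!s %in% members) members <- c(s, members)
    }
    reps <- c(reps, s)
    group_of[members] <- length(reps)
    remaining[members] <- FALSE
  }
  structure(
    list(group_of = group_of, representative = reps,
         members = split(seq_len(n), group_of), n_groups = length(reps),
         tau = tau, method = method),
    class = "column_grouping")
}

#' @export
print.column_grouping <- function(x, ...) {
  n <- length(x$group_of)
  cat(sprintf(
    "Column grouping: %d columns -> %d groups at tau = %g (%.1f%% reduction)\n",
    n, x$n_groups, x$tau, 100 * (1 - x$n_groups / n)))
  invisible(x)
}

#' Reduced sensing system on the grouped basis
#'
#' Keeps one representative column per group: A# has n# columns, column j
#' being the representative (first member) of group j.  The matching
#' low-resolution image is the per-group sum of voxel values,
#' [group_sums()], so that A# x# approximates A x.
#'
#' @param A sensing matrix or bare matrix.
#' @param grouping a [group_columns()] result.
#' @param representative `"first"` (the printed convention) or `"mean"` of
#'   the member columns.
#' @return mq x n# matrix.
#' @export
reduce_system <- function(A, grouping, representative = c("first", "mean")) {
  W <- sensing_values(A)
  representative <- match.arg(representative)
  if (representative == "first") {
    W[, grouping$representative, drop = FALSE]
  } else {
    vapply(grouping$members, function(m) rowMeans(W[, m, drop = FALSE]),
           numeric(nrow(W)))
  }
}

#' @rdname reduce_system
#' @param x full-resolution voxel vector.
#' @return `group_sums`: length-n# vector of per-group sums of `x`.
#' @export
group_sums <- function(x, grouping) {
  as.numeric(rowsum(as.numeric(x), grouping$group_of, reorder = TRUE))
}

#' Relative approximation error of the grouped basis
#'
#' ||A x - A# x#|| / ||A x|| for a reference image x, with x# the per-group
#' sums — the forward-model error committed by collapsing each group onto its
#' representative column.
#'
#' @param A sensing matrix or bare matrix.
#' @param grouping a [group_columns()] result.
#' @param x_ref nonzero reference voxel image.
#' @return relative l2 error (fraction).
#' @export
approximation_error <- function(A, grouping, x_ref) {
  W <- sensing_values(A)
  if (all(x_ref == 0))
    stop("'x_ref' must be nonzero", call. = FALSE)
  y_full <- as.numeric(W %*% as.numeric(x_ref))
  y_red <- as.numeric(reduce_system(W, grouping) %*% group_sums(x_ref, grouping))
  sqrt(sum((y_full - y_red)^2)) / sqrt(sum(y_full^2))
}

#' Choose the effective correlation threshold
#'
#' Sweeps a threshold grid and returns the smallest value whose grouped-basis
#' approximation error ([approximation_error()]) stays below `max_err` —
#' trading maximal dimensionality reduction against a bounded (default 5%)
#' forward-model error.
#'
#' @param A sensing matrix or bare matrix.
#' @param x_ref reference image used to evaluate the error.
#' @param tau_grid ascending candidate thresholds.
#' @param max_err error budget (fraction).
#' @return list: `tau_e`, `errors` (per candidate), `n_groups` (per
#'   candidate), `tau_grid`.
#' @export
select_tau <- function(A, x_ref, tau_grid = seq(0.90, 0.99, by = 0.01),
                       max_err = 0.05) {
  if (is.unsorted(tau_grid, strictly = TRUE))
    stop("'tau_grid' must be strictly ascending", call. = FALSE)
  if (max_err < 0 || max_err >= 1)
    stop("'max_err' must be in [0, 1)", call. = FALSE)
  W <- sensing_values(A)
  errs <- ngrp <- numeric(length(tau_grid))
  tau_e <- NA_real_
  for (i in seq_along(tau_grid)) {
    g <- group_columns(W, tau_grid[i])
    errs[i] <- approximation_error(W, g, x_ref)
    ngrp[i] <- g$n_groups
    if (is.na(tau_e) && errs[i] < max_err) tau_e <- tau_grid[i]
  }
  if (is.na(tau_e)) {
    warning("no threshold met the error budget; returning the largest candidate")
    tau_e <- tau_grid[length(tau_grid)]
  }
  list(tau_e = tau_e, errors = errs, n_groups = ngrp, tau_grid = tau_grid)
}
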