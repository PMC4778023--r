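#' Recover the image support on the grouped basis (Step-1)
#'
#' Solves the nonnegative l1 problem on the reduced system A# and maps the
#' groups carrying appreciable mass back to voxel space: groups with
#' x#_j > eps * max(x#) count as nonzero, and the support I' is the union of
#' their member voxels.  Positivity of the absorption perturbation guarantees
#' that a group containing any true nonzero voxel has a nonzero group sum, so
#' no support is lost to sign cancellation.
#'
#' @param A_red reduced matrix from [reduce_system()].
#' @param y measurement vector.
#' @param lam l1 weight.
#' @param grouping the [group_columns()] result that produced `A_red`.
#' @param cfg a [solver_config()] (nonnegativity is forced on).
#' @param eps relative mass threshold deciding which groups are nonzero.
#' @return list of class `support_mask`: `indices` (sorted voxel support I'),
#'   `n_prime`, `groups` (nonzero group ids), `x_sharp` (grouped solution),
#'   `empty` flag, `fit` (the SALSA result).
#' @export
recover_support <- function(A_red, y, lam, grouping, cfg = solver_config(),
                            eps = 1e-3) {
  cfg$lam <- lam
  cfg$nonneg <- TRUE
  fit <- salsa_l1(A_red, y, cfg)
  xs <- fit$x
  if (max(xs) <= 0) {
    return(structure(list(indices = integer(0), n_prime = 0L,
                          groups = integer(0), x_sharp = xs, empty = TRUE,
                          fit = fit),
                     class = "support_mask"))
  }
  nz <- which(xs > eps * max(xs))
  idx <- sort(unlist(grouping$members[nz], use.names = FALSE))
  structure(list(indices = idx, n_prime = length(idx), groups = nz,
                 x_sharp = xs, empty = FALSE, fit = fit),
            class = "support_mask")
}

#' @export
print.support_mask <- function(x, ...) {
  cat(sprintf("Support mask: %d voxels in %d groups%s\n",
              x$n_prime, length(x$groups), if (x$empty) " (empty!)" else ""))
  invisible(x)
}

#' Refine the sparse image inside the support (Step-2)
#'
#' Nonnegative l1 solve restricted to the support columns, embedded back into
#' the full voxel grid with zeros outside I'.
#'
#' @param A sensing matrix or bare matrix (full resolution).
#' @param support a [recover_support()] mask.
#' @param y measurement vector.
#' @param lam l1 weight.
#' @param cfg a [solver_config()].
#' @return list: `x` (full-length voxel vector), `fit` (SALSA result, `NULL`
#'   for an empty support).
#' @export
refine_in_support <- function(A, support, y, lam, cfg = solver_config()) {
  W <- sensing_values(A)
  x <- numeric(ncol(W))
  if (support$n_prime == 0L)
    return(list(x = x, fit = NULL))
  cfg$lam <- lam
  cfg$nonneg <- TRUE
  fit <- salsa_l1(W[, support$indices, drop = FALSE], y, cfg)
  x[support$indices] <- fit$x
  list(x = x, fit = fit)
}

#' Fit a sparse DOT reconstruction by two-step dimensionality reduction
#'
#' The package's main estimator.  Given surface measurements y of a
#' continuous-wave DOT system with sensing matrix A (y = A x + e), it
#' reconstructs the nonnegative absorption-perturbation image x by:
#' \enumerate{
#'   \item depth compensation (optional, default on): columns of A are
#'     rescaled per depth layer by [layer_weights()] so deep voxels are not
#'     out-shouted by shallow ones;
#'   \item Step-1: correlated columns are grouped at threshold `tau`
#'     ([group_columns()]), the l1 weight lambda is chosen on the reduced
#'     system by the MAP/discrepancy rule ([select_lambda()]) unless given,
#'     and the support I' is recovered ([recover_support()]);
#'   \item Step-2: the image is re-estimated inside I' only
#'     ([refine_in_support()]), then mapped back to physical units by the
#'     inverse depth-weight correction ([undo_depth_compensation()]).
#' }
#'
#' @param y measurement vector (positive Rytov perturbations), or a
#'   `measurement_set` from [simulate_measurements()] (which also supplies
#'   `sigma2`).
#' @param A a [build_sensing_matrix()] object.
#' @param sigma2 measurement-noise variance; required when `lambda` is to be
#'   selected automatically.
#' @param tau correlation threshold of Step-1 (see [select_tau()] for picking
#'   it from a phantom).
#' @param alphas sparsity-parameter grid for lambda selection.
#' @param lambda fixed l1 weight; `NULL` (default) selects it by the
#'   discrepancy principle.
#' @param depth_compensation logical; apply the singular-value layer
#'   weighting.
#' @param p compensation power.
#' @param support_eps relative mass threshold of Step-1 group selection.
#' @param refit_lambda re-run the lambda selector on the restricted Step-2
#'   system instead of reusing Step-1's lambda.
#' @param cfg a [solver_config()].
#' @return object of class `drodot`; see [coef.drodot()], [fitted.drodot()],
#'   [summary.drodot()], [plot.drodot()].
#' @examples
#' \donttest{
#' layout <- make_layout("SD-I")
#' grid <- default_grid("SD-I")
#' A <- build_sensing_matrix(layout, grid)
#' x_true <- voxelize_scene(scene_library("fig1_disk"), grid)
#' meas <- simulate_measurements(A, x_true, noise_level = 0.02, seed = 1)
#' fit <- drodot(meas, A)
#' summary(fit)
#' }
#' @export
drodot <- function(y, A, sigma2 = NULL, tau = 0.96,
                   alphas = default_alpha_grid(), lambda = NULL,
                   depth_compensation = TRUE, p = 1, support_eps = 1e-3,
                   refit_lambda = FALSE, cfg = solver_config()) {
  cl <- match.call()
  if (inherits(y, "measurement_set")) {
    if (is.null(sigma2)) sigma2 <- y$sigma2
    y <- y$y
  }
  stopifnot(inherits(A, "sensing_matrix"))
  if (length(y) != nrow(A$W))
    stop("y and A are not conformable", call. = FALSE)
  if (is.null(lambda) && (is.null(sigma2) || sigma2 <= 0))
    stop("automatic lambda selection needs a positive 'sigma2' ",
         "(estimate it from replicate measurements)", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]

  lw <- NULL
  At <- A
  if (depth_compensation) {
    lw <- layer_weights(A, p = p)
    At <- apply_depth_compensation(A, lw)
  }

  grouping <- group_columns(At, tau)
  A_red <- reduce_system(At, grouping)
  t_group <- proc.time()[["elapsed"]] - t0

  sel <- NULL
  x_sharp0 <- NULL
  if (is.null(lambda)) {
    sel <- select_lambda(A_red, y, sigma2, alphas, cfg)
    lambda <- sel$lambda
    x_sharp0 <- sel$solutions[[sel$index]]
  }

  support <- if (!is.null(x_sharp0)) {
    # reuse the winning Step-1 solve from the selector
    xs <- x_sharp0
    if (max(xs) <= 0) {
      structure(list(indices = integer(0), n_prime = 0L, groups = integer(0),
                     x_sharp = xs, empty = TRUE, fit = NULL),
                class = "support_mask")
    } else {
      nz <- which(xs > support_eps * max(xs))
      idx <- sort(unlist(grouping$members[nz], use.names = FALSE))
      structure(list(indices = idx, n_prime = length(idx), groups = nz,
                     x_sharp = xs, empty = FALSE, fit = NULL),
                class = "support_mask")
    }
  } else {
    recover_support(A_red, y, lambda, grouping, cfg, eps = support_eps)
  }
  t_step1 <- proc.time()[["elapsed"]] - t0 - t_group

  lambda2 <- lambda
  if (refit_lambda && support$n_prime > 0L) {
    sel2 <- select_lambda(At$W[, support$indices, drop = FALSE], y, sigma2,
                          alphas, cfg)
    lambda2 <- sel2$lambda
  }
  refined <- refine_in_support(At, support, y, lambda2, cfg)
  x_hat <- refined$x
  x <- if (!is.null(lw)) undo_depth_compensation(x_hat, lw) else x_hat
  t_step2 <- proc.time()[["elapsed"]] - t0 - t_group - t_step1

  fitted_y <- as.numeric(A$W %*% x)
  structure(
    list(coefficients = x, fitted.values = fitted_y,
         residuals = y - fitted_y, y = y,
         grid = A$grid, layout = A$layout,
         lambda = lambda, lambda_step2 = lambda2, sigma2 = sigma2,
         tau = tau, grouping = grouping, support = support,
         depth_weights = lw,
         selection = if (!is.null(sel))
           sel[c("lambdas", "discrepancy", "index")] else NULL,
         dims = c(n = ncol(A$W), n_sharp = grouping$n_groups,
                  n_prime = support$n_prime),
         iterations = c(step1 = if (!is.null(support$fit))
                          support$fit$iterations else NA_integer_,
                        step2 = if (!is.null(refined$fit))
                          refined$fit$iterations else NA_integer_),
         timings = c(grouping = t_group, step1 = t_step1, step2 = t_step2),
         empty = support$empty, call = cl),
    class = "drodot")
}

#' @export
print.drodot <- function(x, ...) {
  d <- x$dims
  cat("Two-step dimensionality-reduction DOT reconstruction\n")
  cat(sprintf("  voxels: n = %d -> groups: n# = %d (%.1f%% reduction) -> support: n' = %d\n",
              d["n"], d["n_sharp"], 100 * (1 - d["n_sharp"] / d["n"]),
              d["n_prime"]))
  cat(sprintf("  lambda = %.4g%s, tau = %g, depth compensation %s\n",
              x$lambda,
              if (!is.null(x$selection)) " (discrepancy-selected)" else "",
              x$tau, if (is.null(x$depth_weights)) "off" else "on"))
  if (x$empty)
    cat("  ! empty support: all-zero reconstruction (consider a smaller lambda)\n")
  invisible(x)
}

#' @export
coef.drodot <- function(object, ...) object$coefficients

#' @export
fitted.drodot <- function(object, ...) object$fitted.values

#' @export
residuals.drodot <- function(object, ...) object$residuals

#' Summarize a DOT reconstruction
#'
#' @param object a [drodot()] fit.
#' @param truth optional true voxel image; when given, FWHM quality metrics
#'   ([quality_report()]) are included.
#' @param ... unused.
#' @export
summary.drodot <- function(object, truth = NULL, ...) {
  x <- object$coefficients
  out <- list(
    dims = object$dims, lambda = object$lambda, tau = object$tau,
    sigma2 = object$sigma2,
    residual_ms = mean(object$residuals^2),
    max_dmua = max(x),
    n_nonzero = sum(x > 0),
    centroid_depth = if (max(x) > 0) centroid_depth(x, object$grid) else NA_real_,
    timings = object$timings,
    quality = if (!is.null(truth))
      quality_report(x, truth, object$grid) else NULL,
    empty = object$empty)
  class(out) <- "summary.drodot"
  out
}

#' @export
print.summary.drodot <- function(x, ...) {
  d <- x$dims
  cat("DRO-DOT reconstruction summary\n")
  cat(sprintf("  dimensionality: n = %d, n# = %d, n' = %d\n",
              d["n"], d["n_sharp"], d["n_prime"]))
  cat(sprintf("  lambda = %.4g  (sigma2 = %.4g, mean sq. residual = %.4g)\n",
              x$lambda, if (is.null(x$sigma2)) NA else x$sigma2,
              x$residual_ms))
  cat(sprintf("  peak delta-mua = %.4g cm^-1 over %d nonzero voxels; centroid depth %.2f cm\n",
              x$max_dmua, x$n_nonzero, x$centroid_depth))
  if (!is.null(x$quality)) {
    q <- x$quality
    cat(sprintf("  quality vs truth: VR = %.3f, CR = %s, recovery = %.1f%%, components = %d\n",
                q$VR, if (is.infinite(q$CR)) "Inf" else sprintf("%.2f", q$CR),
                q$recovery_pct, q$n_components))
  }
  invisible(x)
}

#' Plot a depth slice of a reconstruction
#'
#' Images the reconstructed absorption perturbation on one x-y plane
#' (default: the layer containing the intensity centroid).
#'
#' @param x a [drodot()] fit.
#' @param layer depth-layer index to show (1 = shallowest).
#' @param ... passed to [graphics::image()].
#' @export
plot.drodot <- function(x, layer = NULL, ...) {
  g <- x$grid
  v <- x$coefficients
  if (is.null(layer)) {
    layer <- if (max(v) > 0) {
      round((centroid_depth(v, g) - g$origin[3]) / g$voxel_size + 0.5)
    } else 1L
    layer <- max(1L, min(g$n_layers, layer))
  }
  sl <- matrix(v[layer_columns(g, layer)], g$shape[1], g$shape[2])
  xs <- g$origin[1] + (seq_len(g$shape[1]) - 0.5) * g$voxel_size
  ys <- g$origin[2] + (seq_len(g$shape[2]) - 0.5) * g$voxel_size
  graphics::image(xs, ys, sl, xlab = "x (cm)", ylab = "y (cm)",
                  main = sprintf("delta-mua at z = %.2f cm",
                                 g$origin[3] + (layer - 0.5) * g$voxel_size),
                  useRaster = TRUE, ...)
  invisible(x)
}
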