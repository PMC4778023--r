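#' Solver settings
#'
#' @param lam l1 penalty weight lambda (>= 0).
#' @param gamma Tikhonov (l2) weight.
#' @param admm_mu augmented-Lagrangian penalty of the ADMM splitting; the
#'   solution is insensitive to it within an order of magnitude.
#' @param tol relative objective-change stopping tolerance.
#' @param max_iter iteration cap.
#' @param nonneg constrain the solution to be elementwise nonnegative.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(lam = 0, gamma = 0.01, admm_mu = 1, tol = 1e-5,
                          max_iter = 2000L, nonneg = TRUE) {
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
  if (max_iter < 1) stop("'max_iter' must be >= 1", call. = FALSE)
  if (admm_mu <= 0) stop("'admm_mu' must be positive", call. = FALSE)
  structure(list(lam = lam, gamma = gamma, admm_mu = admm_mu, tol = tol,
                 max_iter = as.integer(max_iter), nonneg = nonneg),
            class = "solver_config")
}

# soft threshold, one-sided (projected onto x >= 0) when nonneg
soft_threshold <- function(v, t, nonneg = TRUE) {
  if (nonneg) pmax(v - t, 0) else sign(v) * pmax(abs(v) - t, 0)
}

l1_objective <- function(W, y, x, lam) {
  r <- as.numeric(W %*% x) - y
  sum(r^2) + lam * sum(abs(x))
}

#' Nonnegative l1-regularized least squares by SALSA (ADMM)
#'
#' Minimizes ||A x - y||^2 + lambda ||x||_1, optionally subject to x >= 0, by
#' the split augmented Lagrangian shrinkage algorithm — an ADMM splitting
#' x = z whose x-update solves (A'A + mu I) x = A'y + mu (z + d) through the
#' Woodbury identity with a single upfront Cholesky factorization of
#' (A A' + mu I) (cheap for the underdetermined systems of diffuse optical
#' tomography, where rows << columns), and whose z-update is (one-sided) soft
#' thresholding at lambda / (2 mu).  Iterations start from the zero vector —
#' no prior knowledge of object position, size or contrast is assumed — and
#' stop when the relative change of the objective falls below `cfg$tol` and
#' the split is consistent (primal residual small relative to the iterate),
#' which protects small-penalty solves from a spurious stop on the initial
#' plateau.
#'
#' @param A sensing matrix (a `sensing_matrix` or bare matrix).
#' @param y measurement vector.
#' @param cfg a [solver_config()]; `cfg$lam` is the l1 weight.
#' @return list: `x` (solution), `objective` (per-iteration trace evaluated at
#'   the feasible z iterate), `iterations`, `converged`.
#' @export
salsa_l1 <- function(A, y, cfg = solver_config()) {
  W <- sensing_values(A)
  if (length(y) != nrow(W)) stop("A and y are not conformable", call. = FALSE)
  if (cfg$lam < 0) stop("'lam' must be nonnegative", call. = FALSE)
  mu <- cfg$admm_mu
  n <- ncol(W)

  # Woodbury: (W'W + mu I)^{-1} b = (b - W' (WW' + mu I)^{-1} W b) / mu
  Gch <- chol(tcrossprod(W) + diag(mu, nrow(W)))
  Wty <- as.numeric(crossprod(W, y))
  solve_x <- function(b) {
    (b - as.numeric(crossprod(W, backsolve(Gch, backsolve(Gch, as.numeric(W %*% b),
                                                          transpose = TRUE))))) / mu
  }

  z <- numeric(n)
  d <- numeric(n)
  thr <- cfg$lam / (2 * mu)
  obj <- numeric(cfg$max_iter)
  obj_prev <- l1_objective(W, y, z, cfg$lam)
  converged <- FALSE
  it <- 0L
  while (it < cfg$max_iter) {
    it <- it + 1L
    x <- solve_x(Wty + mu * (z + d))
    z <- soft_threshold(x - d, thr, cfg$nonneg)
    d <- d - (x - z)
    obj[it] <- l1_objective(W, y, z, cfg$lam)
    if (obj_prev > 0 && abs(obj[it] - obj_prev) < cfg$tol * obj_prev) {
      # guard against the early-iteration plateau where z is still pinned at
      # zero while the dual variable ramps up: accept the stop only once the
      # split is consistent (small primal residual x ~ z)
      if (max(abs(x - z)) <= sqrt(cfg$tol) * max(abs(x), 1e-300)) {
        converged <- TRUE
        break
      }
    }
    obj_prev <- obj[it]
  }
  if (!converged && obj_prev == 0) converged <- TRUE   # y = 0 edge case
  if (!converged)
    warning("SALSA reached max_iter without meeting the tolerance")
  list(x = z, objective = obj[seq_len(it)], iterations = it,
       converged = converged)
}

#' Closed-form Tikhonov (l2) reconstruction
#'
#' The minimum-norm regularized solution of the underdetermined system,
#' x = A' (A A' + gamma I)^{-1} y — the classic smooth baseline that DOT
#' practice reaches for first.
#'
#' @param A sensing matrix or bare matrix.
#' @param y measurement vector.
#' @param gamma positive regularization weight.
#' @return solution vector.
#' @export
tikhonov <- function(A, y, gamma) {
  W <- sensing_values(A)
  if (gamma <= 0) stop("'gamma' must be positive", call. = FALSE)
  if (length(y) != nrow(W)) stop("A and y are not conformable", call. = FALSE)
  as.numeric(crossprod(W, solve(tcrossprod(W) + diag(gamma, nrow(W)), y)))
}

#' Default sparsity-parameter grid
#'
#' Twelve log-spaced values spanning four decades centered on
#' 1 / (expected contrast x expected object volume) — the order of magnitude
#' that clinical or biomedical prior knowledge of lesion size and contrast
#' pins down.
#'
#' @param expected_contrast anticipated absorption perturbation (cm^-1).
#' @param expected_volume anticipated lesion volume (cm^3).
#' @param n_alphas,decades grid size and log-width.
#' @return increasing vector of sparsity parameters alpha.
#' @export
default_alpha_grid <- function(expected_contrast = 0.2, expected_volume = 0.38,
                               n_alphas = 12L, decades = 4) {
  center <- 1 / (expected_contrast * expected_volume)
  10^seq(log10(center) - decades / 2, log10(center) + decades / 2,
         length.out = n_alphas)
}

#' Select the l1 weight by the MAP / discrepancy-principle rule
#'
#' The l1-regularized problem is the MAP estimator under a Laplacian image
#' prior (sparsity parameter alpha) and Gaussian noise (variance sigma^2),
#' which identifies lambda = 2 sigma^2 alpha.  Given a grid of plausible
#' alphas, every candidate lambda is solved and the one whose per-channel mean
#' squared residual ||y - A x||^2 / mq is closest to sigma^2 is returned
#' (discrepancy principle); ties break toward the smaller lambda.
#'
#' @param A sensing matrix or bare matrix.
#' @param y measurement vector.
#' @param sigma2 measurement-noise variance (> 0), e.g. from
#'   [estimate_noise_variance()].
#' @param alphas increasing positive grid of sparsity parameters.
#' @param cfg a [solver_config()] (its `lam` is overridden per candidate).
#' @return list: `lambda` (chosen), `index`, `lambdas`, `discrepancy`
#'   (per-candidate mean squared residual), `solutions` (list of solution
#'   vectors, kept so the winning solve need not be repeated).
#' @export
select_lambda <- function(A, y, sigma2, alphas = default_alpha_grid(),
                          cfg = solver_config()) {
  W <- sensing_values(A)
  if (sigma2 <= 0) stop("'sigma2' must be positive", call. = FALSE)
  if (length(alphas) < 1L) stop("'alphas' must be nonempty", call. = FALSE)
  if (is.unsorted(alphas, strictly = TRUE) || any(alphas <= 0))
    stop("'alphas' must be strictly increasing and positive", call. = FALSE)
  lambdas <- 2 * sigma2 * alphas
  disc <- rep(NA_real_, length(lambdas))
  sols <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    cfg_i <- cfg
    cfg_i$lam <- lambdas[i]
    fit <- salsa_l1(W, y, cfg_i)
    sols[[i]] <- fit$x
    disc[i] <- mean((y - as.numeric(W %*% fit$x))^2)
  }
  # closest discrepancy to sigma2; ties toward smaller lambda
  gap <- abs(disc - sigma2)
  best <- which(gap == min(gap))[1L]
  list(lambda = lambdas[best], index = best, lambdas = lambdas,
       discrepancy = disc, solutions = sols)
}

#' Choose the Tikhonov weight by the discrepancy principle
#'
#' Bisects on log(gamma) until the per-channel mean squared residual of the
#' closed-form solution matches sigma^2; the residual is monotone increasing
#' in gamma, so bisection converges.  If sigma^2 lies outside the achievable
#' residual range the nearest bracket endpoint is returned with a warning.
#'
#' @param A sensing matrix or bare matrix.
#' @param y measurement vector.
#' @param sigma2 target noise variance (> 0).
#' @param bracket positive range of gamma to search.
#' @param tol relative residual-matching tolerance.
#' @return the selected gamma.
#' @export
tikhonov_gamma_by_discrepancy <- function(A, y, sigma2,
                                          bracket = c(1e-10, 1e6),
                                          tol = 1e-3) {
  W <- sensing_values(A)
  if (sigma2 <= 0) stop("'sigma2' must be positive", call. = FALSE)
  resid2 <- function(g) mean((y - as.numeric(W %*% tikhonov(W, y, g)))^2)
  lo <- bracket[1]; hi <- bracket[2]
  rlo <- resid2(lo); rhi <- resid2(hi)
  if (sigma2 <= rlo) {
    if (sigma2 < rlo * (1 - tol))
      warning("target variance below the achievable residual; returning lower endpoint")
    return(lo)
  }
  if (sigma2 >= rhi) {
    warning("target variance above the residual at the upper endpoint; returning it")
    return(hi)
  }
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    rm_ <- resid2(mid)
    if (abs(rm_ - sigma2) <= tol * sigma2) return(mid)
    if (rm_ < sigma2) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-12) break
  }
  sqrt(lo * hi)
}
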