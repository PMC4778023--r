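# Independent oracles used to validate the optimization and geometry code.
# These deliberately use different algorithms from the package internals.

# independent reference solution of min ||Ax-y||^2 + lam ||x||_1 (+ x >= 0):
# the better of an accelerated proximal-gradient run and glmnet's coordinate
# descent (objective mapping: glmnet minimizes RSS/(2m) + lambda ||x||_1)
l1_oracle <- function(A, y, lam, nonneg = TRUE) {
  pg <- ista_oracle(A, y, lam, nonneg = nonneg)
  xg <- tryCatch({
    gl <- glmnet::glmnet(A, y, lambda = lam / (2 * nrow(A)),
                         standardize = FALSE, intercept = FALSE,
                         thresh = 1e-20, maxit = 1e7,
                         lower.limits = if (nonneg) 0 else -Inf)
    as.numeric(stats::coef(gl))[-1]
  }, error = function(e) NULL)
  obj <- function(x) sum((A %*% x - y)^2) + lam * sum(abs(x))
  if (!is.null(xg) && obj(xg) < pg$objective) {
    list(x = xg, objective = obj(xg))
  } else {
    pg
  }
}

# accelerated proximal-gradient (FISTA) solver for
# min ||Ax-y||^2 + lam ||x||_1 (+ x >= 0), run to near machine precision
ista_oracle <- function(A, y, lam, nonneg = TRUE, tol = 1e-13,
                        max_iter = 50000L) {
  L <- 2 * svd(A, nu = 0, nv = 0)$d[1]^2
  t <- 1 / L
  prox <- function(v) {
    if (nonneg) pmax(v - t * lam, 0) else sign(v) * pmax(abs(v) - t * lam, 0)
  }
  obj <- function(x) sum((A %*% x - y)^2) + lam * sum(abs(x))
  x <- numeric(ncol(A))
  z <- x
  th <- 1
  o_best <- obj(x); x_best <- x
  stall <- 0L
  for (i in seq_len(max_iter)) {
    x_new <- prox(z - t * 2 * as.numeric(crossprod(A, A %*% z - y)))
    th_new <- (1 + sqrt(1 + 4 * th^2)) / 2
    z <- x_new + ((th - 1) / th_new) * (x_new - x)
    x <- x_new; th <- th_new
    o <- obj(x)
    if (o < o_best - tol * max(o_best, 1e-300)) {
      o_best <- o; x_best <- x; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > 200L) break   # no meaningful progress for a long stretch
    }
  }
  list(x = x_best, objective = o_best)
}

# Tikhonov via the (overdetermined-form) normal equations
tikhonov_normal_oracle <- function(A, y, gamma) {
  solve(crossprod(A) + diag(gamma, ncol(A)), as.numeric(crossprod(A, y)))
}

# brute-force check that every member of every group correlates >= tau with
# its representative
grouping_valid <- function(W, grouping, tol = 1e-10) {
  for (g in seq_len(grouping$n_groups)) {
    rep <- grouping$representative[g]
    for (m in grouping$members[[g]]) {
      if (m == rep) next
      if (stats::cor(W[, rep], W[, m]) < grouping$tau - tol) return(FALSE)
    }
  }
  TRUE
}

# small random nonnegative sensing-like matrix
random_instance <- function(m, n, seed) {
  set.seed(seed)
  A <- matrix(abs(rnorm(m * n)), m, n)
  x <- numeric(n)
  x[sample(n, max(1L, n %/% 10))] <- runif(max(1L, n %/% 10), 0.5, 2)
  y <- as.numeric(A %*% x) + rnorm(m, 0, 0.05)
  list(A = A, y = y, x = x)
}

# shared small fixture: SD-I system at coarse voxels, cached per test run
small_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      layout <- make_layout("SD-I")
      grid <- default_grid("SD-I", voxel_size = 0.4)   # 10 x 10 x 7 = 700 voxels
      A <- build_sensing_matrix(layout, grid)
      cache <<- list(layout = layout, grid = grid, A = A)
    }
    cache
  }
})
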