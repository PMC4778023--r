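test_that("greedy column grouping follows the sweep-and-threshold contract", {
  # two identical columns and one uncorrelated column
  a <- c(1, 2, 3, 4, 5)
  b <- residuals(lm(rnorm(5) ~ a))          # exactly decorrelated from a
  W <- cbind(a, a, b)
  g <- group_columns(W, tau = 0.9)
  expect_equal(g$n_groups, 2L)
  expect_equal(g$representative, c(1L, 3L))
  expect_equal(g$group_of, c(1L, 1L, 2L))

  # threshold above every pairwise correlation -> no reduction
  set.seed(8)
  W2 <- matrix(rnorm(40), 8, 5)
  g2 <- group_columns(W2, tau = 0.9999)
  expect_equal(g2$n_groups, 5L)

  # a constant column gets a singleton group with a warning
  W3 <- cbind(W2, 7)
  expect_warning(g3 <- group_columns(W3, 0.9), "zero-variance")
  expect_equal(sum(lengths(g3$members) == 1 &
                     sapply(g3$members, max) == 6), 1)

  expect_error(group_columns(W2, 0), "0, 1")
  expect_error(group_columns(W2, 1.5), "0, 1")
})

test_that("every group member correlates at least tau with its representative", {
  sys <- small_system()
  g <- group_columns(sys$A, tau = 0.96)
  expect_true(grouping_valid(sys$A$W, g))
  # groups partition the columns
  expect_equal(sort(unname(unlist(g$members))), seq_len(ncol(sys$A$W)))
})

test_that("grouping is invariant to positive column rescaling and monotone in tau", {
  sys <- small_system()
  W <- sys$A$W[, seq(1, 700, by = 7)]       # 100 columns for speed
  g1 <- group_columns(W, 0.95)
  set.seed(2)
  scl <- runif(ncol(W), 0.1, 10)
  g2 <- group_columns(sweep(W, 2, scl, "*"), 0.95)
  expect_identical(g1$group_of, g2$group_of)

  # n#(tau) non-decreasing
  ng <- sapply(c(0.8, 0.9, 0.95, 0.99, 1), function(t)
    group_columns(W, t)$n_groups)
  expect_true(all(diff(ng) >= 0))
  expect_equal(ng[5], ncol(W))              # tau = 1 keeps every column
})

test_that("the reduced system reproduces the full system in degenerate cases", {
  a <- abs(rnorm(10)) + 1
  W <- cbind(a, 2 * a, 0.5 * a)             # all proportional
  g <- group_columns(W, 0.99)
  expect_equal(g$n_groups, 1L)
  Ar <- reduce_system(W, g)
  expect_equal(ncol(Ar), 1L)
  x <- c(0.3, 0.5, 0.2)
  # identical-direction columns: A# x# uses the representative column
  expect_equal(as.numeric(Ar %*% group_sums(x, g)), as.numeric(a * 1.0),
               tolerance = 1e-12)

  # singleton grouping leaves the system untouched
  set.seed(4)
  W2 <- matrix(rnorm(50), 10, 5)
  gs <- group_columns(W2, 1)
  expect_equal(reduce_system(W2, gs), W2)
  expect_equal(approximation_error(W2, gs, c(1, 0, 2, 0, 1)), 0)
})

test_that("approximation error is zero for identical groups and shrinks with tau", {
  a <- abs(rnorm(12))
  W <- cbind(a, a, a, abs(rnorm(12)))
  g <- group_columns(W, 0.99)
  expect_equal(approximation_error(W, g, c(1, 2, 3, 4)), 0, tolerance = 1e-12)
  expect_error(approximation_error(W, g, rep(0, 4)), "nonzero")

  # on a real sensing matrix the error trend decreases as tau rises
  sys <- small_system()
  x_ref <- voxelize_scene(phantom_scene(
    inclusion("sphere", c(2, 2, 1.4), 0.9, delta_mua = 0.2)), sys$grid)
  taus <- c(0.80, 0.85, 0.90, 0.95, 0.99)
  errs <- sapply(taus, function(t)
    approximation_error(sys$A, group_columns(sys$A, t), x_ref))
  expect_lt(errs[5], errs[1])
  expect_lte(cor(taus, errs, method = "spearman"), 0)
})

test_that("tau selection returns the smallest threshold within the error budget", {
  sys <- small_system()
  x_ref <- voxelize_scene(phantom_scene(
    inclusion("sphere", c(2, 2, 1.4), 0.9, delta_mua = 0.2)), sys$grid)

  # a grid of only tau = 1 always qualifies (error exactly 0)
  s1 <- select_tau(sys$A, x_ref, tau_grid = 1.0)
  expect_equal(s1$tau_e, 1.0)
  expect_equal(s1$errors, 0)

  # max_err = 0 can never be met strictly; largest candidate + warning
  expect_warning(s0 <- select_tau(sys$A, x_ref, tau_grid = c(0.9, 1.0),
                                  max_err = 0), "largest")
  expect_equal(s0$tau_e, 1.0)

  # generous budget: the smallest candidate wins
  sbig <- select_tau(sys$A, x_ref, tau_grid = c(0.9, 0.95), max_err = 0.99)
  expect_equal(sbig$tau_e, 0.9)
  expect_error(select_tau(sys$A, x_ref, tau_grid = c(0.95, 0.9)), "ascending")
})

test_that("layer weights equalize per-layer maximum singular values", {
  # identical blocks -> all weights 1
  set.seed(6)
  B <- matrix(abs(rnorm(40)), 8, 5)
  W <- cbind(B, B, B)
  fake_grid <- make_grid(c(0, 0, 0), c(5, 1, 3), 0.2)
  lw <- layer_weights(W, grid = fake_grid)
  expect_equal(lw$w, rep(1, 3), tolerance = 1e-12)

  # p = 0 switches compensation off
  sys <- small_system()
  lw0 <- layer_weights(sys$A, p = 0)
  expect_equal(lw0$w, rep(1, sys$grid$n_layers))

  # real system: deepest weight is 1, weights rise with depth beyond the
  # shallow near-surface band, and theta matches a direct svd
  lw1 <- layer_weights(sys$A)
  nz <- sys$grid$n_layers
  expect_equal(lw1$w[nz], 1)
  pk <- which.max(lw1$theta)
  expect_true(all(diff(lw1$w[pk:nz]) > 0))
  th3 <- svd(sys$A$W[, layer_columns(sys$grid, 3)], nu = 0, nv = 0)$d[1]
  expect_equal(lw1$theta[3], th3, tolerance = 1e-10)

  # a zero layer block is rejected
  Wz <- W; Wz[, 11:15] <- 0
  expect_error(layer_weights(Wz, grid = fake_grid), "zero")
})

test_that("depth compensation and its inverse are exact algebraic partners", {
  sys <- small_system()
  lw <- layer_weights(sys$A)
  At <- apply_depth_compensation(sys$A, lw)
  set.seed(9)
  x_hat <- abs(rnorm(sys$grid$n))
  x_tilde <- undo_depth_compensation(x_hat, lw)
  # A~ x-hat = A x-tilde identically
  expect_equal(as.numeric(At$W %*% x_hat), as.numeric(sys$A$W %*% x_tilde),
               tolerance = 1e-10)
  # w = 1 is a no-op
  lw1 <- layer_weights(sys$A, p = 0)
  expect_equal(apply_depth_compensation(sys$A, lw1)$W, sys$A$W)
  expect_equal(undo_depth_compensation(x_hat, lw1), x_hat)
  # grouping is unchanged by compensation (scale invariance)
  gA <- group_columns(sys$A$W[, 1:150], 0.95)
  gAt <- group_columns(At$W[, 1:150], 0.95)
  expect_identical(gA$group_of, gAt$group_of)
})

test_that("support recovery finds true voxels and flags empty solutions", {
  sys <- small_system()
  g <- sys$grid
  true_vox <- grid_index(g, 5L, 5L, 4L)
  x_true <- numeric(g$n); x_true[true_vox] <- 0.2
  y0 <- as.numeric(sys$A$W %*% x_true)
  grp <- group_columns(sys$A, 0.96)
  Ar <- reduce_system(sys$A, grp)

  lam <- 1e-3 * 2 * max(abs(crossprod(Ar, y0)))
  sup <- recover_support(Ar, y0, lam, grp)
  expect_false(sup$empty)
  expect_true(true_vox %in% sup$indices)
  expect_equal(sup$n_prime, length(sup$indices))

  # an overwhelming penalty empties the support
  lam_max <- 2 * max(abs(crossprod(Ar, y0)))
  sup0 <- recover_support(Ar, y0, lam_max * 1.01, grp)
  expect_true(sup0$empty)
  expect_equal(sup0$n_prime, 0L)
})

test_that("in-support refinement embeds correctly and matches a restricted solve", {
  sys <- small_system()
  g <- sys$grid
  x_true <- voxelize_scene(phantom_scene(
    inclusion("sphere", c(2, 2, 1.4), 0.9, delta_mua = 0.2)), g)
  y0 <- as.numeric(sys$A$W %*% x_true)
  truth_idx <- which(x_true > 0)

  # support = exactly the true voxels, noiseless, small lambda:
  # near-perfect image recovery against a nonnegative least-squares oracle
  sup <- structure(list(indices = truth_idx, n_prime = length(truth_idx),
                        groups = integer(0), x_sharp = NULL, empty = FALSE),
                   class = "support_mask")
  lam <- 1e-6 * 2 * max(abs(crossprod(sys$A$W, y0)))
  ref <- refine_in_support(sys$A, sup, y0, lam,
                           solver_config(tol = 1e-10, max_iter = 10000))
  expect_lt(sqrt(sum((ref$x - x_true)^2)) / sqrt(sum(x_true^2)), 0.05)
  expect_true(all(ref$x[-truth_idx] == 0))

  # empty support gives the zero volume
  sup0 <- structure(list(indices = integer(0), n_prime = 0L, empty = TRUE),
                    class = "support_mask")
  expect_equal(refine_in_support(sys$A, sup0, y0, lam)$x, numeric(g$n))
})

test_that("the full estimator localizes a point absorber and handles y = 0", {
  sys <- small_system()
  g <- sys$grid
  true_vox <- grid_index(g, 5L, 6L, 4L)
  x_true <- numeric(g$n); x_true[true_vox] <- 0.2
  y0 <- as.numeric(sys$A$W %*% x_true)
  fit <- drodot(y0, sys$A, lambda = 1e-4 * 2 * max(abs(crossprod(sys$A$W, y0))))
  expect_equal(which.max(coef(fit)), true_vox)
  expect_equal(length(coef(fit)), g$n)
  expect_equal(fitted(fit) + residuals(fit), y0, tolerance = 1e-12)

  # y = 0 collapses to the empty reconstruction with a diagnostic flag
  fit0 <- drodot(rep(0, nrow(sys$A$W)), sys$A, lambda = 0.1)
  expect_true(fit0$empty)
  expect_equal(coef(fit0), numeric(g$n))

  # missing sigma2 with automatic lambda selection is an error
  expect_error(drodot(y0, sys$A), "sigma2")
})

test_that("reported dimensions and print methods are coherent", {
  sys <- small_system()
  g <- sys$grid
  x_true <- voxelize_scene(phantom_scene(
    inclusion("sphere", c(2, 2, 1.4), 0.9, delta_mua = 0.2)), g)
  meas <- simulate_measurements(sys$A, x_true, 0.02, seed = 3)
  fit <- drodot(meas, sys$A)
  d <- fit$dims
  expect_equal(unname(d["n"]), g$n)
  expect_equal(unname(d["n_sharp"]), fit$grouping$n_groups)
  expect_lte(d["n_prime"], d["n"])
  expect_equal(fit$lambda, fit$selection$lambdas[fit$selection$index])
  expect_output(print(fit), "reduction")
  expect_output(print(summary(fit, truth = x_true)), "VR")
})
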