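test_that("voxel grids have the documented size, ordering and bijective index map", {
  g <- make_grid(c(0, 0, 0), c(20, 20, 13), 0.2)
  expect_equal(g$n, 5200)
  expect_equal(g$n_layers, 13)

  g1 <- make_grid(c(0, 0, 0), c(1, 1, 1), 0.5)
  expect_equal(g1$n, 1)
  expect_equal(g1$n_layers, 1)

  # SD-I default volume covers >= 2.5 cm depth at h = 0.2
  gd <- default_grid("SD-I", 0.2)
  expect_equal(gd$shape, c(20L, 20L, 13L))
  expect_gte(gd$shape[3] * gd$voxel_size, 2.5)

  expect_error(make_grid(c(0, 0, 0), c(2, 0, 2), 0.2), "positive")
  expect_error(make_grid(c(0, 0, 0), c(2, 2, 2), -1), "positive")

  # flat index <-> subscripts is a bijection and layer-major
  gs <- make_grid(c(0, 0, 0), c(3, 4, 5), 0.1)
  flat <- seq_len(gs$n)
  sub <- grid_subscripts(gs, flat)
  expect_equal(grid_index(gs, sub[, 1], sub[, 2], sub[, 3]), flat)
  expect_equal(layer_of(gs), rep(1:5, each = 12))
  expect_equal(layer_columns(gs, 3), 25:36)
  # first block of voxel centers all share the layer-1 depth
  vc <- voxel_centers(gs)
  expect_equal(unique(vc[1:12, 3]), 0.05)
})

test_that("optode layouts produce the documented counts and spans", {
  tr <- make_layout("transrectal")
  expect_equal(nrow(tr$sources), 9)
  expect_equal(nrow(tr$detectors), 9)
  expect_equal(nrow(tr$pairs), 81)
  # two rows 2 cm apart, nearest optodes 0.5 cm
  expect_equal(sort(unique(c(tr$sources[, 2], tr$detectors[, 2]))), c(1, 3))
  all_pos <- rbind(tr$sources, tr$detectors)
  d <- as.matrix(dist(all_pos))
  expect_equal(min(d[d > 0]), 0.5)

  sd1 <- make_layout("SD-I", pitch = 1)
  expect_equal(nrow(sd1$sources), 25)
  expect_true(sd1$bifurcated)
  expect_equal(nrow(sd1$pairs), 600)           # co-located pairs excluded
  expect_equal(diff(range(sd1$sources[, 1])), 4)
  expect_equal(diff(range(sd1$sources[, 2])), 4)
  expect_equal(nrow(make_layout("SD-I", include_colocated = TRUE)$pairs), 625)

  sd2 <- make_layout("SD-II")
  expect_false(sd2$bifurcated)
  expect_equal(nrow(sd2$sources) + nrow(sd2$detectors), 25)

  sd4 <- make_layout("SD-IV")
  expect_equal(nrow(sd4$sources) + nrow(sd4$detectors), 10)

  expect_error(make_layout("SD-V"), "arg")
  expect_error(make_layout("SD-I", pitch = 0), "positive")
})

test_that("the semi-infinite Green's function matches its closed form and physics", {
  bg <- optical_background(mua = 0.03, musp = 10)
  expect_equal(bg$D, 1 / (3 * 10.03), tolerance = 1e-12)
  expect_equal(bg$mu_eff, sqrt(0.03 * 3 * 10.03), tolerance = 1e-12)

  # infinite-medium term at r = 1 cm against direct evaluation
  expect_equal(exp(-bg$mu_eff) / (4 * pi * bg$D), 0.9257, tolerance = 1e-3)

  # reciprocity to 1e-12 relative on a batch of random point pairs
  set.seed(42)
  for (i in 1:20) {
    p1 <- c(runif(2, -2, 2), runif(1, 0.1, 3))
    p2 <- c(runif(2, -2, 2), runif(1, 0.1, 3))
    expect_equal(greens_fn(p1, p2, bg), greens_fn(p2, p1, bg),
                 tolerance = 1e-12)
  }

  # boundary condition: zero on the extrapolated plane z = -z_b
  src <- c(0, 0, bg$z0)
  expect_equal(greens_fn(c(0.7, 0.2, -bg$z_b), src, bg), 0, tolerance = 1e-12)

  # exponential decay: 10 cm value tiny compared to 1 cm value
  g1 <- greens_fn(c(0, 0, 1), src, bg)
  g10 <- greens_fn(c(0, 0, 10), src, bg)
  expect_lt(g10, 1e-4 * g1)

  expect_error(greens_fn(src, src, bg), "singular")
  expect_error(optical_background(mua = -0.01), "positive")
})

test_that("sensing matrix rows follow the Rytov formula and reciprocity", {
  bg <- optical_background()
  # single source, single detector, single voxel: entry equals the formula
  g1 <- make_grid(c(0, 0, 0), c(1, 1, 1), 0.2)
  lay1 <- structure(
    list(variant = "SD-I", sources = matrix(c(-0.5, 0, 0), 1),
         detectors = matrix(c(0.5, 0, 0), 1),
         pairs = cbind(detector = 1L, source = 1L),
         bifurcated = FALSE, pitch = 1),
    class = "optode_layout")
  A1 <- build_sensing_matrix(lay1, g1, bg)
  rs <- c(-0.5, 0, bg$z0); rd <- c(0.5, 0, bg$z0); rk <- c(0.1, 0.1, 0.1)
  manual <- (0.2^3 / bg$D) * greens_fn(rs, rk, bg) * greens_fn(rk, rd, bg) /
    greens_fn(rs, rd, bg)
  expect_equal(as.numeric(A1$W), manual, tolerance = 1e-12)

  # bifurcated reciprocity: swapping (d, s) gives an identical row
  sys <- small_system()
  A <- sys$A
  rm <- A$row_map
  i <- which(rm$detector == 3 & rm$source == 7)
  j <- which(rm$detector == 7 & rm$source == 3)
  expect_equal(A$W[i, ], A$W[j, ], tolerance = 1e-10)

  expect_true(all(is.finite(A$W)))
  expect_true(all(A$W >= 0))
})

test_that("column sensitivity decays with depth below the near-surface band", {
  # mean per-layer column norms: near the surface the sparse point-optode
  # sampling (dead zones between optodes) and the extrapolated boundary leave
  # the first couple of layers below their peak; from the peak layer on the
  # decay is strict and steep for every geometry
  for (v in c("SD-I", "SD-II", "SD-III", "SD-IV")) {
    lay <- make_layout(v)
    g <- default_grid(v, 0.4)
    A <- build_sensing_matrix(lay, g)
    norms <- sqrt(colSums(A$W^2))
    ln <- as.numeric(tapply(norms, layer_of(g), mean))
    pk <- which.max(ln)
    expect_lte(pk, 3)
    expect_true(all(diff(ln[pk:length(ln)]) < 0))
    expect_lt(ln[length(ln)], 0.2 * max(ln))
  }
})

test_that("forward projection is linear over disjoint phantoms", {
  sys <- small_system()
  g <- sys$grid
  s1 <- phantom_scene(inclusion("sphere", c(1.2, 1.2, 1.0), 0.7, delta_mua = 0.2))
  s2 <- phantom_scene(inclusion("sphere", c(2.8, 2.8, 1.6), 0.7, delta_mua = 0.3))
  x1 <- voxelize_scene(s1, g); x2 <- voxelize_scene(s2, g)
  y1 <- as.numeric(sys$A$W %*% x1)
  y2 <- as.numeric(sys$A$W %*% x2)
  y12 <- as.numeric(sys$A$W %*% (x1 + x2))
  expect_equal(y12, y1 + y2, tolerance = 1e-12)
})
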