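test_that("phantom spec validation rejects degenerate parameters", {
  expect_error(vessel_phantom_spec(shape = c(16, 64, 64)), "shape")
  expect_error(vessel_phantom_spec(radius_range_um = c(0.5, 2),
                                   spacing_um = c(1, 1, 1)), "radius")
  expect_error(vessel_phantom_spec(n_extra_loops = -1), "loops")
  expect_error(vessel_phantom_spec(n_trees = 0), "n_trees")
  expect_error(vessel_phantom_spec(noise_sd = -1), "noise")
})

test_that("a single straight branch is recorded with its exact length", {
  spec <- vessel_phantom_spec(shape = c(128, 48, 48), n_trees = 1,
                              n_branches_per_tree = 1,
                              branch_length_range_um = c(100, 100),
                              radius_range_um = c(3, 3),
                              curvature = 0, noise_sd = 0, seed = 4)
  ph <- generate_vessel_phantom(spec)
  g <- ph$truth$graph
  expect_equal(nrow(g$branches), 1L)
  expect_equal(g$branches$length_um, 100, tolerance = 1e-8)
  expect_equal(g$branches$mean_radius_um, 3)
})

test_that("each added anastomosis adds exactly one cycle", {
  for (k in c(0L, 3L)) {
    spec <- vessel_phantom_spec(shape = c(96, 96, 96), n_trees = 1,
                                n_branches_per_tree = 12,
                                n_extra_loops = k, seed = 11 + k)
    ph <- generate_vessel_phantom(spec)
    expect_identical(ph$truth$loop_count, k)
    expect_identical(cycle_rank(ph$truth$graph), k)
  }
})

test_that("same spec and seed give bit-identical phantoms", {
  spec <- vessel_phantom_spec(shape = c(64, 64, 64), noise_sd = 8, seed = 3)
  a <- generate_vessel_phantom(spec)
  b <- generate_vessel_phantom(spec)
  expect_identical(unclass(a$stack), unclass(b$stack))
  expect_identical(unclass(a$truth$mask), unclass(b$truth$mask))
})

test_that("truth mask covers every centerline voxel", {
  spec <- vessel_phantom_spec(shape = c(64, 64, 64), n_trees = 2,
                              n_branches_per_tree = 6, seed = 5)
  ph <- generate_vessel_phantom(spec)
  m <- array(as.logical(ph$truth$mask), dim = dim(ph$truth$mask))
  sp <- spacing_um(ph$truth$mask)
  for (p in ph$truth$graph$paths) {
    ijk <- round(sweep(p, 2, sp, "/")) + 1
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= dim(m)[1] &
      ijk[, 2] >= 1 & ijk[, 2] <= dim(m)[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= dim(m)[3]
    idx <- (ijk[ok, 3] - 1) * dim(m)[1] * dim(m)[2] +
      (ijk[ok, 2] - 1) * dim(m)[1] + ijk[ok, 1]
    expect_true(all(m[idx]))
  }
})

test_that("loop phantom has exactly the requested cycle rank", {
  ph <- generate_loop_phantom(4, seed = 2, jitter_um = 0.5)
  expect_identical(ph$truth$loop_count, 4L)
  expect_identical(cycle_rank(ph$truth$graph), 4L)
})

test_that("spherical cyst volume matches the analytic volume within 5%", {
  ph <- generate_cyst_phantom(c(48, 48, 48), c(1, 1, 1),
                              cyst_radii_um = 10, seed = 1)
  expect_length(ph$truth$cyst_volumes_um3, 1)
  analytic <- 4 / 3 * pi * 10^3
  expect_lt(abs(ph$truth$cyst_volumes_um3 - analytic) / analytic, 0.05)
  expect_lt(sum(ph$truth$cyst_volumes_um3), ph$truth$tissue_volume_um3)
})

test_that("cyst phantom degenerate cases behave", {
  ph <- generate_cyst_phantom(c(40, 40, 40), cyst_radii_um = numeric(0),
                              seed = 1)
  expect_false(any(ph$truth$mask))
  ph2 <- generate_cyst_phantom(c(64, 64, 64), cyst_radii_um = c(7, 7),
                               seed = 2)
  expect_equal(ph2$truth$cyst_volumes_um3[1], ph2$truth$cyst_volumes_um3[2])
  expect_error(generate_cyst_phantom(c(40, 40, 40),
                                     cyst_radii_um = rep(15, 20), seed = 1),
               "overlap")
})

test_that("ASL simulator matches the inversion-recovery closed form", {
  TI <- c(30, 50, 100, 150, 200, 300, 500, 1000, 1500, 2500, 5000, 8000)
  M0 <- array(1000, c(2, 2)); T1 <- array(1500, c(2, 2))
  rbf <- array(0, c(2, 2))
  ser <- generate_asl_series(M0, T1, rbf, TI, noise_sd = 0, seed = 1)
  for (k in seq_along(TI)) {
    expected <- 1000 * (1 - 2^(-TI[k] / 1500))
    expect_equal(unname(ser$multiTI_signals[1, 1, k]), expected,
                 tolerance = 1e-12)
  }
  # zero flow: control and label repeats identical
  expect_identical(ser$control_repeats, ser$label_repeats)
  # long-TI limit approaches M0
  ser2 <- generate_asl_series(M0, T1, rbf, c(100, 1000, 1e6), noise_sd = 0)
  expect_equal(unname(ser2$multiTI_signals[1, 1, 3]), 1000, tolerance = 1e-3)
})

test_that("ASL simulator validates inputs", {
  M0 <- array(1000, c(2, 2))
  expect_error(generate_asl_series(M0, array(-5, c(2, 2)), M0 * 0, c(100, 200, 300)),
               "T1")
  expect_error(generate_asl_series(M0, array(1000, c(2, 2)), M0 * 0,
                                   c(300, 200, 100)), "increasing")
})
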