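test_that("rolling-ball subtraction removes plateaus and keeps spots", {
  const <- volume_image(array(37, c(24, 24, 3)))
  out <- subtract_background(const, 5)
  expect_true(all(unclass(out) == 0))

  a <- array(10, c(25, 25, 1))
  a[13, 13, 1] <- 200
  vi <- volume_image(a)
  out2 <- subtract_background(vi, 8)
  # oracle: opening of the slice is the background estimate
  bg <- oracle_open2d(a[, , 1], 8)
  expect_equal(unclass(out2)[, , 1], pmax(a[, , 1] - bg, 0))
  expect_gt(unclass(out2)[13, 13, 1], 150)   # spot preserved
  expect_equal(sum(unclass(out2) > 0), 1)    # plateau removed

  set.seed(1)
  r <- volume_image(array(runif(24^2 * 4, 0, 50), c(24, 24, 4)))
  expect_gte(min(subtract_background(r, 6)), 0)
  expect_error(subtract_background(const, 0), "radius")
  expect_error(subtract_background(const, 30), "extent")
})

test_that("Gaussian smoothing conserves mass and reduces noise variance", {
  const <- volume_image(array(5, c(20, 20, 20)))
  expect_equal(unclass(smooth_stack(const, 2)), unclass(const),
               tolerance = 1e-12)

  imp <- array(0, c(21, 21, 21)); imp[11, 11, 11] <- 1
  sm <- smooth_stack(volume_image(imp), 1.5)
  expect_equal(sum(sm), 1, tolerance = 1e-12)

  set.seed(42)
  noise <- array(rnorm(30^3), c(30, 30, 30))
  sm2 <- smooth_stack(volume_image(noise), 2)
  expect_lt(var(as.numeric(unclass(sm2))), var(as.numeric(noise)))
  expect_equal(mean(unclass(sm2)), mean(noise), tolerance = 1e-3)
  expect_error(smooth_stack(const, 0), "sigma")
})

test_that("mean binarization matches the bimodal oracle exactly", {
  set.seed(7)
  n <- 10000
  vals <- c(rep(10, 0.9 * n), rep(200, 0.1 * n))
  vals <- sample(vals)
  stack <- volume_image(array(vals, c(10, 10, 100)))
  # oracle: mean = 0.9*10 + 0.1*200 = 29; bright 10% selected
  m <- binarize(stack, "mean", 0)
  expect_equal(attr(m, "threshold"), 29)
  expect_equal(sum(m), 0.1 * n)
  expect_true(all(unclass(stack)[unclass(m)] == 200))
})

test_that("Li threshold lands between the modes of a two-delta histogram", {
  x <- c(rep(20, 700), rep(120, 300))
  t_li <- threshold_li(x)
  expect_gt(t_li, 20)
  expect_lt(t_li, 120)
  # brute-force scan of the Li cross-entropy objective over candidate
  # thresholds: the iterative solution must land in the same flat region
  cand <- seq(21, 119, by = 1)
  obj <- vapply(cand, function(t) oracle_li_objective(x, t), numeric(1))
  best <- cand[which.min(obj)]
  expect_equal(oracle_li_objective(x, t_li), oracle_li_objective(x, best))
})

test_that("binarize flags degenerate masks", {
  const <- volume_image(array(3, c(8, 8, 8)))
  # a constant stack warns twice: the Li fallback and the empty-mask QC
  expect_warning(expect_warning(binarize(const, "li"), "constant"), "empty")
  expect_warning(binarize(volume_image(array(c(1, 2), c(8, 8, 8))),
                          "mean", offset = 100), "empty")
})

test_that("clean_mask removes specks, closes gaps, and is idempotent", {
  m <- array(FALSE, c(30, 12, 12))
  m[2:3, 2, 2] <- TRUE                      # 2-voxel speck
  m[5:24, 6:8, 6:8] <- TRUE                 # 180-voxel slab
  bm <- binary_mask(m)
  out <- clean_mask(bm, min_object_vox = 3, n_close = 0, n_dilate_erode = 0)
  expect_false(any(unclass(out)[1:3, , ]))
  expect_true(all(unclass(out)[5:24, 6:8, 6:8]))

  # two tube segments separated by a 1-voxel gap merge after one close
  g <- array(FALSE, c(30, 9, 9))
  g[2:14, 4:6, 4:6] <- TRUE
  g[16:28, 4:6, 4:6] <- TRUE
  expect_equal(attr(renovasc:::.label_components(g, 26), "n_components"), 2)
  closed <- clean_mask(binary_mask(g), 0, n_close = 1, n_dilate_erode = 0)
  expect_equal(attr(renovasc:::.label_components(
    array(as.logical(closed), dim = dim(closed)), 26), "n_components"), 1)

  empty <- clean_mask(binary_mask(array(FALSE, c(8, 8, 8))), 3, 1, 1)
  expect_false(any(empty))

  once <- clean_mask(bm, 3, 1, 1)
  twice <- clean_mask(once, 3, 1, 1)
  expect_identical(unclass(once), unclass(twice))
})

test_that("dilate-then-erode keeps at least the closing of a component", {
  set.seed(9)
  m <- array(FALSE, c(24, 24, 24))
  m[6:18, 8:12, 8:12] <- TRUE
  closed <- clean_mask(binary_mask(m), 0, n_close = 1, n_dilate_erode = 0)
  de <- clean_mask(binary_mask(m), 0, n_close = 0, n_dilate_erode = 1)
  expect_gte(sum(de), sum(closed))
})

test_that("fetal recipe segments noise-free tube phantoms with Dice >= 0.9", {
  spec <- vessel_phantom_spec(shape = c(112, 112, 112),
                              spacing_um = c(0.5, 0.5, 0.5),
                              n_trees = 2, n_branches_per_tree = 6,
                              branch_length_range_um = c(12, 25),
                              radius_range_um = c(3, 5),
                              noise_sd = 0, seed = 2)
  ph <- generate_vessel_phantom(spec)
  cfg <- segmentation_config("fetal", rolling_ball_radius_vox = 25)
  m <- suppressWarnings(segment_vessels(ph$stack, cfg))
  expect_gte(dice_coef(m, ph$truth$mask), 0.90)
})

test_that("component count survives noise at half the tube contrast", {
  spec <- vessel_phantom_spec(shape = c(112, 112, 112),
                              spacing_um = c(0.5, 0.5, 0.5),
                              n_trees = 2, n_branches_per_tree = 6,
                              branch_length_range_um = c(12, 25),
                              radius_range_um = c(3, 5),
                              noise_sd = 75, seed = 2)
  ph <- generate_vessel_phantom(spec)
  cfg <- segmentation_config("fetal", rolling_ball_radius_vox = 25)
  m <- suppressWarnings(segment_vessels(ph$stack, cfg))
  expect_equal(renovasc:::.n_components(
    array(as.logical(m), dim = dim(m)), 26), 2)
})

test_that("all-zero stacks give an empty mask with a QC warning", {
  z <- volume_image(array(0, c(48, 48, 8)))
  expect_warning(m <- segment_vessels(z, segmentation_config("fetal")),
                 "QC")
  expect_false(any(m))
})

test_that("adult recipe enhances tubes and returns a plausible mask", {
  spec <- vessel_phantom_spec(shape = c(64, 64, 64), n_trees = 1,
                              n_branches_per_tree = 5,
                              radius_range_um = c(2.5, 3.5),
                              noise_sd = 0, seed = 2)
  ph <- generate_vessel_phantom(spec)
  cfg <- segmentation_config("adult", rolling_ball_radius_vox = 20,
                             threshold_method = "li")
  m <- suppressWarnings(segment_vessels(ph$stack, cfg))
  tr <- array(as.logical(ph$truth$mask), dim = dim(m))
  # the tubeness mask must overlap the truth far better than chance
  expect_gt(sum(m & tr) / sum(m), 2 * mean(tr))
})

test_that("cyst segmentation recovers a single sphere within 5%", {
  ph <- generate_cyst_phantom(c(64, 64, 64), cyst_radii_um = 10, seed = 3)
  seg <- segment_cysts(ph$stack)
  lab <- renovasc:::.label_components(
    array(as.logical(seg$cyst_mask), dim = dim(seg$cyst_mask)), 26)
  expect_equal(attr(lab, "n_components"), 1)
  vol <- sum(seg$cyst_mask) * voxel_volume_um3(seg$cyst_mask)
  truth <- ph$truth$cyst_volumes_um3
  expect_lt(abs(vol - truth) / truth, 0.05)
})

test_that("cyst segmentation of a cyst-free phantom finds nothing", {
  ph <- generate_cyst_phantom(c(48, 48, 48), cyst_radii_um = numeric(0),
                              seed = 1)
  seg <- segment_cysts(ph$stack)
  expect_equal(sum(seg$cyst_mask), 0)
  expect_gt(sum(seg$kidney_mask), 0)
})

test_that("a border-clipped cyst is counted once and flagged", {
  # build the stack by hand: bright tissue block with a half-sphere hole
  # cut by the z = 1 face
  d <- c(48, 48, 32)
  a <- array(150, d)
  cx <- 24; cy <- 24; r <- 8
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:12)
    if ((i - cx)^2 + (j - cy)^2 + (k - 1)^2 <= r^2) a[i, j, k] <- 10
  seg <- segment_cysts(volume_image(a))
  lab <- renovasc:::.label_components(
    array(as.logical(seg$cyst_mask), dim = d), 26)
  expect_equal(attr(lab, "n_components"), 1)
  expect_length(attr(seg$cyst_mask, "border_touching"), 1)
})

test_that("cyst statistics arithmetic and anisotropy", {
  d <- c(30, 30, 30)
  cysts <- array(FALSE, d); kidney <- array(TRUE, d)
  cysts[2:11, 2:11, 2] <- TRUE            # 100 voxels
  cs <- cyst_statistics(binary_mask(cysts, c(1, 1, 5)),
                        binary_mask(kidney, c(1, 1, 5)))
  expect_equal(cs$n_cysts, 1)
  expect_equal(cs$volumes_um3, 500)
  expect_equal(cs$kidney_volume_um3, prod(d) * 5)
  expect_equal(cs$cyst_fraction, 500 / (prod(d) * 5))
  expect_error(cyst_statistics(binary_mask(cysts),
                               binary_mask(array(FALSE, d))), "zero")
})

test_that("cyst fraction invariant holds on generated phantoms", {
  ph <- generate_cyst_phantom(c(64, 64, 64), cyst_radii_um = c(8, 6, 5),
                              seed = 9)
  seg <- segment_cysts(ph$stack)
  cs <- cyst_statistics(seg$cyst_mask, seg$kidney_mask)
  expect_equal(cs$n_cysts, 3)
  expect_equal(cs$cyst_fraction,
               sum(cs$volumes_um3) / cs$kidney_volume_um3)
  expect_equal(length(cs$volumes_um3), cs$n_cysts)
})
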