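test_that("a solid tube skeletonizes to a single centred chain", {
  bm <- make_tube_mask(40, 15, 15, 5, 35, 8, 8, 3)
  sk <- skeletonize(bm)
  w <- which(array(sk, dim = dim(sk)), arr.ind = TRUE)
  # one voxel-wide chain near the tube axis (thinning may wobble by a
  # voxel or two at the end caps)
  expect_true(all(abs(w[, 2] - 8) <= 3))
  expect_true(all(abs(w[, 3] - 8) <= 3))
  g <- prune_graph(extract_graph(sk, bm), 5)
  expect_equal(nrow(g$branches), 1)
  expect_equal(cycle_rank(g), 0L)
  expect_error(skeletonize(binary_mask(array(FALSE, c(8, 8, 8)))), "empty")
})

test_that("a torus-like loop keeps exactly one cycle through thinning", {
  d <- c(40, 40, 9)
  m <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    rad <- sqrt((i - 20)^2 + (j - 20)^2)
    if (abs(rad - 12) <= 2.5 && abs(k - 5) <= 2.5) m[i, j, k] <- TRUE
  }
  sk <- skeletonize(binary_mask(m))
  g <- extract_graph(sk, binary_mask(m))
  expect_equal(cycle_rank(g), 1L)
})

test_that("component count is preserved by skeletonization", {
  for (s in c(3, 8)) {
    spec <- vessel_phantom_spec(shape = c(64, 64, 64), n_trees = 2,
                                n_branches_per_tree = 5, seed = s)
    ph <- generate_vessel_phantom(spec)
    m <- array(as.logical(ph$truth$mask), dim = dim(ph$truth$mask))
    sk <- skeletonize(ph$truth$mask)
    expect_equal(
      attr(renovasc:::.label_components(
        array(as.logical(sk), dim = dim(sk)), 26), "n_components"),
      attr(renovasc:::.label_components(m, 26), "n_components"))
  }
})

test_that("an 11-voxel chain at 2 um spacing is one 20 um branch", {
  m <- array(FALSE, c(15, 7, 7))
  m[3:13, 4, 4] <- TRUE
  bm <- binary_mask(m, c(2, 2, 2))
  g <- extract_graph(bm, bm)
  expect_equal(nrow(g$branches), 1)
  expect_equal(g$branches$length_um, 20)
})

test_that("a Y-shaped skeleton yields 3 branches and one degree-3 node", {
  m <- array(FALSE, c(21, 21, 5))
  m[2:11, 11, 3] <- TRUE                       # stem
  for (t in 1:8) m[11 + t, 11 + t, 3] <- TRUE  # upper arm
  for (t in 1:8) m[11 + t, 11 - t, 3] <- TRUE  # lower arm
  bm <- binary_mask(m)
  g <- extract_graph(bm, bm)
  expect_equal(nrow(g$branches), 3)
  expect_equal(sum(g$nodes$degree == 3), 1)
  expect_equal(sum(g$nodes$degree == 1), 3)
})

test_that("branch radius is recovered within 20% on a tube", {
  bm <- make_tube_mask(40, 17, 17, 4, 36, 9, 9, 6)
  sk <- skeletonize(bm)
  g <- prune_graph(extract_graph(sk, bm), 8)
  main <- g$branches[which.max(g$branches$length_um), ]
  expect_lt(abs(main$mean_radius_um - 6) / 6, 0.20)
})

test_that("skeleton must be contained in its mask", {
  m <- array(FALSE, c(10, 10, 10)); m[3:7, 5, 5] <- TRUE
  wrong <- array(FALSE, c(10, 10, 10)); wrong[1, 1, 1] <- TRUE
  expect_error(extract_graph(binary_mask(m | wrong), binary_mask(m)),
               "contained")
})

test_that("geometry report arithmetic and pruning monotonicity", {
  # 50 branches in 0.005 mm^3 -> 10000 per mm^3
  nodes <- data.frame(id = 1:51, x = seq(0, 500, length.out = 51), y = 0,
                      z = 0, degree = c(1, rep(2, 49), 1))
  paths <- lapply(1:50, function(i)
    rbind(c((i - 1) * 10, 0, 0), c(i * 10, 0, 0)))
  br <- data.frame(id = 1:50, from = 1:50, to = 2:51, length_um = 10,
                   mean_radius_um = 3)
  g <- vessel_graph(nodes, br, paths)
  tissue <- binary_mask(array(TRUE, c(50, 10, 10)), c(10, 10, 10))  # 0.005 mm3
  rep <- geometry_report(g, tissue)
  expect_equal(rep$tissue_volume_mm3, 0.005)
  expect_equal(rep$branch_density_per_mm3, 10000)
  expect_equal(rep$n_branches, 50)
  expect_equal(rep$mean_branch_length_um, 10)
  expect_error(geometry_report(g, binary_mask(array(FALSE, c(4, 4, 4)))),
               "zero")

  spec <- vessel_phantom_spec(shape = c(64, 64, 64), n_trees = 1,
                              n_branches_per_tree = 8, seed = 6)
  ph <- generate_vessel_phantom(spec)
  sk <- skeletonize(ph$truth$mask)
  gg <- extract_graph(sk, ph$truth$mask)
  tis <- binary_mask(array(TRUE, dim(sk)), spacing_um(sk))
  dens <- vapply(c(0, 4, 8, 16), function(pr)
    geometry_report(gg, tis, prune_below_um = pr)$branch_density_per_mm3,
    numeric(1))
  expect_true(all(diff(dens) <= 0))
})

test_that("total branch length is invariant to axis permutation", {
  spec <- vessel_phantom_spec(shape = c(64, 64, 64), n_trees = 1,
                              n_branches_per_tree = 6, seed = 12)
  ph <- generate_vessel_phantom(spec)
  m <- array(as.logical(ph$truth$mask), dim = dim(ph$truth$mask))
  g1 <- prune_graph(extract_graph(skeletonize(binary_mask(m)),
                                  binary_mask(m)), 5)
  mp <- aperm(m, c(3, 1, 2))
  g2 <- prune_graph(extract_graph(skeletonize(binary_mask(mp)),
                                  binary_mask(mp)), 5)
  # thinning breaks ties in raster order, so permuting axes can move a
  # few skeleton voxels; total length agrees to within a couple percent
  expect_equal(sum(g1$branches$length_um), sum(g2$branches$length_um),
               tolerance = 0.02)
})

test_that("graph recovery on phantoms: branch count, lengths, radii", {
  spec <- vessel_phantom_spec(shape = c(96, 96, 96), n_trees = 1,
                              n_branches_per_tree = 6,
                              branch_length_range_um = c(25, 40),
                              radius_range_um = c(2.5, 3.5),
                              curvature = 0.1, seed = 21)
  ph <- generate_vessel_phantom(spec)
  sk <- skeletonize(ph$truth$mask)
  g <- prune_graph(extract_graph(sk, ph$truth$mask), 5)
  truth <- ph$truth$graph
  expect_equal(nrow(g$branches), nrow(truth$branches))
  expect_equal(sum(g$branches$length_um), sum(truth$branches$length_um),
               tolerance = 0.15)
  expect_equal(mean(g$branches$mean_radius_um),
               mean(truth$branches$mean_radius_um), tolerance = 0.20)
})
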