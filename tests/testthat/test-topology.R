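test_that("endpoint cloud deduplicates shared junctions", {
  nodes <- data.frame(id = 1:4,
                      x = c(0, 10, 20, 20), y = c(0, 0, 5, -5), z = 0,
                      degree = c(1, 3, 1, 1))
  paths <- list(rbind(c(0, 0, 0), c(10, 0, 0)),
                rbind(c(10, 0, 0), c(20, 5, 0)),
                rbind(c(10, 0, 0), c(20, -5, 0)))
  br <- data.frame(id = 1:3, from = c(1, 2, 2), to = c(2, 3, 4),
                   length_um = c(10, 11.2, 11.2), mean_radius_um = 2)
  g <- vessel_graph(nodes, br, paths)
  pts <- endpoint_cloud(g)
  expect_equal(nrow(pts), 4)           # junction counted once
  expect_lte(nrow(pts), 2 * nrow(br))

  g1 <- vessel_graph(nodes[1:2, ], br[1, , drop = FALSE], paths[1])
  expect_equal(nrow(endpoint_cloud(g1)), 2)
})

test_that("far-separated points give only infinite dim-0 bars", {
  pts <- cbind(c(0, 100, 200, 300), 0, 0)
  expect_warning(dg <- rips_persistence(pts, max_edge_um = 10), "QC")
  expect_equal(nrow(dg), 4)
  expect_true(all(dg$dimension == 0))
  expect_true(all(!is.finite(dg$death)))
})

test_that("an 8-point circle carries exactly one dim-1 feature", {
  pts <- circle_points(8, 20)
  dg <- rips_persistence(pts, max_edge_um = 80)
  expect_equal(betti1(dg), 1)
  # birth at the polygon edge; death on the hole-filling scale, i.e.
  # between the radius and the diameter of the circle
  d1 <- dg[dg$dimension == 1, ]
  expect_equal(d1$birth, 2 * 20 * sin(pi / 8), tolerance = 1e-9)
  expect_gt(d1$death, 20)
  expect_lt(d1$death, 40)
})

test_that("two separated circles carry two dim-1 features", {
  pts <- rbind(circle_points(8, 15, c(0, 0, 0)),
               circle_points(8, 15, c(200, 0, 0)))
  dg <- rips_persistence(pts, max_edge_um = 60)
  expect_equal(betti1(dg), 2)
  expect_equal(sum(dg$dimension == 0 & !is.finite(dg$death)), 2)
})

test_that("reduction agrees with the brute-force oracle on small clouds", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(4:10, 1)
    pts <- matrix(runif(3 * n, 0, 50), ncol = 3)
    me <- 40
    got <- sort_diagram(rips_persistence(pts, max_edge_um = me))
    want <- sort_diagram(oracle_rips(pts, me))
    expect_equal(got, want, tolerance = 1e-10)
  }
  # the circle examples, against the same oracle
  pts <- circle_points(8, 20)
  expect_equal(sort_diagram(rips_persistence(pts, max_edge_um = 80)),
               sort_diagram(oracle_rips(pts, 80)), tolerance = 1e-10)
})

test_that("betti1 thresholds lifetimes correctly", {
  dg <- structure(data.frame(dimension = c(0, 1, 1, 1),
                             birth = c(0, 1, 2, 3),
                             death = c(Inf, 2, 8, Inf)),
                  class = c("persistence_diagram", "data.frame"))
  expect_equal(betti1(dg), 3)
  expect_equal(betti1(dg, 2), 2)
  expect_equal(betti1(dg, 100), 1)     # infinite bar always counts
  empty <- structure(data.frame(dimension = 0, birth = 0, death = Inf),
                     class = c("persistence_diagram", "data.frame"))
  expect_equal(betti1(empty), 0)
})

test_that("persistence entropy closed forms", {
  mk <- function(lt) structure(
    data.frame(dimension = 1, birth = 0, death = lt),
    class = c("persistence_diagram", "data.frame"))
  expect_equal(persistence_entropy(mk(rep(2, 5))), log(5), tolerance = 1e-12)
  expect_equal(persistence_entropy(mk(7)), 0)
  expect_equal(persistence_entropy(mk(c(1, 1, 2))),
               log(4) - 0.5 * log(2), tolerance = 1e-12)
  # direct summation oracle on random lifetimes
  set.seed(2)
  lt <- runif(20, 0.1, 5)
  p <- lt / sum(lt)
  expect_equal(persistence_entropy(mk(lt)), -sum(p * log(p)),
               tolerance = 1e-12)
  # invariance under uniform scaling
  expect_equal(persistence_entropy(mk(lt)), persistence_entropy(mk(10 * lt)),
               tolerance = 1e-12)
  inf_only <- mk(Inf)
  expect_error(persistence_entropy(inf_only), "finite")
})

test_that("average lifetime is the mean of finite lifetimes", {
  mk <- function(lt) structure(
    data.frame(dimension = 1, birth = 0, death = lt),
    class = c("persistence_diagram", "data.frame"))
  expect_equal(average_lifetime(mk(c(1, 3))), 2)
  expect_equal(average_lifetime(mk(rep(4.5, 7))), 4.5)
  set.seed(3)
  lt <- runif(15, 0, 9)
  expect_equal(average_lifetime(mk(c(lt, Inf))), mean(lt))
})

test_that("cycle rank of trees, loops and multi-loop phantoms", {
  nodes <- data.frame(id = 1:3, x = c(0, 10, 20), y = 0, z = 0,
                      degree = c(1, 2, 1))
  paths <- list(rbind(c(0, 0, 0), c(10, 0, 0)),
                rbind(c(10, 0, 0), c(20, 0, 0)))
  tree <- vessel_graph(nodes,
                       data.frame(id = 1:2, from = c(1, 2), to = c(2, 3),
                                  length_um = 10, mean_radius_um = 1),
                       paths)
  expect_equal(cycle_rank(tree), 0L)

  loop <- vessel_graph(nodes[1:2, ],
                       data.frame(id = 1:2, from = c(1, 1), to = c(2, 2),
                                  length_um = 10, mean_radius_um = 1),
                       paths)
  expect_equal(cycle_rank(loop), 1L)

  spec <- vessel_phantom_spec(shape = c(96, 96, 96), n_trees = 1,
                              n_branches_per_tree = 14,
                              n_extra_loops = 7, seed = 30)
  ph <- generate_vessel_phantom(spec)
  expect_equal(cycle_rank(ph$truth$graph), 7L)
})

test_that("small coordinate jitter moves lifetimes by at most 2 epsilon", {
  pts <- circle_points(10, 25)
  eps <- 0.01
  set.seed(8)
  jit <- pts + matrix(runif(length(pts), -eps / 2, eps / 2), ncol = 3)
  d0 <- rips_persistence(pts, max_edge_um = 100)
  d1 <- rips_persistence(jit, max_edge_um = 100)
  l0 <- d0[d0$dimension == 1, ]
  l1 <- d1[d1$dimension == 1, ]
  expect_equal(nrow(l0), nrow(l1))
  expect_lt(abs((l0$death - l0$birth) - (l1$death - l1$birth)), 2 * eps)
})

test_that("full pipeline recovers loop counts within one", {
  for (k in c(0, 3)) {
    ph <- generate_loop_phantom(k, seed = 40 + k, jitter_um = 0.5)
    sk <- skeletonize(ph$truth$mask)
    g <- prune_graph(extract_graph(sk, ph$truth$mask), 5)
    tp <- topology_report(g)
    expect_equal(tp$cycle_rank, k)
    expect_lte(abs(tp$betti1_filtered - k), 1)
  }
})
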