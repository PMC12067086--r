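#' Specify a synthetic vessel-network phantom
#'
#' Defines the geometry, contrast and noise of a tubular vessel phantom
#' embedded in autofluorescent background. Branches are grown as gently
#' curved tubes from one or more trees; anastomoses (loops) can be added
#' with exact cycle-count bookkeeping, so Betti-1 ground truth is known by
#' construction.
#'
#' @param shape integer length-3 voxel counts, each >= 32.
#' @param spacing_um voxel spacing in um (anisotropy allowed).
#' @param n_trees number of independent vessel trees.
#' @param branch_length_range_um interval for branch lengths (um).
#' @param radius_range_um interval for branch radii (um); the minimum must be
#'   at least one voxel spacing so tubes rasterize contiguously.
#' @param n_extra_loops anastomoses added after tree growth; each adds
#'   exactly one independent cycle.
#' @param noise_sd additive Gaussian noise (intensity units), clipped at 0.
#' @param background_level baseline tissue intensity.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @param n_branches_per_tree branches grown per tree.
#' @param vessel_intensity peak tube intensity above background.
#' @param cluster_fraction in (0, 1]; values below 1 confine each tree to a
#'   random sub-box holding this fraction of the volume, producing spatially
#'   patchy (heterogeneous) vasculature at unchanged branch statistics.
#' @param curvature relative mid-branch bulge (0 gives straight branches).
#' @return the validated spec as a `vessel_phantom_spec` list.
#' @export
vessel_phantom_spec <- function(shape = c(64, 64, 64),
                                spacing_um = c(1, 1, 1),
                                n_trees = 2,
                                branch_length_range_um = c(20, 50),
                                radius_range_um = c(2.5, 4),
                                n_extra_loops = 0,
                                noise_sd = 0,
                                background_level = 10,
                                seed = 1,
                                n_branches_per_tree = 12,
                                vessel_intensity = 150,
                                cluster_fraction = 1,
                                curvature = 0.15) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("shape must be 3 voxel counts, each >= 32")
  .check_spacing(spacing_um)
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (n_branches_per_tree < 1) stop("n_branches_per_tree must be >= 1")
  if (length(branch_length_range_um) != 2L ||
      any(branch_length_range_um <= 0) ||
      diff(branch_length_range_um) < 0)
    stop("branch_length_range_um must be a positive increasing interval")
  if (length(radius_range_um) != 2L || diff(radius_range_um) < 0)
    stop("radius_range_um must be an increasing interval")
  if (radius_range_um[1] < max(spacing_um))
    stop("minimum radius must be >= one voxel spacing (",
         max(spacing_um), " um)")
  if (n_extra_loops < 0) stop("n_extra_loops must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (cluster_fraction <= 0 || cluster_fraction > 1)
    stop("cluster_fraction must be in (0, 1]")
  structure(list(shape = shape, spacing_um = as.numeric(spacing_um),
                 n_trees = as.integer(n_trees),
                 branch_length_range_um = as.numeric(branch_length_range_um),
                 radius_range_um = as.numeric(radius_range_um),
                 n_extra_loops = as.integer(n_extra_loops),
                 noise_sd = noise_sd, background_level = background_level,
                 seed = as.integer(seed),
                 n_branches_per_tree = as.integer(n_branches_per_tree),
                 vessel_intensity = vessel_intensity,
                 cluster_fraction = cluster_fraction,
                 curvature = curvature),
            class = "vessel_phantom_spec")
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

.rand_unit <- function() .unit(c(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1)))

# quadratic bezier from p0 to p1 bulging sideways, sampled at <= step um;
# perp (unit, orthogonal to the chord) picks the bulge plane
.bezier_path <- function(p0, p1, bulge_um, step, perp = NULL) {
  chord <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(chord / step) + 1L)
  t <- seq(0, 1, length.out = n)
  if (bulge_um <= 0) {
    pts <- outer(1 - t, p0) + outer(t, p1)
    return(pts)
  }
  d <- .unit(p1 - p0)
  if (is.null(perp)) {
    ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- .unit(pracma_cross(d, ref))
  }
  ctrl <- (p0 + p1) / 2 + perp * bulge_um
  outer((1 - t)^2, p0) + outer(2 * t * (1 - t), ctrl) + outer(t^2, p1)
}

# minimal cross product (avoids pulling in pracma for one line)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a vessel phantom with known ground truth
#'
#' Grows the vessel network specified by `spec`, rasterizes it as tubes of
#' Gaussian cross-section over a uniform background, and returns both the
#' image stack and the exact ground truth (graph, mask, loop count). A voxel
#' belongs to the truth mask when its centre lies within the branch radius
#' of the centerline, measured in um with anisotropic spacing honoured. The
#' intensity profile is Gaussian with its half-maximum at the tube wall
#' (FWHM equals the vessel diameter), the usual operational definition of a
#' vessel radius in fluorescence imaging.
#'
#' @param spec a [vessel_phantom_spec()].
#' @return list with elements `stack` (a [volume_image()]) and `truth`
#'   (a `phantom_truth`: `graph`, `mask`, `loop_count`, `cyst_volumes_um3`,
#'   `tissue_volume_um3`).
#' @export
generate_vessel_phantom <- function(spec) {
  if (!inherits(spec, "vessel_phantom_spec"))
    spec <- do.call(vessel_phantom_spec, spec)
  .with_seed(spec$seed, .generate_vessel_phantom_impl(spec))
}

.generate_vessel_phantom_impl <- function(spec) {
  shape <- spec$shape
  sp <- spec$spacing_um
  extent <- (shape - 1) * sp
  lr <- spec$branch_length_range_um
  rr <- spec$radius_range_um
  margin <- rr[2] + 2 * max(sp)
  lo_full <- rep(margin, 3)
  hi_full <- extent - margin
  if (any(hi_full <= lo_full))
    stop("volume too small for the requested radii")

  nodes <- list()       # coords
  node_tree <- integer(0)
  edges <- list()       # list(from, to, radius, path)

  add_node <- function(p, tree) {
    nodes[[length(nodes) + 1]] <<- p
    node_tree[length(nodes)] <<- tree
    length(nodes)
  }

  step <- min(sp) / 2

  # occupancy of already-placed centerlines, for collision-aware growth.
  # Tubes may only touch other tubes near a shared node (the junction
  # blob), so the rasterized mask has exactly the cycles the graph has.
  occ_pts <- matrix(numeric(0), ncol = 3)
  occ_r <- numeric(0)
  occ_edge <- integer(0)
  occ_tree <- integer(0)
  # gap between tube surfaces must beat the 26-neighbourhood diagonal or
  # rasterized tubes bridge through voxel corners (plus subsampling slack);
  # distinct trees keep extra distance so downstream morphological cleanup
  # (closing, dilate/erode) cannot fuse them either
  clearance <- 2 * max(sp) + min(sp)
  clearance_tree <- clearance + 4 * max(sp)
  path_clear <- function(path, r, node_ids, tree_id) {
    if (nrow(occ_pts) == 0) return(TRUE)
    inc_edges <- which(vapply(edges, function(e)
      e$from %in% node_ids || e$to %in% node_ids, logical(1)))
    node_xyz <- do.call(rbind, nodes[node_ids])
    clr <- ifelse(occ_tree == tree_id, clearance, clearance_tree)
    idx <- unique(c(seq(1, nrow(path), by = 2), nrow(path)))
    for (i in idx) {
      p <- path[i, ]
      dd <- sqrt(rowSums(sweep(occ_pts, 2, p)^2))
      hit <- which(dd <= occ_r + r + clr)
      if (length(hit) == 0) next
      for (j in hit) {
        ok <- FALSE
        if (occ_edge[j] %in% inc_edges) {
          # contacts are only legitimate inside the junction blob, i.e.
          # within roughly the sum of the two radii of the shared node
          zone <- 1.5 * (r + occ_r[j]) + max(sp)
          for (ni in seq_len(nrow(node_xyz))) {
            nz <- node_xyz[ni, ]
            if (sqrt(sum((p - nz)^2)) < zone &&
                sqrt(sum((occ_pts[j, ] - nz)^2)) < zone) {
              ok <- TRUE
              break
            }
          }
        }
        if (!ok) return(FALSE)
      }
    }
    TRUE
  }
  occ_add <- function(path, r, edge_id, tree_id) {
    idx <- unique(c(seq(1, nrow(path), by = 2), nrow(path)))
    occ_pts <<- rbind(occ_pts, path[idx, , drop = FALSE])
    occ_r <<- c(occ_r, rep(r, length(idx)))
    occ_edge <<- c(occ_edge, rep(edge_id, length(idx)))
    occ_tree <<- c(occ_tree, rep(tree_id, length(idx)))
  }

  for (tree in seq_len(spec$n_trees)) {
    lo <- lo_full; hi <- hi_full
    if (spec$cluster_fraction < 1) {
      side <- (hi - lo) * spec$cluster_fraction^(1 / 3)
      orig <- lo + runif(3) * (hi - lo - side)
      lo <- orig; hi <- orig + side
    }
    made <- 0L
    for (root_try in 1:8) {            # re-root if the position is hopeless
      root <- lo + runif(3) * (hi - lo)
      root_id <- add_node(root, tree)
      tips <- list(list(node = root_id, dir = .rand_unit()))
      reseeds <- 0L
      while (made < spec$n_branches_per_tree) {
      if (length(tips) == 0) {
        # all tips crowded out: restart growth from a random existing node
        if (reseeds >= 20L) break
        reseeds <- reseeds + 1L
        ids <- which(node_tree == tree)
        tips <- list(list(node = ids[sample.int(length(ids), 1)],
                          dir = .rand_unit()))
      }
      ti <- if (length(tips) == 1) 1L else sample.int(length(tips), 1)
      tip <- tips[[ti]]
      tips[[ti]] <- NULL
      nchild <- if (made == 0L) 1L else sample(c(1L, 2L), 1, prob = c(0.35, 0.65))
      for (ch in seq_len(nchild)) {
        if (made >= spec$n_branches_per_tree) break
        L <- runif(1, lr[1], lr[2])
        radius <- runif(1, rr[1], rr[2])
        p0 <- nodes[[tip$node]]
        placed <- NULL
        axis_dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
        for (try in 1:46) {
          # last resort in narrow volumes: the six axis directions
          d <- if (try <= 40) .unit(tip$dir * 0.8 + .rand_unit() * 0.8)
               else axis_dirs[[try - 40]]
          cand <- p0 + L * d
          if (!all(cand >= lo) || !all(cand <= hi)) next
          path <- .bezier_path(p0, cand, spec$curvature * L, step)
          if (!path_clear(path, radius, tip$node, tree)) next
          placed <- list(p1 = cand, path = path)
          break
        }
        if (is.null(placed)) next     # crowded tip: give up on this child
        nid <- add_node(placed$p1, tree)
        edges[[length(edges) + 1]] <- list(from = tip$node, to = nid,
                                           radius = radius,
                                           path = placed$path)
        occ_add(placed$path, radius, length(edges), tree)
        made <- made + 1L
        tips[[length(tips) + 1]] <- list(node = nid,
                                         dir = .unit(placed$p1 - p0))
      }
      }
      if (made > 0L) break     # this root took; reseeding already retried
    }
  }

  # drop roots that never grew a branch
  if (length(edges) > 0) {
    used <- sort(unique(unlist(lapply(edges, function(e) c(e$from, e$to)))))
    if (length(used) < length(nodes)) {
      remap <- integer(length(nodes))
      remap[used] <- seq_along(used)
      nodes <- nodes[used]
      node_tree <- node_tree[used]
      for (i in seq_along(edges)) {
        edges[[i]]$from <- remap[edges[[i]]$from]
        edges[[i]]$to <- remap[edges[[i]]$to]
      }
    }
  } else stop("phantom generation placed no branches")

  # anastomoses: connect two existing nodes of the same tree by a new arc;
  # each connection closes exactly one independent cycle
  if (spec$n_extra_loops > 0) {
    adj <- lapply(seq_along(nodes), function(i) integer(0))
    for (e in edges) {
      adj[[e$from]] <- c(adj[[e$from]], e$to)
      adj[[e$to]] <- c(adj[[e$to]], e$from)
    }
    hop_dist <- function(a, b) {   # BFS hops in the current graph
      dist <- rep(NA_integer_, length(nodes))
      dist[a] <- 0L
      q <- a
      while (length(q) > 0) {
        cur <- q[1]; q <- q[-1]
        for (nb in adj[[cur]]) if (is.na(dist[nb])) {
          dist[nb] <- dist[cur] + 1L
          if (nb == b) return(dist[nb])
          q <- c(q, nb)
        }
      }
      dist[b]
    }
    coords <- do.call(rbind, nodes)
    for (l in seq_len(spec$n_extra_loops)) {
      placed <- FALSE
      for (try in 1:900) {
        tree <- sample.int(spec$n_trees, 1)
        ids <- which(node_tree == tree)
        if (length(ids) < 4) next
        ab <- sample(ids, 2)
        a <- ab[1]; b <- ab[2]
        if (b %in% adj[[a]]) next
        eu <- sqrt(sum((coords[a, ] - coords[b, ])^2))
        eu_hi <- if (try <= 600) 2.2 * lr[2] else 3 * lr[2]
        if (eu < 0.4 * lr[1] || eu > eu_hi) next
        h <- hop_dist(a, b)
        if (is.na(h) || h < 2) next
        if (try <= 300 && h < 3) next   # prefer loops sampled by >= 4 nodes
        p0 <- coords[a, ]; p1 <- coords[b, ]
        radius <- runif(1, rr[1], rr[2])
        d <- .unit(p1 - p0)
        rv <- .rand_unit()
        perp <- .unit(rv - sum(rv * d) * d)
        path <- .bezier_path(p0, p1, runif(1, 0.25, 0.5) * eu, step, perp)
        if (any(apply(path, 1, function(p) any(p < lo_full - margin / 2) ||
                        any(p > hi_full + margin / 2)))) next
        if (!path_clear(path, radius, c(a, b), tree)) next
        edges[[length(edges) + 1]] <- list(from = a, to = b,
                                           radius = radius,
                                           path = path)
        occ_add(path, radius, length(edges), tree)
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place anastomosis ", l,
             ": trees too small for the requested loop count")
    }
  }

  coords <- do.call(rbind, nodes)
  deg <- integer(nrow(coords))
  for (e in edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L
  }
  branches <- data.frame(
    id = seq_along(edges),
    from = vapply(edges, function(e) e$from, integer(1)),
    to = vapply(edges, function(e) e$to, integer(1)),
    length_um = vapply(edges, function(e) .polyline_length(e$path), numeric(1)),
    mean_radius_um = vapply(edges, function(e) e$radius, numeric(1))
  )
  graph <- vessel_graph(
    nodes = data.frame(id = seq_len(nrow(coords)), x = coords[, 1],
                       y = coords[, 2], z = coords[, 3], degree = deg),
    branches = branches,
    paths = lapply(edges, function(e) e$path),
    spacing_um = sp
  )
  # single-child extensions leave degree-2 nodes; merge them so the truth
  # graph satisfies the branch-endpoint invariant (degree != 2)
  graph <- prune_graph(graph, 0)

  # rasterize: dn = min over branches of (distance to centerline / radius)
  dn <- array(Inf, dim = shape)
  for (e in edges) {
    dn <- array(cpp_stamp_tube(as.numeric(dn), shape, sp, e$path,
                               e$radius, 1.8), dim = shape)
  }
  mask <- binary_mask(dn <= 1, sp)
  profile <- exp(-log(2) * dn^2)     # half maximum exactly at the wall
  profile[!is.finite(dn)] <- 0
  img <- spec$background_level + spec$vessel_intensity * profile
  if (spec$noise_sd > 0)
    img <- img + rnorm(length(img), 0, spec$noise_sd)
  img <- pmax(img, 0)
  stack <- volume_image(array(img, dim = shape), sp)

  truth <- structure(list(graph = graph, mask = mask,
                          loop_count = spec$n_extra_loops,
                          cyst_volumes_um3 = numeric(0),
                          tissue_volume_um3 = prod(shape) * prod(sp)),
                     class = "phantom_truth")
  stopifnot(cycle_rank(graph) == truth$loop_count)
  list(stack = stack, truth = truth)
}

#' Generate a loop-count validation phantom
#'
#' Builds a vessel network with exactly `n_loops` independent cycles of
#' controlled geometry: a straight backbone vessel with `n_loops` circular
#' ring anastomoses attached laterally (alternating directions), each ring
#' carrying `n_ring_nodes` junctions with short outward side twigs so its
#' hole is sampled by well-separated branch endpoints. Unlike the random
#' trees of [generate_vessel_phantom()], every hole here has a known size
#' (`ring_radius_um`), which makes the phantom suitable for validating
#' loop detection (Betti 1) through the full image pipeline.
#'
#' @param n_loops number of ring anastomoses (>= 0).
#' @param spacing_um voxel spacing in um.
#' @param radius_um tube radius (um).
#' @param ring_radius_um ring (hole) radius in um.
#' @param n_ring_nodes junctions per ring (>= 4).
#' @param twig_length_um side-twig length (um); must exceed any graph
#'   pruning threshold used downstream or ring junctions dissolve.
#' @param seed RNG seed (used only when `jitter_um > 0`).
#' @param jitter_um Gaussian positional jitter applied to all nodes.
#' @param noise_sd,background_level,vessel_intensity intensity model as in
#'   [generate_vessel_phantom()].
#' @return list with `stack` and `truth` as in [generate_vessel_phantom()].
#' @export
generate_loop_phantom <- function(n_loops, spacing_um = c(1, 1, 1),
                                  radius_um = 2.5, ring_radius_um = 20,
                                  n_ring_nodes = 8, twig_length_um = 10,
                                  seed = 1, jitter_um = 0, noise_sd = 0,
                                  background_level = 10,
                                  vessel_intensity = 150) {
  if (n_loops < 0) stop("n_loops must be >= 0")
  if (n_ring_nodes < 4) stop("n_ring_nodes must be >= 4")
  .check_spacing(spacing_um)
  sp <- as.numeric(spacing_um)
  R <- ring_radius_um
  sep <- 26
  offset <- 12                      # backbone-to-ring connector length
  lat <- offset + 2 * R + twig_length_um
  x_end <- 30 + sep * (max(n_loops, 1) + 1) + 30
  cy <- lat + 10                    # lateral centre
  shape <- ceiling(c(x_end, 2 * cy, 2 * cy) / sp)
  step <- min(sp) / 2

  nodes <- list()
  edges <- list()
  add_node <- function(p) { nodes[[length(nodes) + 1]] <<- p; length(nodes) }
  add_edge <- function(from, to, path) {
    edges[[length(edges) + 1]] <<- list(from = from, to = to,
                                        radius = radius_um, path = path)
  }
  seg <- function(p0, p1) .bezier_path(p0, p1, 0, step)

  centre_yz <- c(cy, cy)
  bb_x <- c(25, x_end - 25)
  n_prev <- add_node(c(bb_x[1], centre_yz))
  dirs <- list(c(0, 1, 0), c(0, 0, 1), c(0, -1, 0), c(0, 0, -1))
  .with_seed(seed, {
    jit <- function(p) if (jitter_um > 0) p + rnorm(3, 0, jitter_um) else p
    for (i in seq_len(n_loops)) {
      xa <- 30 + sep * i
      attach_node <- add_node(jit(c(xa, centre_yz)))
      add_edge(n_prev, attach_node,
               seg(nodes[[n_prev]], nodes[[attach_node]]))
      n_prev <- attach_node
      dirv <- dirs[[(i - 1) %% 4 + 1]]
      ring_centre <- nodes[[attach_node]] + dirv * (offset + R)
      # ring plane spanned by the x axis and the lateral direction
      e1 <- c(1, 0, 0)
      e2 <- dirv
      ang <- seq(0, 2 * pi, length.out = n_ring_nodes + 1)[-(n_ring_nodes + 1)]
      ang <- ang + pi / 2          # node 1 sits nearest the backbone
      # place node 1 nearest the backbone: angle where point = centre - e2*R
      ring_pts <- lapply(ang, function(a)
        jit(ring_centre + cos(a) * e1 * R - sin(a) * e2 * R))
      ring_ids <- vapply(ring_pts, add_node, integer(1))
      add_edge(attach_node, ring_ids[1],
               seg(nodes[[attach_node]], nodes[[ring_ids[1]]]))
      for (j in seq_len(n_ring_nodes)) {
        j2 <- if (j == n_ring_nodes) 1L else j + 1L
        a0 <- ang[j]; a1 <- if (j == n_ring_nodes) ang[1] + 2 * pi else ang[j2]
        tt <- seq(a0, a1, length.out = max(3, ceiling(R * (a1 - a0) / step)))
        arc <- t(vapply(tt, function(a)
          ring_centre + cos(a) * e1 * R - sin(a) * e2 * R, numeric(3)))
        arc[1, ] <- nodes[[ring_ids[j]]]
        arc[nrow(arc), ] <- nodes[[ring_ids[j2]]]
        add_edge(ring_ids[j], ring_ids[j2], arc)
        if (j > 1) {     # outward twig keeps the junction alive downstream
          out_dir <- .unit(nodes[[ring_ids[j]]] - ring_centre)
          tip <- add_node(jit(nodes[[ring_ids[j]]] + out_dir * twig_length_um))
          add_edge(ring_ids[j], tip, seg(nodes[[ring_ids[j]]], nodes[[tip]]))
        }
      }
    }
    # trailing backbone segment and clutter twigs on the backbone
    end_node <- add_node(c(bb_x[2], centre_yz))
    add_edge(n_prev, end_node, seg(nodes[[n_prev]], nodes[[end_node]]))
    nmid <- max(n_loops, 2)
    for (i in seq_len(nmid)) {
      xa <- 30 + sep * (i - 0.5)
      if (xa > bb_x[2] - 10) break
      dirv <- .unit(c(0, 1, -1)) * (if (i %% 2 == 0) 1 else -1)
      base <- add_node(jit(c(xa, centre_yz)))
      tip <- add_node(jit(c(xa, centre_yz) + dirv * twig_length_um))
      add_edge(base, tip, seg(nodes[[base]], nodes[[tip]]))
    }
    coords <- do.call(rbind, nodes)
    deg <- integer(nrow(coords))
    for (e in edges) {
      deg[e$from] <- deg[e$from] + 1L
      deg[e$to] <- deg[e$to] + 1L
    }
    branches <- data.frame(
      id = seq_along(edges),
      from = vapply(edges, function(e) e$from, integer(1)),
      to = vapply(edges, function(e) e$to, integer(1)),
      length_um = vapply(edges, function(e) .polyline_length(e$path),
                         numeric(1)),
      mean_radius_um = vapply(edges, function(e) e$radius, numeric(1)))
    graph <- vessel_graph(
      data.frame(id = seq_len(nrow(coords)), x = coords[, 1],
                 y = coords[, 2], z = coords[, 3], degree = deg),
      branches, lapply(edges, function(e) e$path), sp)

    dn <- array(Inf, dim = shape)
    for (e in edges)
      dn <- array(cpp_stamp_tube(as.numeric(dn), shape, sp, e$path,
                                 e$radius, 1.8), dim = shape)
    mask <- binary_mask(dn <= 1, sp)
    profile <- exp(-log(2) * dn^2)
    profile[!is.finite(dn)] <- 0
    img <- background_level + vessel_intensity * profile
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    stack <- volume_image(array(pmax(img, 0), dim = shape), sp)
    truth <- structure(list(graph = graph, mask = mask,
                            loop_count = as.integer(n_loops),
                            cyst_volumes_um3 = numeric(0),
                            tissue_volume_um3 = prod(shape) * prod(sp)),
                       class = "phantom_truth")
    list(stack = stack, truth = truth)
  })
}

#' Delete vessel branches in a spatial patch or at random
#'
#' Removes exactly `n_delete` branches from a vessel graph, either the
#' ones nearest a randomly chosen patch centre (`"patch"`: spatially
#' coherent loss, emulating focal microvascular rarefaction) or a uniform
#' random subset (`"random"`: the density-matched control). Both modes
#' remove the same number of branches, so groups built this way differ
#' only in the spatial pattern of the loss. Degree-2 chains left behind
#' are merged to restore the branch-endpoint invariant.
#'
#' @param graph a [vessel_graph()].
#' @param n_delete number of branches to remove (>= 1, < branch count).
#' @param mode `"patch"` or `"random"`.
#' @param seed RNG seed for the patch centre / subset choice.
#' @return the reduced [vessel_graph()].
#' @export
delete_branches <- function(graph, n_delete, mode = c("patch", "random"),
                            seed = 1) {
  mode <- match.arg(mode)
  br <- graph$branches
  if (n_delete < 1 || n_delete >= nrow(br))
    stop("n_delete must be in [1, branch count)")
  .with_seed(seed, {
    drop <- if (mode == "patch") {
      mids <- t(vapply(graph$paths, function(p)
        p[ceiling(nrow(p) / 2), ], numeric(3)))
      ctr <- mids[sample.int(nrow(mids), 1), ]
      d <- sqrt(rowSums(sweep(mids, 2, ctr)^2))
      order(d)[seq_len(n_delete)]
    } else {
      sample.int(nrow(br), n_delete)
    }
    drop_branches(graph, drop)
  })
}

#' Remove specific branches from a vessel graph
#'
#' Drops the branches with the given ids, removes nodes that become
#' isolated, and merges any degree-2 chains the removal leaves behind.
#' Building block for custom ablation experiments (see
#' [delete_branches()] for patch/random deletion).
#'
#' @param graph a [vessel_graph()].
#' @param ids integer branch ids to remove.
#' @return the reduced [vessel_graph()].
#' @export
drop_branches <- function(graph, ids) {
  br <- graph$branches
  if (length(ids) == 0) return(graph)
  if (any(!ids %in% seq_len(nrow(br)))) stop("invalid branch ids")
  if (length(ids) >= nrow(br)) stop("cannot drop every branch")
  br <- br[-ids, , drop = FALSE]
  paths <- graph$paths[-ids]
  keep <- sort(unique(c(br$from, br$to)))
  remap <- setNames(seq_along(keep), keep)
  br$from <- unname(remap[as.character(br$from)])
  br$to <- unname(remap[as.character(br$to)])
  nodes <- graph$nodes[graph$nodes$id %in% keep, , drop = FALSE]
  nodes$id <- unname(remap[as.character(nodes$id)])
  nodes$degree <- tabulate(c(br$from, br$to), nbins = length(keep))
  br$id <- seq_len(nrow(br))
  rownames(br) <- NULL; rownames(nodes) <- NULL
  prune_graph(vessel_graph(nodes, br, paths, attr(graph, "spacing_um")), 0)
}

#' Render a vessel graph as an image stack and mask
#'
#' Rasterizes every branch as a tube of its recorded radius with the same
#' Gaussian cross-section intensity model as [generate_vessel_phantom()],
#' over a uniform background with optional Gaussian noise. Used to turn
#' manipulated graphs (for example after [delete_branches()]) back into
#' phantoms the imaging pipeline can consume.
#'
#' @param graph a [vessel_graph()] with per-branch `mean_radius_um`.
#' @param shape voxel counts (length 3).
#' @param spacing_um voxel spacing; defaults to the graph's.
#' @param background_level,vessel_intensity,noise_sd intensity model.
#' @param seed RNG seed for the noise.
#' @return list with `stack` ([volume_image()]) and `mask`
#'   ([binary_mask()]).
#' @export
rasterize_vessel_graph <- function(graph, shape,
                                   spacing_um = attr(graph, "spacing_um"),
                                   background_level = 10,
                                   vessel_intensity = 150,
                                   noise_sd = 0, seed = 1) {
  shape <- as.integer(shape)
  .check_spacing(spacing_um)
  dn <- array(Inf, dim = shape)
  for (b in seq_len(nrow(graph$branches))) {
    dn <- array(cpp_stamp_tube(as.numeric(dn), shape,
                               as.numeric(spacing_um), graph$paths[[b]],
                               graph$branches$mean_radius_um[b], 1.8),
                dim = shape)
  }
  mask <- binary_mask(dn <= 1, spacing_um)
  profile <- exp(-log(2) * dn^2)
  profile[!is.finite(dn)] <- 0
  img <- background_level + vessel_intensity * profile
  if (noise_sd > 0)
    img <- .with_seed(seed, img + rnorm(length(img), 0, noise_sd))
  list(stack = volume_image(array(pmax(img, 0), dim = shape), spacing_um),
       mask = mask)
}

#' Generate a cyst phantom: dark ellipsoidal holes in bright parenchyma
#'
#' Places non-overlapping spherical cysts (ellipsoids in voxel space when
#' spacing is anisotropic) inside a bright ellipsoidal tissue envelope,
#' rendering them as dark holes, which emulates autofluorescence stacks
#' where cyst lumens are signal voids. Truth volumes are the rasterized
#' voxel counts times the voxel volume.
#'
#' @param shape voxel counts (length 3).
#' @param spacing_um voxel spacing in um.
#' @param cyst_radii_um numeric vector of cyst radii (um); may be empty.
#' @param seed RNG seed.
#' @param parenchyma_level,background_level,noise_sd intensity model.
#' @param max_tries placement retries per cyst before giving up.
#' @return list with `stack` (a [volume_image()]) and `truth`
#'   (`phantom_truth` whose `mask` is the cyst mask and which also carries
#'   `envelope_mask`).
#' @export
generate_cyst_phantom <- function(shape, spacing_um = c(1, 1, 1),
                                  cyst_radii_um = numeric(0), seed = 1,
                                  parenchyma_level = 150,
                                  background_level = 10,
                                  noise_sd = 0, max_tries = 300) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) stop("shape too small")
  .check_spacing(spacing_um)
  if (any(cyst_radii_um <= 0)) stop("cyst radii must be positive")
  .with_seed(seed, {
    sp <- as.numeric(spacing_um)
    extent <- (shape - 1) * sp
    centre <- extent / 2
    semi <- 0.45 * extent
    ax <- (seq_len(shape[1]) - 1) * sp[1]
    ay <- (seq_len(shape[2]) - 1) * sp[2]
    az <- (seq_len(shape[3]) - 1) * sp[3]
    X <- array(rep(ax, times = shape[2] * shape[3]), dim = shape)
    Y <- array(rep(rep(ay, each = shape[1]), times = shape[3]), dim = shape)
    Z <- array(rep(az, each = shape[1] * shape[2]), dim = shape)
    env <- ((X - centre[1]) / semi[1])^2 + ((Y - centre[2]) / semi[2])^2 +
      ((Z - centre[3]) / semi[3])^2 <= 1

    centres <- matrix(numeric(0), ncol = 3)
    placed_radii <- numeric(0)
    radii <- sort(cyst_radii_um, decreasing = TRUE)  # big first: easier packing
    for (r in radii) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        u <- .rand_unit() * runif(1)^(1 / 3)
        cand <- centre + u * pmax(semi - r - 2 * max(sp), 0)
        cand <- round(cand / sp) * sp   # snap to the voxel grid so equal
                                        # radii rasterize identically
        ok <- TRUE
        if (nrow(centres) > 0) {
          dd <- sqrt(rowSums(sweep(centres, 2, cand)^2))
          if (any(dd <= placed_radii + r + max(sp))) ok <- FALSE
        }
        if (ok) {
          centres <- rbind(centres, cand)
          placed_radii <- c(placed_radii, r)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place a cyst of radius ", r,
             " um without overlap after ", max_tries, " tries")
    }

    cysts <- array(FALSE, dim = shape)
    vols <- numeric(nrow(centres))
    for (i in seq_len(nrow(centres))) {
      r <- placed_radii[i]
      cc <- centres[i, ]
      b <- (X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2 <= r^2
      vols[i] <- sum(b) * prod(sp)
      cysts <- cysts | b
    }

    img <- array(background_level, dim = shape)
    img[env & !cysts] <- parenchyma_level
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    img <- pmax(img, 0)
    truth <- structure(list(graph = NULL,
                            mask = binary_mask(cysts, sp),
                            loop_count = 0L,
                            cyst_volumes_um3 = vols,
                            tissue_volume_um3 = sum(env) * prod(sp),
                            envelope_mask = binary_mask(env, sp)),
                       class = "phantom_truth")
    list(stack = volume_image(array(img, dim = shape), sp), truth = truth)
  })
}

#' Simulate a FAIR-ASL acquisition
#'
#' Forward-simulates the signals consumed by the ASL quantification module:
#' a multi-TI non-selective inversion-recovery series following
#' `M_C(TI) = M0 (1 - 2^(-TI/T1))`, and paired control (non-selective) /
#' label (slice-selective) repeats at the labelling TI where the label
#' signal carries the perfusion-weighted difference dM implied by inverting
#' the kinetic model at the requested renal blood flow. Gaussian noise is
#' added independently per repeat and per TI.
#'
#' @param M0_map,T1_map,rbf_map numeric arrays of identical shape:
#'   equilibrium magnetization, longitudinal relaxation time (ms) and true
#'   renal blood flow (ml/min/100 g).
#' @param TI_list_ms positive increasing inversion times (ms).
#' @param noise_sd Gaussian noise sd (signal units).
#' @param seed RNG seed.
#' @param lambda_partition blood-tissue partition coefficient (ml/g).
#' @param TI_label_ms labelling inversion time (ms).
#' @param n_repeats number of control/label repeats.
#' @return an `asl_series` list: `control_repeats`, `label_repeats`
#'   (shape x repeats), `multiTI_signals` (shape x TI), `TI_list_ms`,
#'   `TI_label_ms`, `lambda_partition`, and the simulation `truth`.
#' @export
generate_asl_series <- function(M0_map, T1_map, rbf_map, TI_list_ms,
                                noise_sd = 0, seed = 1,
                                lambda_partition = 0.9,
                                TI_label_ms = 2000, n_repeats = 10) {
  M0 <- as.array(M0_map); T1 <- as.array(T1_map); rbf <- as.array(rbf_map)
  if (!identical(dim(M0), dim(T1)) || !identical(dim(M0), dim(rbf)))
    stop("M0_map, T1_map and rbf_map must share a shape")
  if (any(!is.finite(M0)) || any(M0 <= 0)) stop("M0 must be positive everywhere")
  if (any(!is.finite(T1)) || any(T1 <= 0)) stop("T1 must be positive everywhere")
  if (length(TI_list_ms) == 0 || any(TI_list_ms <= 0) ||
      is.unsorted(TI_list_ms, strictly = TRUE))
    stop("TI_list_ms must be nonempty, positive and strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  .with_seed(seed, {
    shp <- dim(M0)
    nvox <- length(M0)
    nTI <- length(TI_list_ms)
    multi <- array(0, dim = c(shp, nTI))
    for (k in seq_len(nTI)) {
      s <- ir_signal(M0, T1, TI_list_ms[k])
      if (noise_sd > 0) s <- s + rnorm(nvox, 0, noise_sd)
      multi[seq_len(nvox) + (k - 1) * nvox] <- s
    }
    mc <- ir_signal(M0, T1, TI_label_ms)
    dm <- dm_from_rbf(rbf, M0, T1, TI_label_ms, lambda_partition)
    ctrl <- array(0, dim = c(shp, n_repeats))
    lab <- array(0, dim = c(shp, n_repeats))
    for (r in seq_len(n_repeats)) {
      cs <- mc
      ls <- mc + dm
      if (noise_sd > 0) {
        cs <- cs + rnorm(nvox, 0, noise_sd)
        ls <- ls + rnorm(nvox, 0, noise_sd)
      }
      ctrl[seq_len(nvox) + (r - 1) * nvox] <- cs
      lab[seq_len(nvox) + (r - 1) * nvox] <- ls
    }
    structure(list(control_repeats = ctrl, label_repeats = lab,
                   multiTI_signals = multi,
                   TI_list_ms = as.numeric(TI_list_ms),
                   TI_label_ms = TI_label_ms,
                   lambda_partition = lambda_partition,
                   truth = list(M0 = M0, T1_ms = T1, rbf = rbf, dM = dm)),
              class = "asl_series")
  })
}
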