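#' Construct a vessel graph object
#'
#' A spatial graph of a vascular network: nodes are junctions and endpoints
#' (degree != 2), branches are maximal junction-free centerline paths with
#' physical length and mean radius in um.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (um), `degree`.
#' @param branches data.frame with columns `id`, `from`, `to`, `length_um`,
#'   `mean_radius_um`.
#' @param paths list of n-by-3 matrices of centerline points (um), one per
#'   branch, ordered from `from` to `to`.
#' @param spacing_um voxel spacing of the source volume.
#' @return a `vessel_graph`.
#' @export
vessel_graph <- function(nodes, branches, paths, spacing_um = c(1, 1, 1)) {
  stopifnot(is.data.frame(nodes), is.data.frame(branches),
            length(paths) == nrow(branches))
  if (any(branches$mean_radius_um < 0)) stop("radii must be >= 0")
  structure(list(nodes = nodes, branches = branches, paths = paths),
            spacing_um = as.numeric(spacing_um), class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes, %d branches, total length %.1f um, cycle rank %d\n",
              nrow(x$nodes), nrow(x$branches),
              sum(x$branches$length_um), cycle_rank(x)))
  invisible(x)
}

# igraph view of the branch-level multigraph
.as_igraph <- function(graph) {
  el <- cbind(graph$branches$from, graph$branches$to)
  igraph::graph_from_edgelist(matrix(as.character(el), ncol = 2),
                              directed = FALSE)
}

#' Skeletonize a binary mask
#'
#' Reduces the mask to a one-voxel-wide centerline by distance-ordered
#' homotopic thinning: voxels are deleted in increasing order of their
#' Euclidean distance to the background, only when deletion preserves the
#' local topology (simple points) and the voxel is not a curve endpoint.
#' The skeleton therefore has the same number of connected components and
#' independent cycles as the input.
#'
#' @param mask a nonempty [binary_mask()].
#' @return skeleton [binary_mask()].
#' @export
skeletonize <- function(mask) {
  sp <- spacing_um(mask)
  m <- array(as.logical(mask), dim = dim(mask))
  if (!any(m)) stop("cannot skeletonize an empty mask")
  pr <- .distance_to(!m, sp)      # distance to background, um
  sk <- cpp_skeletonize(m, dim(m), as.numeric(pr))
  binary_mask(array(sk, dim = dim(m)), sp)
}

# 26-neighbourhood offsets as a 26 x 3 matrix
.offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

#' Extract the vessel graph from a skeleton
#'
#' Skeleton voxels become a 26-connected voxel graph; voxels with three or
#' more skeleton neighbours are junctions, and clusters of adjacent
#' junction voxels are merged into a single node at their centroid.
#' Branches are maximal paths between nodes; their length is the
#' anisotropy-aware polyline arc length and their radius the mean Euclidean
#' distance-transform value of the mask along the centerline.
#'
#' @param skeleton skeleton [binary_mask()] (from [skeletonize()]).
#' @param mask the mask the skeleton was derived from (for radii).
#' @param spacing_um voxel spacing; defaults to the skeleton's.
#' @param extend_tips extend free tips to the mask boundary minus the
#'   branch radius, compensating end-cap retraction where thinning
#'   retracts tips (off by default; on curved branches the walk can
#'   overshoot through the side wall).
#' @return a [vessel_graph()].
#' @export
extract_graph <- function(skeleton, mask, spacing_um = NULL,
                          extend_tips = FALSE) {
  if (is.null(spacing_um)) spacing_um <- spacing_um(skeleton)
  .check_spacing(spacing_um)
  if (!identical(dim(skeleton), dim(mask)))
    stop("skeleton and mask shapes differ")
  sk <- array(as.logical(skeleton), dim = dim(skeleton))
  if (!any(sk)) stop("empty skeleton")
  if (any(sk & !as.logical(mask)))
    stop("skeleton is not contained in the mask")
  d <- dim(sk)
  vox <- which(sk)
  n <- length(vox)
  ijk <- arrayInd(vox, d)
  tmap <- integer(prod(d))
  tmap[vox] <- seq_len(n)

  # neighbour lists under 26-connectivity
  nbrs <- vector("list", n)
  for (t in seq_len(n)) {
    p <- ijk[t, ]
    cand <- sweep(.offsets26, 2, p, "+")
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    li <- .vox_index(cand, d)
    nbrs[[t]] <- tmap[li[sk[li]]]
  }
  deg <- lengths(nbrs)

  radius_um <- .distance_to(!array(as.logical(mask), dim = d), spacing_um)
  coords_um <- .vox_to_um(ijk, spacing_um)

  # node voxels: junctions (>= 3) and endpoints (<= 1); junction clusters
  # merge into one node at their centroid
  node_of <- rep(NA_integer_, n)
  junction <- deg >= 3
  endpoint <- deg <= 1
  node_coords <- list()
  next_node <- 0L
  if (any(junction)) {
    jm <- array(FALSE, dim = d)
    jm[vox[junction]] <- TRUE
    jl <- .label_components(jm, 26)
    jlab <- jl[vox[junction]]
    for (cl in sort(unique(jlab))) {
      next_node <- next_node + 1L
      members <- which(junction)[jlab == cl]
      node_of[members] <- next_node
      node_coords[[next_node]] <- colMeans(coords_um[members, , drop = FALSE])
    }
  }
  for (t in which(endpoint)) {
    next_node <- next_node + 1L
    node_of[t] <- next_node
    node_coords[[next_node]] <- coords_um[t, ]
  }

  visited_edge <- new.env(hash = TRUE)
  branches <- list()
  add_branch <- function(from_node, to_node, path_idx) {
    pts <- coords_um[path_idx, , drop = FALSE]
    branches[[length(branches) + 1]] <<- list(
      from = from_node, to = to_node, pts = pts, path_idx = path_idx,
      radius = mean(radius_um[vox[path_idx]]),
      length = .polyline_length(pts))
  }
  edge_key <- function(a, b) paste(min(a, b), max(a, b))

  # walk from every node voxel through degree-2 chains
  for (t in which(!is.na(node_of))) {
    for (nb in nbrs[[t]]) {
      if (!is.na(node_of[nb])) {
        k <- edge_key(t, nb)
        if (!is.null(visited_edge[[k]])) next
        visited_edge[[k]] <- TRUE
        # direct node-node adjacency: skip if same junction cluster
        if (node_of[t] == node_of[nb] && junction[t] && junction[nb]) next
        add_branch(node_of[t], node_of[nb], c(t, nb))
        next
      }
      k <- edge_key(t, nb)
      if (!is.null(visited_edge[[k]])) next
      path <- c(t, nb)
      prev <- t; cur <- nb
      visited_edge[[k]] <- TRUE
      repeat {
        nxt <- setdiff(nbrs[[cur]], prev)
        if (length(nxt) == 0) break           # dead end mid-chain
        nxt <- nxt[1]
        visited_edge[[edge_key(cur, nxt)]] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
        if (!is.na(node_of[cur])) break
      }
      end_node <- node_of[cur]
      if (is.na(end_node)) next               # swallowed chain (shouldn't occur)
      add_branch(node_of[t], end_node, path)
    }
  }

  # isolated cycles: degree-2 rings with no node voxel; promote one voxel
  leftover <- which(is.na(node_of) & deg == 2)
  if (length(leftover) > 0) {
    seen <- rep(FALSE, n)
    for (t in leftover) {
      if (seen[t]) next
      if (any(vapply(nbrs[[t]], function(nb) !is.null(
        visited_edge[[edge_key(t, nb)]]), logical(1)))) { seen[t] <- TRUE; next }
      next_node <- next_node + 1L
      node_of[t] <- next_node
      node_coords[[next_node]] <- coords_um[t, ]
      start <- t
      prev <- t; cur <- nbrs[[t]][1]
      visited_edge[[edge_key(prev, cur)]] <- TRUE
      path <- c(t, cur)
      seen[t] <- TRUE
      while (cur != start) {
        seen[cur] <- TRUE
        nxt <- setdiff(nbrs[[cur]], prev)[1]
        visited_edge[[edge_key(cur, nxt)]] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      add_branch(next_node, next_node, path)
    }
  }

  # endpoint extension: thinning retracts terminal tips into the tube by
  # roughly one radius (the end cap peels like a blob). Walk each free tip
  # along its end direction to the mask boundary and pull back by the
  # branch radius, recovering the true centerline end to about a voxel.
  mask_arr <- array(as.logical(mask), dim = d)
  if (extend_tips) for (bi in seq_along(branches)) {
    b <- branches[[bi]]
    for (endside in 1:2) {
      vt <- if (endside == 1) b$path_idx[1] else
        b$path_idx[length(b$path_idx)]
      if (deg[vt] > 1) next                  # only free tips
      pts <- b$pts
      if (endside == 1) pts <- pts[nrow(pts):1, , drop = FALSE]
      n <- nrow(pts)
      if (n < 2) next
      dirv <- pts[n, ] - pts[max(1, n - 3), ]
      nrm <- sqrt(sum(dirv^2))
      if (nrm < 1e-9) next
      dirv <- dirv / nrm
      tip <- pts[n, ]
      step <- 0.5 * min(spacing_um)
      maxwalk <- 4 * b$radius + 2 * max(spacing_um)
      walk <- 0
      repeat {
        cand <- tip + dirv * (walk + step)
        ijk <- round(cand / spacing_um) + 1
        if (any(ijk < 1) || any(ijk > d)) break
        if (!mask_arr[ijk[1], ijk[2], ijk[3]]) break
        walk <- walk + step
        if (walk >= maxwalk) break
      }
      ext <- max(0, walk - b$radius)
      if (ext > 0) {
        newtip <- tip + dirv * ext
        if (endside == 1) b$pts <- rbind(newtip, b$pts, deparse.level = 0)
        else b$pts <- rbind(b$pts, newtip, deparse.level = 0)
        b$length <- b$length + ext
        node_coords[[node_of[vt]]] <- newtip
      }
    }
    branches[[bi]] <- b
  }

  nb <- length(branches)
  node_mat <- do.call(rbind, node_coords)
  branch_df <- data.frame(
    id = seq_len(nb),
    from = vapply(branches, function(b) b$from, integer(1)),
    to = vapply(branches, function(b) b$to, integer(1)),
    length_um = vapply(branches, function(b) b$length, numeric(1)),
    mean_radius_um = vapply(branches, function(b) b$radius, numeric(1)))
  degree_out <- tabulate(c(branch_df$from, branch_df$to), nbins = next_node)
  nodes_df <- data.frame(id = seq_len(next_node),
                         x = node_mat[, 1], y = node_mat[, 2],
                         z = node_mat[, 3], degree = degree_out)
  vessel_graph(nodes_df, branch_df, lapply(branches, function(b) b$pts),
               spacing_um)
}

#' Prune short terminal twigs from a vessel graph
#'
#' Removes terminal branches (one endpoint of degree 1) shorter than
#' `prune_below_um` — typically skeletonization spurs at tube ends — and
#' then merges any resulting degree-2 node into a single branch
#' (concatenated centerline, summed length, length-weighted mean radius),
#' restoring the invariant that branch endpoints have degree != 2.
#'
#' @param graph a [vessel_graph()].
#' @param prune_below_um twig length threshold in um; at 0 no twigs are
#'   removed but degree-2 chains are still merged.
#' @return pruned [vessel_graph()].
#' @export
prune_graph <- function(graph, prune_below_um) {
  if (nrow(graph$branches) == 0) return(graph)
  br <- graph$branches
  paths <- graph$paths
  while (prune_below_um > 0) {
    nn <- max(c(br$from, br$to))
    deg <- tabulate(c(br$from, br$to), nbins = nn)
    twig <- (deg[br$from] == 1 | deg[br$to] == 1) &
      br$from != br$to & br$length_um < prune_below_um &
      deg[br$from] + deg[br$to] > 2    # keep isolated single branches
    if (!any(twig)) break
    # remove the shortest twig first, then re-evaluate (degrees change)
    drop <- which(twig)[which.min(br$length_um[twig])]
    br <- br[-drop, , drop = FALSE]
    paths <- paths[-drop]
  }
  # merge chains through degree-2 nodes (not touching self-loops)
  repeat {
    nn <- max(c(br$from, br$to))
    deg <- tabulate(c(br$from, br$to), nbins = nn)
    mid <- which(deg == 2)
    merged <- FALSE
    for (v in mid) {
      inc <- which(br$from == v | br$to == v)
      if (length(inc) != 2) next                 # self-loop at v
      b1 <- inc[1]; b2 <- inc[2]
      # orient both paths so they run towards/away from v
      p1 <- paths[[b1]]; p2 <- paths[[b2]]
      if (br$to[b1] != v) { p1 <- p1[nrow(p1):1, , drop = FALSE]
        ends1 <- c(br$to[b1], v) } else ends1 <- c(br$from[b1], v)
      if (br$from[b2] != v) { p2 <- p2[nrow(p2):1, , drop = FALSE]
        ends2 <- c(v, br$from[b2]) } else ends2 <- c(v, br$to[b2])
      newpath <- rbind(p1, p2[-1, , drop = FALSE])
      l1 <- br$length_um[b1]; l2 <- br$length_um[b2]
      r <- (br$mean_radius_um[b1] * l1 + br$mean_radius_um[b2] * l2) /
        max(l1 + l2, 1e-12)
      br$from[b1] <- ends1[1]; br$to[b1] <- ends2[2]
      br$length_um[b1] <- l1 + l2
      br$mean_radius_um[b1] <- r
      paths[[b1]] <- newpath
      br <- br[-b2, , drop = FALSE]
      paths <- paths[-b2]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  keep_nodes <- sort(unique(c(br$from, br$to)))
  nodes <- graph$nodes[graph$nodes$id %in% keep_nodes, , drop = FALSE]
  remap <- setNames(seq_along(keep_nodes), keep_nodes)
  br$from <- unname(remap[as.character(br$from)])
  br$to <- unname(remap[as.character(br$to)])
  nodes$id <- unname(remap[as.character(nodes$id)])
  br$id <- seq_len(nrow(br))
  nodes$degree <- tabulate(c(br$from, br$to), nbins = length(keep_nodes))
  rownames(br) <- NULL; rownames(nodes) <- NULL
  vessel_graph(nodes, br, paths, attr(graph, "spacing_um"))
}

#' Summarize vessel-network geometry
#'
#' Mean branch radius and length, branch count, and branch density per mm^3
#' of tissue. Isolated end twigs shorter than `prune_below_um` are removed
#' before summarizing.
#'
#' @param graph a [vessel_graph()].
#' @param tissue_mask [binary_mask()] defining the tissue volume.
#' @param spacing_um voxel spacing of the tissue mask; defaults to its own.
#' @param prune_below_um prune threshold (um), 0 disables pruning.
#' @return a `geometry_report` list: `mean_radius_um`,
#'   `mean_branch_length_um`, `branch_density_per_mm3`, `n_branches`,
#'   `tissue_volume_mm3`.
#' @export
geometry_report <- function(graph, tissue_mask, spacing_um = NULL,
                            prune_below_um = 0) {
  if (prune_below_um < 0) stop("prune_below_um must be >= 0")
  if (is.null(spacing_um)) spacing_um <- spacing_um(tissue_mask)
  tv_mm3 <- sum(tissue_mask) * prod(spacing_um) * 1e-9
  if (tv_mm3 == 0) stop("tissue volume is zero")
  if (prune_below_um > 0) graph <- prune_graph(graph, prune_below_um)
  br <- graph$branches
  n <- nrow(br)
  structure(list(
    mean_radius_um = if (n > 0) mean(br$mean_radius_um) else NA_real_,
    mean_branch_length_um = if (n > 0) mean(br$length_um) else NA_real_,
    branch_density_per_mm3 = n / tv_mm3,
    n_branches = n,
    tissue_volume_mm3 = tv_mm3), class = "geometry_report")
}
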