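#' Branch endpoint cloud of a vessel graph
#'
#' The deduplicated set of branch start/end coordinates (node positions),
#' in um. This is the point cloud the persistence diagram is built from.
#'
#' @param graph a [vessel_graph()].
#' @return matrix with columns x, y, z (um).
#' @export
endpoint_cloud <- function(graph) {
  if (nrow(graph$branches) == 0) stop("graph has no branches")
  ids <- sort(unique(c(graph$branches$from, graph$branches$to)))
  pts <- as.matrix(graph$nodes[match(ids, graph$nodes$id), c("x", "y", "z")])
  unique(pts)
}

#' Vietoris-Rips persistence of a point cloud
#'
#' Builds the Vietoris-Rips filtration on Euclidean distances up to an
#' edge-length cutoff and reduces the boundary matrix to obtain dimension-0
#' and dimension-1 features. Deterministic given the input ordering.
#' Essential classes have `death = Inf`; with a cutoff too small to connect
#' anything the diagram degenerates to one infinite dim-0 bar per point
#' (QC-warned).
#'
#' @param points n-by-d numeric matrix (n >= 2), coordinates in um.
#' @param max_dim maximal homology dimension (only 1 is supported).
#' @param max_edge_um edge-length cutoff in um; `NULL` selects four times
#'   the 95th percentile of nearest-neighbour distances.
#' @return a `persistence_diagram` data.frame with columns `dimension`,
#'   `birth`, `death`.
#' @export
rips_persistence <- function(points, max_dim = 1, max_edge_um = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("need at least 1 point")
  if (max_dim != 1) stop("only max_dim = 1 is supported")
  if (nrow(points) == 1)
    return(structure(data.frame(dimension = 0, birth = 0, death = Inf),
                     class = c("persistence_diagram", "data.frame"),
                     max_edge_um = max_edge_um))
  if (is.null(max_edge_um)) {
    nnd <- .nearest_neighbour_dist(points)
    max_edge_um <- 4 * quantile(nnd, 0.95, names = FALSE)
  }
  if (max_edge_um <= 0) stop("max_edge_um must be > 0")
  dg <- cpp_rips(points, max_edge_um)
  if (all(!is.finite(dg$death) & dg$dimension == 0) &&
      nrow(dg) == nrow(points))
    warning("QC: max_edge_um connects no points; diagram is trivial")
  structure(dg, class = c("persistence_diagram", "data.frame"),
            max_edge_um = max_edge_um)
}

.nearest_neighbour_dist <- function(points) {
  dm <- as.matrix(stats::dist(points))
  diag(dm) <- Inf
  apply(dm, 1, min)
}

#' First Betti number from a persistence diagram
#'
#' Number of dimension-1 features (loops) with lifetime strictly greater
#' than `min_lifetime_um`. At the default 0 every positive-persistence
#' loop counts; a positive threshold suppresses short-lived features that
#' typically arise from endpoint clutter rather than true vessel loops.
#'
#' @param diagram a `persistence_diagram`.
#' @param min_lifetime_um lifetime threshold in um.
#' @return integer count.
#' @export
betti1 <- function(diagram, min_lifetime_um = 0) {
  d1 <- diagram[diagram$dimension == 1, , drop = FALSE]
  if (nrow(d1) == 0) return(0L)
  sum(d1$death - d1$birth > min_lifetime_um)
}

#' Persistence entropy
#'
#' Shannon entropy (natural log) of the normalized finite lifetimes pooled
#' over homology dimensions: with lifetimes `l_i` and `p_i = l_i / sum(l)`,
#' the entropy is `-sum(p_i log p_i)`. Infinite bars are excluded. Higher
#' values indicate a wider diversity of feature scales.
#'
#' @param diagram a `persistence_diagram` with at least one finite feature.
#' @param by_dimension also return per-dimension entropies.
#' @return scalar entropy, or a list when `by_dimension = TRUE`.
#' @export
persistence_entropy <- function(diagram, by_dimension = FALSE) {
  lt <- diagram$death - diagram$birth
  fin <- is.finite(lt) & lt > 0
  if (!any(fin))
    stop("no finite-lifetime features: entropy is undefined")
  ent <- function(l) {
    p <- l / sum(l)
    -sum(p * log(p)) + 0      # + 0 normalizes IEEE negative zero
  }
  total <- ent(lt[fin])
  if (!by_dimension) return(total)
  dims <- sort(unique(diagram$dimension[fin]))
  per <- vapply(dims, function(dd) {
    l <- lt[fin & diagram$dimension == dd]
    if (length(l) == 0) NA_real_ else ent(l)
  }, numeric(1))
  list(entropy = total, per_dimension = setNames(per, paste0("dim", dims)))
}

#' Average lifetime of finite features
#'
#' @param diagram a `persistence_diagram` with at least one finite feature.
#' @return mean finite lifetime (um).
#' @export
average_lifetime <- function(diagram) {
  lt <- diagram$death - diagram$birth
  fin <- is.finite(lt)
  if (!any(fin)) stop("no finite-lifetime features")
  mean(lt[fin])
}

#' Exact cycle rank of a vessel graph
#'
#' The number of independent cycles `E - V + C` of the branch-level
#' multigraph: the exact loop count the persistence-based Betti 1
#' approximates.
#'
#' @param graph a [vessel_graph()].
#' @return integer cycle rank.
#' @export
cycle_rank <- function(graph) {
  br <- graph$branches
  if (nrow(br) == 0) return(0L)
  ids <- sort(unique(c(br$from, br$to)))
  g <- .as_igraph(graph)
  E <- nrow(br)
  V <- length(ids)
  C <- igraph::components(g)$no
  as.integer(E - V + C)
}

#' Topology report for a vessel graph
#'
#' Persistence diagram from the branch endpoint cloud plus the summary
#' metrics: Betti 1 (raw and noise-filtered), persistence entropy and
#' average lifetime, alongside the exact graph cycle rank.
#'
#' @param graph a [vessel_graph()].
#' @param max_edge_um Rips cutoff; `NULL` for the adaptive default.
#' @param min_lifetime_um threshold for the noise-filtered Betti 1;
#'   `NULL` selects twice the median nearest-neighbour distance of the
#'   endpoint cloud.
#' @return a `topology_report` list.
#' @export
topology_report <- function(graph, max_edge_um = NULL,
                            min_lifetime_um = NULL) {
  pts <- endpoint_cloud(graph)
  dg <- rips_persistence(pts, 1, max_edge_um)
  if (is.null(min_lifetime_um)) {
    nnd <- .nearest_neighbour_dist(pts)
    min_lifetime_um <- 2 * median(nnd)
  }
  structure(list(
    betti1 = betti1(dg),
    betti1_filtered = betti1(dg, min_lifetime_um),
    min_lifetime_um = min_lifetime_um,
    persistence_entropy = tryCatch(persistence_entropy(dg),
                                   error = function(e) NA_real_),
    average_lifetime_um = tryCatch(average_lifetime(dg),
                                   error = function(e) NA_real_),
    cycle_rank = cycle_rank(graph),
    diagram = dg), class = "topology_report")
}
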