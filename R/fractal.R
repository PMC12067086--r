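#' Box-counting fractal dimension
#'
#' Counts, for each box size `s`, the number of occupied boxes `N(s)` on a
#' fixed grid anchored at the array origin, and returns the least-squares
#' slope of `log N(s)` against `log(1/s)`. The slope is clipped to the
#' admissible range \[0, 3\] for a 3D pattern.
#'
#' @param mask a nonempty [binary_mask()] or logical array.
#' @param box_sizes box edge lengths in voxels; default is the dyadic
#'   series from `min(dim)/2` down to 2. At least three sizes are required.
#' @param grid_average average counts over all grid offsets per size
#'   (slower; off by default so results are deterministic functions of the
#'   array alone).
#' @return list with `dimension`, `box_sizes_vox`, `counts`, `r2`.
#' @export
box_count_dimension <- function(mask, box_sizes = NULL, grid_average = FALSE) {
  m <- array(as.logical(mask), dim = dim(mask))
  if (!any(m)) stop("box counting needs a nonempty mask")
  d <- dim(m)
  if (is.null(box_sizes)) box_sizes <- .dyadic_sizes(d)
  box_sizes <- sort(unique(as.integer(box_sizes)), decreasing = TRUE)
  if (length(box_sizes) < 3) stop("need at least 3 box sizes")
  ijk <- arrayInd(which(m), d)
  counts <- vapply(box_sizes, function(s) {
    if (!grid_average) return(.count_boxes(ijk, s, 0L))
    # full offset averaging is cubic in s; sample the axis-aligned offsets
    offs <- unique(rbind(c(0, 0, 0), cbind(0:(s - 1), 0, 0),
                         cbind(0, 0:(s - 1), 0), cbind(0, 0, 0:(s - 1))))
    mean(apply(offs, 1, function(o) .count_boxes(ijk, s, o)))
  }, numeric(1))
  fit <- .loglog_fit(log(1 / box_sizes), log(counts))
  list(dimension = min(max(fit$slope, 0), 3),
       box_sizes_vox = box_sizes, counts = counts, r2 = fit$r2)
}

.dyadic_sizes <- function(d) {
  top <- floor(log2(min(d) / 2))
  if (top < 1) stop("volume too small for box counting")
  2^(top:1)
}

.count_boxes <- function(ijk, s, offset) {
  if (length(offset) == 1) offset <- rep(offset, 3)
  bx <- (ijk[, 1] - 1 + offset[1]) %/% s
  by <- (ijk[, 2] - 1 + offset[2]) %/% s
  bz <- (ijk[, 3] - 1 + offset[3]) %/% s
  nrow(unique(cbind(bx, by, bz)))
}

# 3D summed-area table with a zero-padded leading plane per axis
.integral_image <- function(m) {
  a <- array(as.numeric(m), dim = dim(m))
  a <- apply(a, c(2, 3), cumsum)
  a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3))
  a <- aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))
  d <- dim(m)
  out <- array(0, dim = d + 1L)
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  out
}

# sums of r^3 boxes with given 1-based start indices (vectors per axis)
.box_sums <- function(ii, sx, sy, sz, r) {
  x0 <- sx; x1 <- sx + r; y0 <- sy; y1 <- sy + r; z0 <- sz; z1 <- sz + r
  g <- expand.grid(x0 = x0, y0 = y0, z0 = z0)
  gx1 <- g$x0 + r; gy1 <- g$y0 + r; gz1 <- g$z0 + r
  ii[cbind(gx1, gy1, gz1)] - ii[cbind(g$x0, gy1, gz1)] -
    ii[cbind(gx1, g$y0, gz1)] - ii[cbind(gx1, gy1, g$z0)] +
    ii[cbind(g$x0, g$y0, gz1)] + ii[cbind(g$x0, gy1, g$z0)] +
    ii[cbind(gx1, g$y0, g$z0)] - ii[cbind(g$x0, g$y0, g$z0)]
}

#' Gliding-box lacunarity
#'
#' For each box size `r`, slides an `r^3` window over the volume with
#' stride `r/2` (floored at 1), records the foreground mass `m` in each
#' window and computes `Lambda(r) = var(m)/mean(m)^2 + 1` (population
#' variance). The summary lacunarity is the mean of `Lambda(r)` over
#' sizes; the per-size curve is returned so any other reduction can be
#' recomputed. A completely full mask gives exactly 1 at every size;
#' values grow with the gappiness and spatial clustering of the pattern.
#'
#' @param mask a nonempty [binary_mask()] or logical array.
#' @param box_sizes window edges in voxels; dyadic default as in
#'   [box_count_dimension()].
#' @return list with `lacunarity` (summary), `per_size` (data.frame of
#'   `box_size_vox`, `lambda`, `n_boxes`).
#' @export
lacunarity <- function(mask, box_sizes = NULL) {
  m <- array(as.logical(mask), dim = dim(mask))
  if (!any(m)) stop("lacunarity needs a nonempty mask")
  d <- dim(m)
  if (is.null(box_sizes)) box_sizes <- .dyadic_sizes(d)
  box_sizes <- sort(unique(as.integer(box_sizes)), decreasing = TRUE)
  box_sizes <- box_sizes[box_sizes <= min(d)]
  ii <- .integral_image(m)
  rows <- lapply(box_sizes, function(r) {
    stride <- max(1L, r %/% 2L)
    sx <- seq(1L, d[1] - r + 1L, by = stride)
    sy <- seq(1L, d[2] - r + 1L, by = stride)
    sz <- seq(1L, d[3] - r + 1L, by = stride)
    mass <- .box_sums(ii, sx, sy, sz, r)
    mu <- mean(mass)
    lam <- if (mu == 0) NA_real_ else mean((mass - mu)^2) / mu^2 + 1
    data.frame(box_size_vox = r, lambda = lam, n_boxes = length(mass))
  })
  per_size <- do.call(rbind, rows)
  list(lacunarity = mean(per_size$lambda, na.rm = TRUE), per_size = per_size)
}

#' Connectivity (mass-radius) dimension of a skeleton
#'
#' Sandbox scaling along the network: from randomly seeded skeleton voxels,
#' `M(r)` is the number of skeleton voxels within geodesic (along-skeleton)
#' distance `r`, where geodesic distances are shortest paths on the
#' 26-connected voxel graph weighted by physical step lengths in um. The
#' dimension is the slope of `log mean M(r)` versus `log r`.
#'
#' @param skeleton_mask a nonempty skeleton [binary_mask()].
#' @param seed_fraction fraction of skeleton voxels used as seeds.
#' @param radii increasing geodesic radii in um; defaults to a geometric
#'   series spanning twice the voxel pitch to a quarter of the network
#'   extent.
#' @param seed RNG seed for seed-voxel sampling.
#' @return list with `dimension`, `r2`, `radii_um`, `mean_mass`.
#' @export
connectivity_dimension <- function(skeleton_mask, seed_fraction = 0.1,
                                   radii = NULL, seed = 1) {
  sp <- spacing_um(skeleton_mask)
  m <- array(as.logical(skeleton_mask), dim = dim(skeleton_mask))
  if (!any(m)) stop("empty skeleton")
  d <- dim(m)
  vox <- which(m)
  n <- length(vox)
  ijk <- arrayInd(vox, d)
  tmap <- integer(prod(d))
  tmap[vox] <- seq_len(n)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(.offsets26))) {
    o <- .offsets26[k, ]
    if (o[3] < 0 || (o[3] == 0 && (o[2] < 0 || (o[2] == 0 && o[1] < 0))))
      next    # each unordered pair once
    cand <- sweep(ijk, 2, o, "+")
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    li <- .vox_index(cand[ok, , drop = FALSE], d)
    hit <- tmap[li] > 0
    from <- c(from, which(ok)[hit])
    to <- c(to, tmap[li[hit]])
    w <- c(w, rep(sqrt(sum((o * sp)^2)), sum(hit)))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  if (is.null(radii)) {
    span <- max(apply(.vox_to_um(ijk, sp), 2, function(v) diff(range(v))))
    r0 <- 2 * min(sp)
    r1 <- max(span / 4, r0 * 4)
    radii <- exp(seq(log(r0), log(r1), length.out = 8))
  }
  if (length(radii) < 3 || is.unsorted(radii, strictly = TRUE))
    stop("radii must be at least 3 increasing values")
  nseed <- max(2L, ceiling(seed_fraction * n))
  seeds <- .with_seed(seed, sample.int(n, min(nseed, n)))
  dist <- igraph::distances(g, v = seeds)
  mean_mass <- vapply(radii, function(r) mean(rowSums(dist <= r)), numeric(1))
  fit <- .loglog_fit(log(radii), log(mean_mass))
  list(dimension = min(max(fit$slope, 0), 3), r2 = fit$r2,
       radii_um = radii, mean_mass = mean_mass)
}

#' Full fractal report for a vascular mask
#'
#' Convenience wrapper bundling [box_count_dimension()], [lacunarity()]
#' and [connectivity_dimension()] (the latter on the mask's skeleton).
#'
#' @param mask vessel [binary_mask()].
#' @param skeleton optional precomputed skeleton; computed when `NULL`.
#' @param box_sizes passed to the box-based estimators.
#' @param seed RNG seed for connectivity-dimension seeding.
#' @return a `fractal_report` list.
#' @export
fractal_report <- function(mask, skeleton = NULL, box_sizes = NULL, seed = 1) {
  bc <- box_count_dimension(mask, box_sizes)
  lac <- lacunarity(mask, box_sizes)
  if (is.null(skeleton)) skeleton <- skeletonize(mask)
  cd <- connectivity_dimension(skeleton, seed = seed)
  structure(list(fractal_dimension = bc$dimension,
                 lacunarity = lac$lacunarity,
                 connectivity_dimension = cd$dimension,
                 box_sizes_vox = bc$box_sizes_vox,
                 counts = bc$counts,
                 r2_fit = c(box_count = bc$r2, connectivity = cd$r2),
                 lacunarity_per_size = lac$per_size),
            class = "fractal_report")
}
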