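# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

dice_coef <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# brute-force persistent homology (dims 0-1) of a point cloud by full
# boundary-matrix reduction over GF(2), all simplices up to triangles
oracle_rips <- function(pts, max_edge) {
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  simp <- list()
  for (i in seq_len(n)) simp[[length(simp) + 1]] <-
      list(v = i, dim = 0, filt = 0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] <= max_edge)
      simp[[length(simp) + 1]] <- list(v = c(i, j), dim = 1, filt = D[i, j])
  if (n >= 3)
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      f <- max(D[i, j], D[i, k], D[j, k])
      if (f <= max_edge)
        simp[[length(simp) + 1]] <- list(v = c(i, j, k), dim = 2, filt = f)
    }
  ord <- order(vapply(simp, `[[`, numeric(1), "filt"),
               vapply(simp, `[[`, numeric(1), "dim"),
               vapply(simp, function(s) paste(s$v, collapse = ","), ""))
  simp <- simp[ord]
  key <- vapply(simp, function(s) paste(s$v, collapse = ","), "")
  idx_of <- stats::setNames(seq_along(simp), key)
  m <- length(simp)
  cols <- vector("list", m)
  for (c in seq_len(m)) {
    s <- simp[[c]]
    if (s$dim == 0) { cols[[c]] <- integer(0); next }
    faces <- utils::combn(s$v, length(s$v) - 1)
    cols[[c]] <- sort(unname(idx_of[apply(faces, 2, paste, collapse = ",")]))
  }
  low_of <- rep(NA_integer_, m)   # row -> column owning that pivot
  pairs <- list()
  for (c in seq_len(m)) {
    col <- cols[[c]]
    while (length(col) > 0) {
      l <- max(col)
      owner <- low_of[l]
      if (is.na(owner)) break
      col <- sort(union(setdiff(col, cols[[owner]]),
                        setdiff(cols[[owner]], col)))
    }
    cols[[c]] <- col
    if (length(col) > 0) {
      l <- max(col)
      low_of[l] <- c
      pairs[[length(pairs) + 1]] <-
        list(dim = simp[[l]]$dim, birth = simp[[l]]$filt,
             death = simp[[c]]$filt)
    }
  }
  paired <- unique(c(
    vapply(which(!is.na(low_of)), identity, integer(1)),   # birth simplices
    stats::na.omit(low_of)))                               # death simplices
  essential <- setdiff(seq_len(m), paired)
  bars <- do.call(rbind, c(
    lapply(pairs, function(p)
      data.frame(dimension = p$dim, birth = p$birth, death = p$death)),
    lapply(essential, function(e) {
      s <- simp[[e]]
      if (s$dim > 1) return(NULL)
      data.frame(dimension = s$dim, birth = s$filt, death = Inf)
    })))
  bars <- bars[bars$death > bars$birth, , drop = FALSE]
  rownames(bars) <- NULL
  bars[order(bars$dimension, bars$birth, bars$death), ]
}

# canonical sort for diagram comparison
sort_diagram <- function(d) {
  d <- as.data.frame(d)[, c("dimension", "birth", "death")]
  d <- d[order(d$dimension, d$birth, d$death), ]
  rownames(d) <- NULL
  d
}

# brute-force gliding-box lacunarity at one size
oracle_lacunarity_size <- function(mask, r) {
  d <- dim(mask)
  stride <- max(1L, r %/% 2L)
  masses <- c()
  for (x in seq(1, d[1] - r + 1, by = stride))
    for (y in seq(1, d[2] - r + 1, by = stride))
      for (z in seq(1, d[3] - r + 1, by = stride))
        masses <- c(masses, sum(mask[x:(x + r - 1), y:(y + r - 1),
                                     z:(z + r - 1)]))
  mu <- mean(masses)
  mean((masses - mu)^2) / mu^2 + 1
}

# grayscale opening of a 2D slice by direct min/max over a disk
oracle_open2d <- function(sl, radius) {
  d <- dim(sl)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  er <- matrix(Inf, d[1], d[2])
  for (x in 1:d[1]) for (y in 1:d[2]) {
    xs <- x + offs$dx; ys <- y + offs$dy
    ok <- xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2]
    er[x, y] <- min(sl[cbind(xs[ok], ys[ok])])
  }
  op <- matrix(-Inf, d[1], d[2])
  for (x in 1:d[1]) for (y in 1:d[2]) {
    xs <- x + offs$dx; ys <- y + offs$dy
    ok <- xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2]
    op[x, y] <- max(er[cbind(xs[ok], ys[ok])])
  }
  op
}

# Li minimum cross-entropy objective for a brute-force threshold scan
oracle_li_objective <- function(x, t) {
  lo <- x[x <= t]; hi <- x[x > t]
  if (length(lo) == 0 || length(hi) == 0) return(Inf)
  m0 <- mean(lo); m1 <- mean(hi)
  if (m0 <= 0 || m1 <= 0) return(Inf)
  -(sum(lo) * log(m0) + sum(hi) * log(m1))
}

# solid tube mask along the x axis, radius in voxels
make_tube_mask <- function(nx, ny, nz, x0, x1, cy, cz, r,
                           spacing = c(1, 1, 1)) {
  m <- array(FALSE, c(nx, ny, nz))
  for (i in x0:x1) for (j in 1:ny) for (k in 1:nz)
    if ((j - cy)^2 + (k - cz)^2 <= r^2) m[i, j, k] <- TRUE
  binary_mask(m, spacing)
}

# points on a circle in 3D
circle_points <- function(n, radius, centre = c(0, 0, 0)) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(centre[1] + radius * cos(a), centre[2] + radius * sin(a), centre[3])
}
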