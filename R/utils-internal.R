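# Internal numeric helpers shared across modules. Not exported.

# run code with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# voxel offsets (m x 3 integer matrix) within a Euclidean radius, measured
# in voxel units scaled per axis; planar = TRUE restricts to dz = 0
.ball_offsets <- function(radius_vox, aspect = c(1, 1, 1), planar = FALSE) {
  r <- ceiling(radius_vox / aspect)
  if (planar) r[3] <- 0
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d <- sqrt((g$dx * aspect[1])^2 + (g$dy * aspect[2])^2 + (g$dz * aspect[3])^2)
  as.matrix(g[d <= radius_vox + 1e-9, , drop = FALSE])
}

.cube_offsets <- function() {
  as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
}

# grayscale erosion / dilation / opening / closing over an offset SE
.erode_gray <- function(arr, offsets) {
  array(cpp_min_filter(as.numeric(arr), dim(arr), offsets), dim = dim(arr))
}
.dilate_gray <- function(arr, offsets) {
  array(cpp_max_filter(as.numeric(arr), dim(arr), offsets), dim = dim(arr))
}
.open_gray <- function(arr, offsets) .dilate_gray(.erode_gray(arr, offsets), offsets)
.close_gray <- function(arr, offsets) .erode_gray(.dilate_gray(arr, offsets), offsets)

.dilate_binary <- function(mask, offsets) {
  .dilate_gray(array(as.numeric(mask), dim(mask)), offsets) > 0.5
}
.erode_binary <- function(mask, offsets) {
  .erode_gray(array(as.numeric(mask), dim(mask)), offsets) > 0.5
}

# 26- or 6-connected component labels; attr "n_components" holds the count
.label_components <- function(mask, connectivity = 26) {
  lab <- cpp_label(as.logical(mask), dim(mask), as.integer(connectivity))
  n <- attr(lab, "n_components")
  out <- array(lab, dim = dim(mask))
  attr(out, "n_components") <- n
  out
}

.n_components <- function(mask, connectivity = 26) {
  attr(.label_components(mask, connectivity), "n_components")
}

# Euclidean distance (um) from every voxel to the nearest TRUE voxel
.distance_to <- function(feature, spacing_um) {
  array(cpp_edt(as.logical(feature), dim(feature), as.numeric(spacing_um)),
        dim = dim(feature))
}

# linear voxel index from 1-based (i, j, k) matrix
.vox_index <- function(ijk, dims) {
  (ijk[, 3] - 1) * dims[1] * dims[2] + (ijk[, 2] - 1) * dims[1] + ijk[, 1]
}

# physical um coords of 1-based voxel indices
.vox_to_um <- function(ijk, spacing_um) {
  sweep(ijk - 1, 2, spacing_um, "*")
}

# nearest 1-based voxel index of physical um coords, clamped to the volume
.um_to_vox <- function(xyz_um, spacing_um, dims) {
  ijk <- round(sweep(xyz_um, 2, spacing_um, "/")) + 1
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 1), dims[a])
  ijk
}

# arc length of a polyline given as an n x 3 matrix of um coords
.polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# least-squares slope of y on x with R^2; exact collinearity (analytic
# solids) makes summary.lm warn about a perfect fit, which is expected
.loglog_fit <- function(x, y) {
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]),
       r2 = suppressWarnings(summary(fit)$r.squared))
}

.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
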