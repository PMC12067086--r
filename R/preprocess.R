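#' Segmentation configuration
#'
#' Bundles the parameters of the two vessel-segmentation recipes and the
#' cyst recipe. The `adult` recipe (cleared 3-month kidney stacks) runs
#' rolling-ball background subtraction, grayscale closing, multi-scale
#' Hessian tubeness and thresholding; the `fetal` recipe (E18.5 stacks)
#' runs rolling-ball subtraction, a 3D Gaussian blur (sigma 2 voxels),
#' mean-based thresholding and mask cleanup (minimum object size 3,
#' one close, one dilate/erode).
#'
#' @param recipe one of `"adult"`, `"fetal"`, `"cyst"`.
#' @param rolling_ball_radius_vox rolling-ball radius in pixels (slice-wise).
#' @param gaussian_sigma_vox Gaussian blur sigma in voxels (isotropic).
#' @param threshold_method `"li"` or `"mean"`.
#' @param threshold_offset added to the automatic threshold; the explicit,
#'   logged stand-in for a manually fine-tuned threshold. `NULL` selects the
#'   half-peak rule: threshold at half of the (99.9th percentile) ridge
#'   peak, the FWHM criterion under which a vessel's apparent radius equals
#'   its half-maximum radius.
#' @param min_object_vox components smaller than this are removed.
#' @param n_close number of binary closings.
#' @param n_dilate_erode dilations followed by the same number of erosions.
#' @param tubeness_scales_vox Hessian scales (voxels) for the adult recipe.
#' @param closing_radius_vox grayscale closing ball radius (adult recipe).
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(recipe = c("fetal", "adult", "cyst"),
                                rolling_ball_radius_vox = 50L,
                                gaussian_sigma_vox = 2,
                                threshold_method = c("mean", "li"),
                                threshold_offset = NULL,
                                min_object_vox = 3L,
                                n_close = 1L,
                                n_dilate_erode = 1L,
                                tubeness_scales_vox = c(1, 2),
                                closing_radius_vox = 2L) {
  recipe <- match.arg(recipe)
  threshold_method <- match.arg(threshold_method)
  if (gaussian_sigma_vox <= 0) stop("gaussian_sigma_vox must be > 0")
  if (min_object_vox < 0) stop("min_object_vox must be >= 0")
  if (rolling_ball_radius_vox <= 0) stop("rolling_ball_radius_vox must be > 0")
  structure(list(recipe = recipe,
                 rolling_ball_radius_vox = as.integer(rolling_ball_radius_vox),
                 gaussian_sigma_vox = gaussian_sigma_vox,
                 threshold_method = threshold_method,
                 threshold_offset = threshold_offset,
                 min_object_vox = as.integer(min_object_vox),
                 n_close = as.integer(n_close),
                 n_dilate_erode = as.integer(n_dilate_erode),
                 tubeness_scales_vox = tubeness_scales_vox,
                 closing_radius_vox = as.integer(closing_radius_vox)),
            class = "segmentation_config")
}

#' Rolling-ball background subtraction
#'
#' Estimates the background of each z-slice as its grayscale opening with a
#' flat disk of the given radius (the rolling-ball background model) and
#' subtracts it. The result is nonnegative because an opening never exceeds
#' the image.
#'
#' @param stack a [volume_image()] or 3D array.
#' @param radius_vox ball (disk) radius in pixels; must be positive and
#'   smaller than the slice extent.
#' @return background-subtracted `volume_image`.
#' @export
subtract_background <- function(stack, radius_vox = 50) {
  sp <- spacing_um(stack)
  a <- .as_plain(stack)
  if (radius_vox <= 0) stop("radius_vox must be > 0")
  if (radius_vox >= min(dim(a)[1:2]))
    stop("rolling-ball radius exceeds the slice extent")
  bg <- array(cpp_disk_open2d(as.numeric(a), dim(a),
                              as.integer(radius_vox)), dim = dim(a))
  volume_image(pmax(a - bg, 0), sp)
}

# separable Gaussian convolution along one axis with edge renormalization
.convolve_axis <- function(a, kernel, axis) {
  array(cpp_convolve_axis(as.numeric(a), dim(a), kernel, as.integer(axis)),
        dim = dim(a))
}

#' 3D Gaussian smoothing
#'
#' Separable Gaussian convolution (kernel truncated at 3 sigma) with edge
#' renormalization, so a constant stack is reproduced exactly and the mean
#' is preserved to numerical tolerance.
#'
#' @param stack a [volume_image()] or 3D array.
#' @param sigma_vox Gaussian sigma in voxels (applied along all axes).
#' @return smoothed `volume_image`.
#' @export
smooth_stack <- function(stack, sigma_vox = 2) {
  if (sigma_vox <= 0) stop("sigma_vox must be > 0")
  sp <- spacing_um(stack)
  a <- .as_plain(stack)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  for (axis in 1:3) a <- .convolve_axis(a, k, axis)
  volume_image(a, sp)
}

#' Li minimum cross-entropy threshold
#'
#' Iterative Li threshold: starting from the global mean, alternate between
#' splitting the histogram at `t` and moving `t` to the log-mean of the two
#' class means until convergence. Intensities are shifted to be nonnegative
#' first; the returned threshold is on the original scale.
#'
#' @param x numeric vector or array of intensities.
#' @param tol convergence tolerance on the threshold.
#' @return scalar threshold.
#' @export
threshold_li <- function(x, tol = NULL) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  if (is.null(tol)) tol <- diff(rng) / 1e6
  y <- v - rng[1]
  eps <- diff(rng) * 1e-9
  t <- mean(y)
  for (i in 1:200) {
    m0 <- mean(y[y <= t])
    m1 <- mean(y[y > t])
    if (!is.finite(m1)) break
    m0 <- max(m0, eps)
    t_new <- (m1 - m0) / (log(m1) - log(m0))
    if (!is.finite(t_new)) break
    if (abs(t_new - t) < tol) { t <- t_new; break }
    t <- t_new
  }
  t + rng[1]
}

#' Binarize a stack by global thresholding
#'
#' `mean` thresholds at the global mean plus `offset`; `li` minimizes Li's
#' cross-entropy objective (see [threshold_li()]), plus `offset`. The mask
#' is `TRUE` strictly above the threshold. Degenerate results (constant
#' input, empty or full mask) raise a QC warning.
#'
#' @param stack a [volume_image()] or array.
#' @param method `"mean"` or `"li"`.
#' @param offset added to the automatic threshold (manual fine-tune).
#' @return a [binary_mask()]; the threshold used is stored in
#'   `attr(, "threshold")`.
#' @export
binarize <- function(stack, method = c("mean", "li"), offset = 0) {
  method <- match.arg(method)
  sp <- spacing_um(stack)
  a <- .as_plain(stack)
  if (diff(range(a)) == 0) {
    warning("constant stack: threshold set to the constant, mask is empty")
    thr <- a[1] + offset
  } else {
    thr <- switch(method, mean = mean(a) + offset,
                  li = threshold_li(a) + offset)
  }
  m <- a > thr
  frac <- mean(m)
  if (frac == 0 || frac == 1)
    warning(sprintf("QC: thresholding produced a %s mask",
                    if (frac == 0) "empty" else "full"))
  out <- binary_mask(m, sp)
  attr(out, "threshold") <- thr
  out
}

#' Clean a binary mask
#'
#' Removes 26-connected components smaller than `min_object_vox`, applies
#' binary closing `n_close` times, then `n_dilate_erode` dilations followed
#' by the same number of erosions (3x3x3 structuring element), ensuring
#' continuity of touching vessel segments.
#'
#' @param mask a [binary_mask()] or logical array.
#' @param min_object_vox minimum component size kept (voxels).
#' @param n_close number of closings.
#' @param n_dilate_erode dilation/erosion count.
#' @return cleaned [binary_mask()].
#' @export
clean_mask <- function(mask, min_object_vox = 3, n_close = 1,
                       n_dilate_erode = 1) {
  sp <- spacing_um(mask)
  m <- array(as.logical(mask), dim = dim(mask))
  if (min_object_vox > 0 && any(m)) {
    lab <- .label_components(m, 26)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_vox)
    m <- array(lab %in% keep & lab > 0, dim = dim(m))
  }
  offs <- .cube_offsets()
  for (i in seq_len(n_close)) m <- .erode_binary(.dilate_binary(m, offs), offs)
  if (n_dilate_erode > 0) {
    for (i in seq_len(n_dilate_erode)) m <- .dilate_binary(m, offs)
    for (i in seq_len(n_dilate_erode)) m <- .erode_binary(m, offs)
  }
  binary_mask(m, sp)
}

# multi-scale Hessian tubeness: bright curvilinear structures score
# sqrt(|l2 * l3|) where l2, l3 are the two most negative eigenvalues;
# responses are combined across scales by the configured reducer
.tubeness <- function(a, scales, combine = min) {
  d <- dim(a)
  res <- NULL
  for (s in scales) {
    sm <- .as_plain(smooth_stack(volume_image(a), s))
    g <- function(arr, axis) {
      idx <- lapply(d, seq_len)
      up <- idx; dn <- idx
      up[[axis]] <- c(2:d[axis], d[axis])
      dn[[axis]] <- c(1, 1:(d[axis] - 1))
      (do.call(`[`, c(list(arr), up)) - do.call(`[`, c(list(arr), dn))) / 2
    }
    gx <- g(sm, 1); gy <- g(sm, 2); gz <- g(sm, 3)
    hxx <- g(gx, 1); hyy <- g(gy, 2); hzz <- g(gz, 3)
    hxy <- g(gx, 2); hxz <- g(gx, 3); hyz <- g(gy, 3)
    ev <- .sym3_eigenvalues(hxx, hxy, hxz, hyy, hyz, hzz)
    l2 <- ev$mid; l3 <- ev$low      # ascending: low <= mid <= high
    score <- ifelse(l2 < 0 & l3 < 0, sqrt(abs(l2 * l3)) * s^2, 0)
    res <- if (is.null(res)) score else {
      if (identical(combine, min)) pmin(res, score) else pmax(res, score)
    }
  }
  array(res, dim = d)
}

# closed-form eigenvalues of voxel-wise symmetric 3x3 matrices
.sym3_eigenvalues <- function(a11, a12, a13, a22, a23, a33) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 1e-300))
  b11 <- (a11 - q) / p; b12 <- a12 / p; b13 <- a13 / p
  b22 <- (a22 - q) / p; b23 <- a23 / p; b33 <- (a33 - q) / p
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  zero <- p2 == 0
  e1[zero] <- q[zero]; e2[zero] <- q[zero]; e3[zero] <- q[zero]
  list(high = e1, mid = e2, low = e3)
}

#' Segment blood vessels from a fluorescence stack
#'
#' Runs the configured recipe end to end. `fetal`: background subtraction,
#' 3D Gaussian blur, mean threshold (with offset), mask cleanup. `adult`:
#' background subtraction, grayscale closing, multi-scale tubeness
#' enhancement, Li threshold, mask cleanup. A QC warning is raised when the
#' vessel fraction falls outside \[0.1%, 60%\] of the volume.
#'
#' @param stack a [volume_image()].
#' @param config a [segmentation_config()].
#' @return vessel [binary_mask()].
#' @export
segment_vessels <- function(stack, config = segmentation_config()) {
  if (!inherits(config, "segmentation_config"))
    stop("config must be a segmentation_config")
  if (!config$recipe %in% c("adult", "fetal"))
    stop("config$recipe must be 'adult' or 'fetal'")
  sp <- spacing_um(stack)
  if (diff(range(.as_plain(stack))) == 0) {
    warning("QC: constant stack, returning an empty vessel mask")
    return(binary_mask(array(FALSE, dim = dim(stack)), sp))
  }
  x <- subtract_background(stack, config$rolling_ball_radius_vox)
  if (config$recipe == "fetal") {
    x <- smooth_stack(x, config$gaussian_sigma_vox)
    off <- config$threshold_offset
    if (is.null(off)) {
      # half-peak rule: the ridge peak is estimated robustly from the
      # extreme upper tail of the smoothed stack
      a <- .as_plain(x)
      off <- 0.5 * quantile(a, 0.9999, names = FALSE) - mean(a)
    }
    m <- suppressWarnings(binarize(x, "mean", off))
    m <- clean_mask(m, config$min_object_vox, config$n_close,
                    config$n_dilate_erode)
  } else {
    offs <- .ball_offsets(config$closing_radius_vox)
    x <- volume_image(.close_gray(.as_plain(x), offs), sp)
    tb <- .tubeness(.as_plain(x), config$tubeness_scales_vox, min)
    off <- if (is.null(config$threshold_offset)) 0 else config$threshold_offset
    m <- suppressWarnings(binarize(volume_image(tb, sp),
                                   config$threshold_method, off))
    m <- clean_mask(m, config$min_object_vox, config$n_close,
                    config$n_dilate_erode)
  }
  frac <- mean(m)
  if (frac < 0.001 || frac > 0.6)
    warning(sprintf("QC: vessel fraction %.3f%% outside [0.1%%, 60%%]",
                    100 * frac))
  m
}

# fill enclosed background cavities: 3D background not connected to the
# border, plus slice-wise fills along each axis so cavities clipped by the
# stack border are still recovered
.fill_holes <- function(mask) {
  d <- dim(mask)
  filled <- .fill_holes_3d(mask)
  for (axis in 1:3) {
    for (s in seq_len(d[axis])) {
      idx <- lapply(d, seq_len)
      idx[[axis]] <- s
      sl <- do.call(`[`, c(list(mask), idx, list(drop = TRUE)))
      f2 <- .fill_holes_2d(sl)
      cur <- do.call(`[`, c(list(filled), idx, list(drop = TRUE)))
      filled <- do.call(`[<-`, c(list(filled), idx, list(value = cur | f2)))
    }
  }
  filled
}

.fill_holes_3d <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  lab <- .label_components(array(bg, dim = d), 6)
  border_labels <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ],
                            lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
  border_labels <- border_labels[border_labels > 0]
  holes <- bg & !(lab %in% border_labels)
  mask | array(holes, dim = d)
}

.fill_holes_2d <- function(sl) {
  d <- dim(sl)
  m3 <- array(sl, dim = c(d[1], d[2], 1))
  bg <- !m3
  lab <- .label_components(bg, 6)
  border_labels <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ]))
  border_labels <- border_labels[border_labels > 0]
  holes <- bg & !(lab %in% border_labels)
  array(sl | holes[, , 1], dim = d)
}

#' Segment cysts from an autofluorescence stack
#'
#' Parenchyma is bright and cyst lumens are dark holes: the stack is
#' smoothed, Li-thresholded into a tissue mask, holes are filled to obtain
#' the kidney mask, and cysts are detected as the filled kidney minus the
#' tissue. Because Li thresholds sit well below the edge midpoint, the
#' detected cyst boundary is then refined to the half-maximum isovalue
#' between the parenchyma and lumen levels (restricted to the detected
#' cysts' neighbourhood), which makes cyst volumes accurate to a fraction
#' of a voxel. Cyst components touching the stack border are flagged.
#'
#' @param autofluor_stack a [volume_image()] of the autofluorescence channel.
#' @param sigma_vox Gaussian sigma for pre-smoothing.
#' @param refine refine the boundary at the half-maximum isovalue.
#' @return list with `cyst_mask` and `kidney_mask` ([binary_mask()]s);
#'   `attr(cyst_mask, "border_touching")` gives ids of border components.
#' @export
segment_cysts <- function(autofluor_stack, sigma_vox = 1, refine = TRUE) {
  sp <- spacing_um(autofluor_stack)
  sm <- smooth_stack(autofluor_stack, sigma_vox)
  tissue <- binarize(sm, "li")
  if (!any(tissue)) stop("no tissue detected in the autofluorescence stack")
  tis <- array(as.logical(tissue), dim = dim(tissue))
  kidney <- .fill_holes(tis)
  cysts <- kidney & !tis
  if (refine && any(cysts)) {
    a <- .as_plain(sm)
    t_mid <- (median(a[tis & kidney]) + median(a[cysts])) / 2
    near <- .dilate_binary(cysts, .ball_offsets(ceiling(2 * sigma_vox) + 1))
    cysts <- kidney & near & (a < t_mid)
    kidney <- kidney | cysts
  }
  lab <- .label_components(cysts, 26)
  d <- dim(cysts)
  border_ids <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                         lab[, , 1], lab[, , d[3]]))
  border_ids <- sort(border_ids[border_ids > 0])
  cyst_mask <- binary_mask(cysts, sp)
  attr(cyst_mask, "border_touching") <- border_ids
  list(cyst_mask = cyst_mask, kidney_mask = binary_mask(kidney, sp))
}

#' Cyst volumetrics
#'
#' Component-wise cyst volumes (26-connectivity), kidney volume and cyst
#' fraction, all from voxel counts times the physical voxel volume.
#'
#' @param cyst_mask,kidney_mask aligned [binary_mask()]s.
#' @param spacing_um voxel spacing; defaults to the masks' spacing.
#' @return a `cyst_stats` list: `n_cysts`, `volumes_um3`, `mean_volume_um3`,
#'   `sd_volume_um3`, `kidney_volume_um3`, `cyst_fraction`.
#' @export
cyst_statistics <- function(cyst_mask, kidney_mask, spacing_um = NULL) {
  if (is.null(spacing_um)) spacing_um <- spacing_um(cyst_mask)
  .check_spacing(spacing_um)
  if (!identical(dim(cyst_mask), dim(kidney_mask)))
    stop("masks are not aligned")
  vox <- prod(spacing_um)
  kidney_volume <- sum(kidney_mask) * vox
  if (kidney_volume == 0) stop("kidney volume is zero")
  lab <- .label_components(array(as.logical(cyst_mask), dim = dim(cyst_mask)), 26)
  n <- attr(lab, "n_components")
  vols <- if (n > 0) tabulate(lab[lab > 0], nbins = n) * vox else numeric(0)
  structure(list(n_cysts = n, volumes_um3 = vols,
                 mean_volume_um3 = if (n > 0) mean(vols) else NA_real_,
                 sd_volume_um3 = if (n > 1) sd(vols) else NA_real_,
                 kidney_volume_um3 = kidney_volume,
                 cyst_fraction = sum(vols) / kidney_volume),
            class = "cyst_stats")
}
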