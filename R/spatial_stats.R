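#' Per-region and per-vessel fluorescence quantification
#'
#' Works on the maximum-intensity z-projection of the channel: the region
#' mean is taken over the whole projected field, and per-vessel means over
#' the projected centerline of each sampled branch dilated to its radius.
#' Branches are sampled without replacement with a fixed seed.
#'
#' @param channel a [volume_image()] of the marker channel (e.g. SPP1).
#' @param graph the [vessel_graph()] extracted from the same volume.
#' @param n_sample minimum number of branches to sample (uses all, with a
#'   warning, when fewer exist).
#' @param seed RNG seed for branch sampling.
#' @return a `vessel_intensity_report` list: `region_mean_intensity`,
#'   `per_vessel` (data.frame of branch id and mean intensity),
#'   `n_vessels_sampled`, `seed`.
#' @export
vessel_intensity <- function(channel, graph, n_sample = 10, seed = 1) {
  sp <- spacing_um(channel)
  a <- .as_plain(channel)
  d <- dim(a)
  mip <- apply(a, c(1, 2), max)
  nb <- nrow(graph$branches)
  if (nb == 0) stop("graph has no branches")
  if (nb < n_sample) {
    warning("fewer branches (", nb, ") than requested sample (", n_sample,
            "); using all")
    picked <- seq_len(nb)
  } else {
    picked <- .with_seed(seed, sort(sample.int(nb, n_sample)))
  }
  per <- lapply(picked, function(b) {
    pts <- graph$paths[[b]]
    r_um <- graph$branches$mean_radius_um[b]
    pix <- unique(.um_to_vox(pts, sp, d)[, 1:2, drop = FALSE])
    rpix <- c(ceiling(r_um / sp[1]), ceiling(r_um / sp[2]))
    offs <- expand.grid(dx = -rpix[1]:rpix[1], dy = -rpix[2]:rpix[2])
    keep <- (offs$dx * sp[1])^2 + (offs$dy * sp[2])^2 <= r_um^2 + 1e-9
    offs <- as.matrix(offs[keep, , drop = FALSE])
    foot <- unique(do.call(rbind, lapply(seq_len(nrow(pix)), function(i) {
      sweep(offs, 2, pix[i, ], "+")
    })))
    foot <- foot[foot[, 1] >= 1 & foot[, 1] <= d[1] &
                   foot[, 2] >= 1 & foot[, 2] <= d[2], , drop = FALSE]
    mean(mip[foot])
  })
  structure(list(region_mean_intensity = mean(mip),
                 per_vessel = data.frame(branch_id = picked,
                                         mean_intensity = unlist(per)),
                 n_vessels_sampled = length(picked),
                 seed = seed),
            class = "vessel_intensity_report")
}

#' Vessel-to-cyst distance analysis
#'
#' For each vessel representative point (branch centerline midpoint by
#' convention), the Euclidean distance in um to the nearest cyst boundary
#' voxel (a cyst voxel with at least one non-cyst face neighbour), binned
#' at 50 um increments with half-open bins `[0, 50), [50, 100), ...`.
#' "Within 100 um" means distance < 100 um (the first two bins).
#'
#' @param vessel_points n-by-3 matrix of um coordinates, or a
#'   [vessel_graph()] (midpoints of every branch are used).
#' @param cyst_mask nonempty cyst [binary_mask()].
#' @param spacing_um voxel spacing; defaults to the mask's.
#' @param bin_width_um histogram bin width (um).
#' @return a `distance_binning` list: `distances_um`, `counts_per_bin`
#'   (named by bin), `fraction_within_100um`, `bin_width_um`.
#' @export
distance_to_cysts <- function(vessel_points, cyst_mask, spacing_um = NULL,
                              bin_width_um = 50) {
  if (is.null(spacing_um)) spacing_um <- spacing_um(cyst_mask)
  .check_spacing(spacing_um)
  if (!any(cyst_mask)) stop("cyst mask is empty")
  if (inherits(vessel_points, "vessel_graph")) {
    vessel_points <- do.call(rbind, lapply(vessel_points$paths, function(p) {
      p[ceiling(nrow(p) / 2), , drop = FALSE]
    }))
  }
  vessel_points <- as.matrix(vessel_points)
  m <- array(as.logical(cyst_mask), dim = dim(cyst_mask))
  boundary <- m & !.erode_face(m)
  dist_map <- .distance_to(boundary, spacing_um)
  ijk <- .um_to_vox(vessel_points, spacing_um, dim(m))
  dists <- dist_map[.vox_index(ijk, dim(m))]
  edges <- seq(0, max(dists, 100) + bin_width_um, by = bin_width_um)
  bins <- cut(dists, breaks = edges, right = FALSE, include.lowest = FALSE)
  counts <- table(bins)
  structure(list(distances_um = dists,
                 counts_per_bin = counts,
                 fraction_within_100um = mean(dists < 100),
                 bin_width_um = bin_width_um),
            class = "distance_binning")
}

# face (6-neighbourhood) erosion treating out-of-volume as background
.erode_face <- function(m) {
  offs <- matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1),
                 ncol = 3, byrow = TRUE)
  d <- dim(m)
  out <- m
  for (k in seq_len(nrow(offs))) {
    shifted <- array(FALSE, dim = d)
    o <- offs[k, ]
    src <- lapply(1:3, function(a) {
      i <- seq_len(d[a]) + o[a]
      i[i >= 1 & i <= d[a]]
    })
    dst <- lapply(1:3, function(a) {
      i <- seq_len(d[a])
      i[i + o[a] >= 1 & i + o[a] <= d[a]]
    })
    shifted <- do.call(`[<-`, c(list(shifted), dst,
                                list(value = do.call(`[`, c(list(m), src)))))
    out <- out & shifted
  }
  out
}
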