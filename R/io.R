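# File interfaces: multi-page TIFF stacks, JSON sidecars, CSV tables.

#' Write a volume as a multi-page TIFF
#'
#' Each z-slice becomes one 32-bit float page. Spacing is stored in a JSON
#' sidecar (same path with extension `.json`) because baseline TIFF has no
#' standard 3D spacing tag.
#'
#' @param x a [volume_image()] or [binary_mask()] (masks are written 8-bit).
#' @param path output file path (`.tif`).
#' @param sidecar write the JSON sidecar with spacing and provenance.
#' @return the path, invisibly.
#' @export
write_volume_tiff <- function(x, path, sidecar = TRUE) {
  d <- dim(x)
  is_mask <- inherits(x, "binary_mask") || is.logical(x)
  pages <- lapply(seq_len(d[3]), function(k) {
    sl <- matrix(as.numeric(unclass(x)[, , k]), nrow = d[1])
    if (is_mask) sl else sl
  })
  if (is_mask) {
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  } else {
    mx <- max(unlist(lapply(pages, max)), 1)
    pages <- lapply(pages, function(p) p / mx)   # writeTIFF expects [0,1]
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
    attr(path, "scale") <- mx
    if (sidecar)
      jsonlite::write_json(list(spacing_um = spacing_um(x), scale = mx,
                                shape = d),
                           paste0(tools::file_path_sans_ext(path), ".json"),
                           auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  if (sidecar)
    jsonlite::write_json(list(spacing_um = spacing_um(x), scale = 1,
                              shape = d),
                         paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_volume_tiff()]
#'
#' @param path TIFF path; the JSON sidecar is consulted for spacing and
#'   intensity scale when present.
#' @param spacing_um fallback spacing when no sidecar exists.
#' @return a [volume_image()].
#' @export
read_volume_tiff <- function(path, spacing_um = c(1, 1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- 1
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    spacing_um <- meta$spacing_um
    if (!is.null(meta$scale)) scale <- meta$scale
  }
  d1 <- dim(pages[[1]])
  arr <- array(0, dim = c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * scale
  volume_image(arr, spacing_um)
}

#' Write a phantom (stack, truth sidecar) to disk
#'
#' The stack goes to a multi-page TIFF; the ground truth (graph node/edge
#' lists with um coordinates, loop count, volumes, spec echo) to a JSON
#' sidecar named `<stem>_truth.json`.
#'
#' @param phantom output of [generate_vessel_phantom()] or
#'   [generate_cyst_phantom()].
#' @param stem output path stem (no extension).
#' @param spec optional spec echoed into the sidecar.
#' @return list of written paths, invisibly.
#' @export
write_phantom <- function(phantom, stem, spec = NULL) {
  tif <- paste0(stem, ".tif")
  write_volume_tiff(phantom$stack, tif)
  tr <- phantom$truth
  truth <- list(loop_count = tr$loop_count,
                cyst_volumes_um3 = tr$cyst_volumes_um3,
                tissue_volume_um3 = tr$tissue_volume_um3,
                spacing_um = spacing_um(phantom$stack),
                spec = spec)
  if (!is.null(tr$graph)) {
    truth$nodes <- tr$graph$nodes
    truth$branches <- tr$graph$branches
  }
  js <- paste0(stem, "_truth.json")
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(list(tiff = tif, truth = js))
}

#' Export a vessel graph as JSON and CSV
#'
#' @param graph a [vessel_graph()].
#' @param stem path stem; writes `<stem>_graph.json` (node/edge lists) and
#'   `<stem>_branches.csv` (per-branch table).
#' @return written paths, invisibly.
#' @export
export_graph <- function(graph, stem) {
  js <- paste0(stem, "_graph.json")
  csv <- paste0(stem, "_branches.csv")
  jsonlite::write_json(list(nodes = graph$nodes, branches = graph$branches,
                            spacing_um = attr(graph, "spacing_um")),
                       js, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  write.csv(graph$branches, csv, row.names = FALSE)
  invisible(list(json = js, csv = csv))
}

#' Export a persistence diagram as CSV
#'
#' @param diagram a `persistence_diagram`.
#' @param path CSV path; infinite deaths are written as `Inf`.
#' @return the path, invisibly.
#' @export
export_diagram <- function(diagram, path) {
  write.csv(as.data.frame(diagram), path, row.names = FALSE)
  invisible(path)
}
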