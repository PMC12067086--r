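#' Create a 3D volume image
#'
#' A `volume_image` is a numeric 3D array (one channel) carrying per-axis
#' voxel spacing in micrometres. Voxel `(i, j, k)` has its centre at
#' physical position `((i-1)*sx, (j-1)*sy, (k-1)*sz)` um.
#'
#' @param data numeric 3D array.
#' @param spacing_um length-3 numeric, voxel spacing in um per axis
#'   (may be anisotropic).
#' @return A `volume_image` object.
#' @export
volume_image <- function(data, spacing_um = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume_image requires a 3D array")
  .check_spacing(spacing_um)
  storage.mode(data) <- "double"
  structure(data, spacing_um = as.numeric(spacing_um),
            class = c("volume_image", "array"))
}

#' Create a 3D binary mask
#'
#' @param data logical 3D array (numeric input is coerced with `!= 0`).
#' @param spacing_um length-3 numeric voxel spacing in um.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, spacing_um = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("binary_mask requires a 3D array")
  .check_spacing(spacing_um)
  if (!is.logical(data)) {
    d <- array(data != 0, dim = dim(data))
    data <- d
  }
  structure(data, spacing_um = as.numeric(spacing_um),
            class = c("binary_mask", "array"))
}

#' Voxel spacing of a volume or mask
#' @param x a `volume_image`, `binary_mask` or array with a spacing attribute.
#' @return numeric length-3 spacing in um (defaults to 1 um isotropic).
#' @export
spacing_um <- function(x) {
  s <- attr(x, "spacing_um")
  if (is.null(s)) c(1, 1, 1) else s
}

#' Physical volume of one voxel in cubic micrometres
#' @param x object with voxel spacing.
#' @return scalar voxel volume in um^3.
#' @export
voxel_volume_um3 <- function(x) prod(spacing_um(x))

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume_image> %d x %d x %d voxels, spacing (%s) um, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(spacing_um(x), 4), collapse = ", "),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, spacing (%s) um, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], paste(signif(spacing_um(x), 4), collapse = ", "),
              sum(x), 100 * mean(x)))
  invisible(x)
}

.check_spacing <- function(spacing_um) {
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) ||
      any(spacing_um <= 0))
    stop("spacing_um must be 3 positive finite values")
  invisible(TRUE)
}

# strip class/attrs down to a plain array (fast paths)
.as_plain <- function(x) {
  a <- unclass(x)
  attr(a, "spacing_um") <- NULL
  a
}
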