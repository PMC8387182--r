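#' Cartesian volume container
#'
#' A 3D scalar grid with isotropic or per-axis physical spacing in mm.
#' The array is indexed `vol[x, y, z]`; voxel `(i, j, k)` (1-based) sits at
#' physical position `(i - 1, j - 1, k - 1) * spacing` mm.
#'
#' @param data numeric 3D array (a 2D matrix is promoted to shape
#'   `c(nrow, ncol, 1)`).
#' @param spacing physical voxel size in mm, length 1 or 3.
#' @return object of class `cartesian_volume` (an array with a `spacing`
#'   attribute).
#' @export
cartesian_volume <- function(data, spacing = 1) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    config_error("volume data must be a 2D matrix or 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    config_error("spacing must be positive, length 1 or 3")
  structure(data, spacing = spacing, class = c("cartesian_volume", "array"))
}

#' @export
print.cartesian_volume <- function(x, ...) {
  d <- dim(x)
  sp <- attr(x, "spacing")
  cat(sprintf("<cartesian_volume> %d x %d x %d voxels, spacing %s mm, range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(sp, 4), collapse = " x "),
              min(x), max(x)))
  invisible(x)
}

vol_spacing <- function(vol) {
  sp <- attr(vol, "spacing")
  if (is.null(sp)) rep(1, 3) else sp
}

vol_data <- function(vol) {
  d <- dim(vol)
  array(as.numeric(vol), dim = d)
}

as_volume_like <- function(data, template) {
  cartesian_volume(data, vol_spacing(template))
}

#' Quantize a real-valued volume to integer gray levels
#'
#' Rounds to the nearest level and clamps to `[0, gray_levels - 1]`.
#'
#' @param vol `cartesian_volume` or numeric array.
#' @param gray_levels number of levels (default 256).
#' @return volume of the same shape with integer-valued entries.
#' @export
quantize_volume <- function(vol, gray_levels = 256) {
  q <- pmin(pmax(round(as.numeric(vol)), 0), gray_levels - 1)
  out <- array(q, dim = dim(vol))
  if (inherits(vol, "cartesian_volume")) out <- as_volume_like(out, vol)
  out
}
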