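# Scan conversion of rotational slice stacks and full-volume wedge assembly.

#' Polar-to-Cartesian scan conversion
#'
#' Reconstructs a Cartesian volume from a rotational slice stack. For each
#' output voxel the signed radius `R` and argument `alpha` about the central
#' depth axis are computed, the two bracketing slice angles found (wrapping at
#' 180 degrees with the radius sign flipped, since the plane at 0 degrees is
#' the mirrored plane at 180), and the value is obtained by bilinear
#' interpolation in (angle, radius). Depth rows are shared by all slices, so
#' `z` maps index-exactly. A stack of `W x D` slices yields a `W x W x D`
#' volume; voxels beyond the scanned disc radius `(W - 1) / 2` are 0.
#'
#' @param stack a `slice_stack` with at least 2 slices at a uniform angular
#'   step.
#' @return a `cartesian_volume` of shape `W x W x D`.
#' @export
scan_convert <- function(stack) {
  stopifnot(inherits(stack, "slice_stack"))
  d <- dim(stack$slices)
  if (d[3] < 2L) config_error("scan conversion needs at least 2 slices")
  steps <- diff(stack$angles)
  if (max(abs(steps - steps[1])) > 1e-9)
    config_error("slice angles must be uniformly spaced")
  vol <- cpp_scan_convert(stack$slices, d, steps[1])
  cartesian_volume(vol, stack$spacing)
}

#' Assemble full-volume wedges into one pyramidal volume
#'
#' Averages the four 15-degree wedges on their common grid: voxels covered by
#' one wedge take its value, seam voxels covered by two wedges are averaged,
#' uncovered voxels are 0.
#'
#' @param wedges a `wedge_set` with exactly 4 wedges.
#' @return list with `volume` (a `cartesian_volume`) and `coverage` (integer
#'   array counting contributing wedges per voxel).
#' @export
assemble_wedges <- function(wedges) {
  stopifnot(inherits(wedges, "wedge_set"))
  if (length(wedges$wedges) != 4L)
    config_error("expected exactly 4 wedges, got %d", length(wedges$wedges))
  d <- dim(wedges$wedges[[1]]$volume)
  acc <- array(0, dim = d)
  cov <- array(0L, dim = d)
  for (w in wedges$wedges) {
    if (!identical(dim(w$volume), d))
      config_error("wedges disagree on grid shape")
    m <- w$mask
    acc <- acc + vol_data(w$volume) * m
    cov <- cov + m
  }
  out <- acc
  nz <- cov > 0L
  out[nz] <- acc[nz] / cov[nz]
  list(volume = cartesian_volume(out, wedges$spacing), coverage = cov)
}
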