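# Digital heart phantom with a parameterized atrial septal defect, plus the
# two acquisition simulators (rotational-probe TTO and four-wedge full
# volume).  The phantom stands in for the ex vivo ASD specimens used to
# validate virtual measurement: two blood-filled hemispherical chambers
# separated by a planar septum slab carrying an elliptical through-hole.

PHANTOM_BACKGROUND <- 0L
PHANTOM_MYOCARDIUM <- 1L
PHANTOM_BLOOD <- 2L

#' Phantom specification
#'
#' Describes the ground-truth geometry: a spherical blood pool (the two
#' "atria") inside a myocardial shell, split by a planar septum slab of given
#' normal, offset and thickness. The septum carries an elliptical through-hole
#' (the defect) with major/minor axes `defect_long`/`defect_short` in mm,
#' rotated by `defect_angle` degrees within the septum plane.
#'
#' @param grid_shape integer voxel counts `(nx, ny, nz)`.
#' @param spacing isotropic voxel size, mm.
#' @param chamber_radius radius of the blood pool, mm.
#' @param wall_thickness myocardial shell thickness, mm.
#' @param septum_normal direction of the septum normal (normalized internally).
#' @param septum_offset signed distance of the septum mid-plane from the
#'   chamber centre along the normal, mm.
#' @param septum_thickness slab thickness, mm.
#' @param defect_long,defect_short ellipse major and minor axes, mm. Zero
#'   means an intact septum.
#' @param defect_angle in-plane orientation of the major axis, degrees.
#' @param intensity_myocardium,intensity_blood gray levels in `[0, 255]`.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(120L, 120L, 64L),
                         spacing = 0.5,
                         chamber_radius = 12,
                         wall_thickness = 3,
                         septum_normal = c(1, 0, 0),
                         septum_offset = 0,
                         septum_thickness = 2,
                         defect_long = 10,
                         defect_short = 7,
                         defect_angle = 0,
                         intensity_myocardium = 180,
                         intensity_blood = 30) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    config_error("grid_shape must be three integers >= 2")
  if (defect_short > defect_long)
    config_error("defect_short (%g) must not exceed defect_long (%g)",
                 defect_short, defect_long)
  if (defect_long < 0 || defect_short < 0)
    config_error("defect axes must be non-negative")
  ints <- c(intensity_myocardium, intensity_blood)
  if (any(ints < 0) || any(ints > 255))
    config_error("intensities must lie in [0, 255]")
  n <- as.numeric(septum_normal)
  nn <- sqrt(sum(n^2))
  if (length(n) != 3L || nn == 0)
    config_error("septum_normal must be a nonzero 3-vector")
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 chamber_radius = chamber_radius,
                 wall_thickness = wall_thickness,
                 septum_normal = n / nn,
                 septum_offset = septum_offset,
                 septum_thickness = septum_thickness,
                 defect_long = defect_long, defect_short = defect_short,
                 defect_angle = defect_angle,
                 intensity_myocardium = intensity_myocardium,
                 intensity_blood = intensity_blood),
            class = "phantom_spec")
}

#' Acquisition configuration
#'
#' Parameters of the ultrasound acquisition simulators. The rotational probe
#' sweeps 360 degrees in steps of 1, 2 or 3 degrees, producing 180, 90 or 60
#' full-diameter slices of `slice_width x slice_depth` pixels quantized to
#' `gray_levels` levels. Speckle is multiplicative mean-one noise of scale
#' `speckle_sigma`; `impulse_prob` is the per-pixel salt-and-pepper rate.
#' `jitter` (voxels) models inter-cycle misalignment of full-volume wedges.
#'
#' @param angular_step degrees per rotation step, one of 1, 2, 3.
#' @param slice_width,slice_depth slice raster in pixels.
#' @param gray_levels quantization levels (default 256).
#' @param speckle_sigma multiplicative noise scale (0 disables).
#' @param impulse_prob salt-and-pepper probability (0 disables).
#' @param jitter per-wedge rigid translation scale in voxels (0 disables).
#' @param seed integer seed for the simulator noise; `NULL` uses the session
#'   RNG stream.
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(angular_step = 1, slice_width = 240L,
                               slice_depth = 128L, gray_levels = 256L,
                               speckle_sigma = 0.2, impulse_prob = 0.01,
                               jitter = 0, seed = NULL) {
  if (!angular_step %in% c(1, 2, 3))
    config_error("angular_step must be 1, 2 or 3 degrees (got %g)", angular_step)
  stopifnot(180 %% angular_step == 0)
  if (gray_levels < 2) config_error("gray_levels must be >= 2")
  if (speckle_sigma < 0 || impulse_prob < 0 || impulse_prob > 1)
    config_error("invalid noise parameters")
  structure(list(angular_step = angular_step,
                 slice_width = as.integer(slice_width),
                 slice_depth = as.integer(slice_depth),
                 gray_levels = as.integer(gray_levels),
                 speckle_sigma = speckle_sigma, impulse_prob = impulse_prob,
                 jitter = jitter, seed = seed),
            class = "acquisition_config")
}

# Evaluate code with a locally-set seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Deterministic orthonormal in-plane basis for a unit normal.
plane_basis <- function(n) {
  a <- if (abs(n[1]) <= abs(n[2]) && abs(n[1]) <= abs(n[3])) c(1, 0, 0)
       else if (abs(n[2]) <= abs(n[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- c(n[2] * a[3] - n[3] * a[2],
          n[3] * a[1] - n[1] * a[3],
          n[1] * a[2] - n[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

phantom_center <- function(spec) (spec$grid_shape - 1) / 2 * spec$spacing

#' Septum plane of a phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `point` (mm), `normal` (unit vector) and `thickness` (mm),
#'   usable as the `septum_plane` argument of [extract_rim()].
#' @export
phantom_septum_plane <- function(spec) {
  ctr <- phantom_center(spec)
  list(point = ctr + spec$septum_offset * spec$septum_normal,
       normal = spec$septum_normal, thickness = spec$septum_thickness)
}

#' Ground-truth defect metrics of a phantom
#'
#' @param spec a [phantom_spec()].
#' @return data.frame with `long_diameter`, `short_diameter` (mm) and
#'   `area` (mm^2) of the specified elliptical defect.
#' @export
phantom_true_metrics <- function(spec) {
  data.frame(long_diameter = spec$defect_long,
             short_diameter = spec$defect_short,
             area = pi * spec$defect_long / 2 * spec$defect_short / 2)
}

#' Generate a ground-truth heart phantom
#'
#' Builds the intensity volume and the voxel label volume (0 background,
#' 1 myocardium, 2 blood). The septum slab splits the blood pool; when the
#' defect axes are positive an elliptical through-hole connects the two
#' chambers. Output is deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @param seed accepted for interface symmetry with the simulators; the
#'   geometry is noise-free so the seed has no effect.
#' @return list with `volume` and `labels`, both `cartesian_volume`s.
#' @export
generate_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$defect_long > 0 && spec$defect_long / 2 >= spec$chamber_radius)
    geometry_error("defect (long axis %g mm) does not fit inside the septum extent (chamber radius %g mm)",
                   spec$defect_long, spec$chamber_radius)
  g <- spec$grid_shape
  sp <- spec$spacing
  ctr <- phantom_center(spec)
  xs <- (seq_len(g[1]) - 1) * sp - ctr[1]
  ys <- (seq_len(g[2]) - 1) * sp - ctr[2]
  zs <- (seq_len(g[3]) - 1) * sp - ctr[3]
  X <- array(xs, dim = g)
  Y <- array(rep(ys, each = g[1]), dim = g)
  Z <- array(rep(zs, each = g[1] * g[2]), dim = g)
  r2 <- X^2 + Y^2 + Z^2
  r_in <- spec$chamber_radius
  r_out <- spec$chamber_radius + spec$wall_thickness

  labels <- array(PHANTOM_BACKGROUND, dim = g)
  labels[r2 <= r_out^2] <- PHANTOM_MYOCARDIUM
  labels[r2 <= r_in^2] <- PHANTOM_BLOOD

  n <- spec$septum_normal
  sdot <- X * n[1] + Y * n[2] + Z * n[3] - spec$septum_offset
  in_slab <- abs(sdot) <= spec$septum_thickness / 2 & r2 <= r_in^2
  labels[in_slab] <- PHANTOM_MYOCARDIUM

  if (spec$defect_long > 0 && spec$defect_short > 0) {
    b <- plane_basis(n)
    off <- spec$septum_offset
    U <- (X - off * n[1]) * b$e1[1] + (Y - off * n[2]) * b$e1[2] +
      (Z - off * n[3]) * b$e1[3]
    V <- (X - off * n[1]) * b$e2[1] + (Y - off * n[2]) * b$e2[2] +
      (Z - off * n[3]) * b$e2[3]
    psi <- spec$defect_angle * pi / 180
    Ur <- U * cos(psi) + V * sin(psi)
    Vr <- -U * sin(psi) + V * cos(psi)
    a <- spec$defect_long / 2
    bb <- spec$defect_short / 2
    in_hole <- in_slab & ((Ur / a)^2 + (Vr / bb)^2 <= 1)
    labels[in_hole] <- PHANTOM_BLOOD
  }

  vol <- array(0, dim = g)
  vol[labels == PHANTOM_MYOCARDIUM] <- spec$intensity_myocardium
  vol[labels == PHANTOM_BLOOD] <- spec$intensity_blood
  list(volume = cartesian_volume(vol, sp),
       labels = cartesian_volume(labels, sp))
}

# Multiplicative mean-one speckle, then salt-and-pepper impulses, then
# quantization -- applied in this order to an array of noise-free samples.
apply_us_noise <- function(x, cfg) {
  if (cfg$speckle_sigma > 0) {
    n <- 1 + cfg$speckle_sigma * stats::rnorm(length(x))
    x <- x * pmax(0, n)
  }
  if (cfg$impulse_prob > 0) {
    hit <- stats::runif(length(x)) < cfg$impulse_prob
    salt <- stats::runif(length(x)) < 0.5
    x[hit & salt] <- cfg$gray_levels - 1
    x[hit & !salt] <- 0
  }
  pmin(pmax(round(x), 0), cfg$gray_levels - 1)
}

#' Simulate a rotational-probe (TTO) acquisition
#'
#' The probe plane rotates about the central depth axis of the volume in
#' steps of `angular_step` degrees; 180/angular_step full-diameter planar
#' slices cover the full revolution. Each slice is trilinearly resampled from
#' the volume, corrupted by multiplicative speckle and impulse noise, and
#' quantized to `gray_levels` integer levels.
#'
#' @param volume a `cartesian_volume`.
#' @param cfg an [acquisition_config()].
#' @return object of class `slice_stack`: `slices` (width x depth x n array),
#'   `angles` (degrees), `spacing`, `gray_levels`.
#' @export
simulate_tto <- function(volume, cfg = acquisition_config()) {
  stopifnot(inherits(cfg, "acquisition_config"))
  d <- dim(volume)
  if (d[3] < cfg$slice_depth)
    config_error("volume depth %d < slice_depth %d", d[3], cfg$slice_depth)
  n_slices <- 180L %/% as.integer(cfg$angular_step)
  angles <- (seq_len(n_slices) - 1) * cfg$angular_step
  W <- cfg$slice_width
  D <- cfg$slice_depth
  slices <- array(0, dim = c(W, D, n_slices))
  vd <- vol_data(volume)
  for (s in seq_len(n_slices)) {
    slices[, , s] <- cpp_extract_slice(vd, d, angles[s], W, D, 0, 0, 0)
  }
  slices <- with_local_seed(cfg$seed, {
    array(apply_us_noise(slices, cfg), dim = dim(slices))
  })
  structure(list(slices = slices, angles = angles,
                 spacing = vol_spacing(volume),
                 gray_levels = cfg$gray_levels),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<slice_stack> %d slices of %d x %d px, step %g deg\n",
              d[3], d[1], d[2], if (d[3] > 1) diff(x$angles[1:2]) else NA))
  invisible(x)
}

WEDGE_RANGES <- list(c(0, 15), c(15, 30), c(30, 45), c(45, 60))

#' Simulate a full-volume (four-wedge) acquisition
#'
#' Partitions the 0-60 degree azimuthal field of view into four fixed
#' 15-degree wedges ("melon petals"), acquired on consecutive cardiac cycles:
#' each wedge gets independent noise and, when `cfg$jitter > 0`, an
#' independent rigid translation emulating inter-cycle misalignment.
#'
#' @param volume a `cartesian_volume`.
#' @param cfg an [acquisition_config()].
#' @return object of class `wedge_set`; each wedge holds `volume` (masked to
#'   its azimuth range), `range` (degrees) and logical coverage `mask`.
#' @export
simulate_full_volume <- function(volume, cfg = acquisition_config()) {
  stopifnot(inherits(cfg, "acquisition_config"))
  d <- dim(volume)
  vd <- vol_data(volume)
  wedges <- with_local_seed(cfg$seed, {
    lapply(WEDGE_RANGES, function(rg) {
      mask <- cpp_azimuth_mask(d, rg[1], rg[2])
      wv <- vd
      if (cfg$jitter > 0) {
        shift <- stats::rnorm(3, sd = cfg$jitter)
        idx <- as.matrix(expand.grid(x = seq_len(d[1]) - 1,
                                     y = seq_len(d[2]) - 1,
                                     z = seq_len(d[3]) - 1))
        idx <- sweep(idx, 2, shift, "+")
        wv <- array(cpp_sample_points(vd, d, idx, FALSE), dim = d)
      }
      wv <- array(apply_us_noise(wv, cfg), dim = d)
      wv[!mask] <- 0
      list(volume = as_volume_like(wv, volume), range = rg,
           mask = array(mask, dim = d))
    })
  })
  structure(list(wedges = wedges, spacing = vol_spacing(volume)),
            class = "wedge_set")
}

#' @export
print.wedge_set <- function(x, ...) {
  cat(sprintf("<wedge_set> %d wedges: %s deg\n", length(x$wedges),
              paste(vapply(x$wedges, function(w)
                paste(w$range, collapse = "-"), ""), collapse = ", ")))
  invisible(x)
}
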