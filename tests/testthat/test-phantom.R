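# Phantom geometry and the two acquisition simulators.

test_that("defect hole area matches the ellipse closed form and refines with resolution", {
  # 10 mm circular defect: voxel-counted mid-plane area within 5% of pi*5^2
  spec <- phantom_spec(defect_long = 10, defect_short = 10)
  ph <- generate_phantom(spec)
  g <- spec$grid_shape
  mid <- round((g[1] - 1) / 2) + 1
  area <- sum(ph$labels[mid, , ] == 2) * spec$spacing^2
  expect_lt(abs(area / (pi * 25) - 1), 0.05)

  # voxelization error decreases (at least halves) as spacing halves
  err_at <- function(spacing, n) {
    sp <- phantom_spec(grid_shape = n, spacing = spacing,
                       defect_long = 9, defect_short = 7)
    lb <- generate_phantom(sp)$labels
    mid <- round((n[1] - 1) / 2) + 1
    abs(sum(lb[mid, , ] == 2) * spacing^2 - pi * 4.5 * 3.5)
  }
  e1 <- err_at(1.0, c(60L, 60L, 32L))
  e2 <- err_at(0.5, c(120L, 120L, 64L))
  expect_lte(e2, e1 / 2 + 1e-9)
})

test_that("degenerate defect leaves the septum intact and pools disconnected", {
  spec <- phantom_spec(defect_long = 0, defect_short = 0)
  ph <- generate_phantom(spec)
  n <- spec$septum_normal
  g <- coord_grids(spec$grid_shape, spec$spacing)
  sdot <- g$X * n[1] + g$Y * n[2] + g$Z * n[3] - spec$septum_offset
  in_slab <- abs(sdot) <= spec$septum_thickness / 2
  expect_false(any(ph$labels[in_slab] == 2))
  rim <- extract_rim(as.array(ph$labels) == 2, phantom_septum_plane(spec),
                     "left_atrial", spacing = spec$spacing)
  expect_false(rim$found)
})

test_that("phantom generation is deterministic and validates geometry", {
  spec <- phantom_spec(grid_shape = c(40L, 40L, 24L))
  expect_identical(generate_phantom(spec)$volume, generate_phantom(spec)$volume)
  expect_error(generate_phantom(phantom_spec(defect_long = 30, defect_short = 10)),
               class = "echoasd_geometry_error")
  expect_error(phantom_spec(defect_long = 5, defect_short = 8),
               class = "echoasd_config_error")
  expect_error(phantom_spec(intensity_blood = 300),
               class = "echoasd_config_error")
})

test_that("rotational acquisition emits 180/90/60 slices at 1/2/3 degree steps", {
  spec <- phantom_spec(grid_shape = c(48L, 48L, 24L))
  vol <- generate_phantom(spec)$volume
  for (step in c(1, 2, 3)) {
    cfg <- acquisition_config(angular_step = step, slice_width = 48,
                              slice_depth = 24, speckle_sigma = 0,
                              impulse_prob = 0)
    st <- simulate_tto(vol, cfg)
    expect_equal(dim(st$slices)[3], 180 / step)
  }
  expect_error(acquisition_config(angular_step = 5),
               class = "echoasd_config_error")
})

test_that("noiseless acquisition of a constant volume reproduces the constant", {
  vol <- cartesian_volume(array(77, c(32, 32, 16)), 1)
  cfg <- acquisition_config(angular_step = 3, slice_width = 20,
                            slice_depth = 16, speckle_sigma = 0,
                            impulse_prob = 0)
  st <- simulate_tto(vol, cfg)
  expect_true(all(st$slices == 77))
})

test_that("simulator outputs are integers in [0, gray_levels - 1] and seed-reproducible", {
  spec <- phantom_spec(grid_shape = c(40L, 40L, 24L))
  vol <- generate_phantom(spec)$volume
  cfg <- acquisition_config(angular_step = 3, slice_width = 40,
                            slice_depth = 24, speckle_sigma = 0.3,
                            impulse_prob = 0.05, seed = 11)
  st1 <- simulate_tto(vol, cfg)
  st2 <- simulate_tto(vol, cfg)
  expect_identical(st1$slices, st2$slices)
  expect_true(all(st1$slices == round(st1$slices)))
  expect_gte(min(st1$slices), 0)
  expect_lte(max(st1$slices), 255)
  wg <- simulate_full_volume(vol, cfg)
  wg2 <- simulate_full_volume(vol, cfg)
  expect_identical(wg$wedges[[2]]$volume, wg2$wedges[[2]]$volume)
})

test_that("full-volume acquisition emits 4 wedges that tile the 0-60 sector", {
  spec <- phantom_spec(grid_shape = c(40L, 40L, 24L))
  vol <- generate_phantom(spec)$volume
  cfg <- acquisition_config(speckle_sigma = 0, impulse_prob = 0, jitter = 0)
  wg <- simulate_full_volume(vol, cfg)
  expect_length(wg$wedges, 4L)
  expect_equal(lapply(wg$wedges, `[[`, "range"),
               list(c(0, 15), c(15, 30), c(30, 45), c(45, 60)))
  asm <- assemble_wedges(wg)
  covered <- asm$coverage > 0
  expect_true(all(asm$volume[covered] == as.array(vol)[covered]))
})

test_that("wedge jitter produces a strictly positive seam discontinuity", {
  spec <- phantom_spec(grid_shape = c(40L, 40L, 24L))
  vol <- generate_phantom(spec)$volume
  seam_gap <- function(jitter) {
    cfg <- acquisition_config(speckle_sigma = 0, impulse_prob = 0,
                              jitter = jitter, seed = 3)
    wg <- simulate_full_volume(vol, cfg)
    seam <- wg$wedges[[1]]$mask & wg$wedges[[2]]$mask
    mean(abs(wg$wedges[[1]]$volume[seam] - wg$wedges[[2]]$volume[seam]))
  }
  expect_equal(seam_gap(0), 0)
  expect_gt(seam_gap(1.5), 0)
})
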