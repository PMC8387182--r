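# Polar-to-Cartesian scan conversion and wedge assembly.

test_that("default-geometry stacks reconstruct to 240 x 240 x 128", {
  f <- function(x, y, z) 100 + 50 * cos(pi * sqrt(x^2 + y^2) / 240)
  st <- analytic_stack(f, W = 240, D = 128, step = 2)
  vol <- scan_convert(st)
  expect_equal(dim(vol), c(240L, 240L, 128L))
})

test_that("scan conversion is exact on angularly constant inputs", {
  st <- analytic_stack(function(x, y, z) 0 * x + 42, W = 33, D = 8, step = 3)
  vol <- scan_convert(st)
  half <- (33 - 1) / 2
  xs <- (seq_len(33) - 1) - half
  disc <- array(sqrt(outer(xs^2, xs^2, "+")) <= half, dim = dim(vol))
  expect_true(all(vol[disc] == 42))
  expect_true(all(vol[!disc] == 0))
})

test_that("scan conversion matches a rotationally symmetric oracle within 2 gray levels", {
  g <- function(x, y, z) {
    R <- sqrt(x^2 + y^2)
    120 + 80 * cos(pi * R / 40) * (0.5 + z / 40)
  }
  st <- analytic_stack(g, W = 61, D = 20, step = 1)
  vol <- scan_convert(st)
  oracle <- analytic_volume(g, W = 61, D = 20)
  expect_lte(max(abs(vol - oracle)), 2)
})

test_that("reconstruction error decreases monotonically at finer angular steps", {
  # off-axis Gaussian blob: genuinely angle-dependent, known in closed form
  f <- function(x, y, z) 200 * exp(-((x - 8)^2 + (y - 3)^2) / 60) + 20
  oracle <- analytic_volume(f, W = 49, D = 6)
  errs <- vapply(c(3, 2, 1), function(step) {
    vol <- scan_convert(analytic_stack(f, W = 49, D = 6, step = step))
    max(abs(vol - oracle))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("interpolation keeps output intensities inside the input range", {
  set.seed(4)
  slices <- array(runif(31 * 6 * 60, 10, 90), c(31, 6, 60))
  st <- structure(list(slices = slices, angles = seq(0, 177, by = 3),
                       spacing = rep(1, 3), gray_levels = 256L),
                  class = "slice_stack")
  vol <- scan_convert(st)
  inside <- vol != 0   # outside-disc fill is 0 by contract
  expect_gte(min(vol[inside]), 10)
  expect_lte(max(vol), 90)
})

test_that("scan conversion rejects malformed stacks", {
  st <- analytic_stack(function(x, y, z) x * 0 + 1, W = 21, D = 4, step = 3)
  st$angles[3] <- st$angles[3] + 0.5
  expect_error(scan_convert(st), class = "echoasd_config_error")
  one <- structure(list(slices = array(1, c(21, 4, 1)), angles = 0,
                        spacing = rep(1, 3), gray_levels = 256L),
                   class = "slice_stack")
  expect_error(scan_convert(one), class = "echoasd_config_error")
})

test_that("wedge assembly averages seams and rejects wrong wedge counts", {
  d <- c(8L, 8L, 2L)
  mk <- function(val, mask) list(volume = cartesian_volume(array(val, d), 1),
                                 range = c(0, 15), mask = mask)
  m1 <- array(FALSE, d); m1[1:5, , ] <- TRUE
  m2 <- array(FALSE, d); m2[4:8, , ] <- TRUE
  m0 <- array(FALSE, d)
  ws <- structure(list(wedges = list(mk(10, m1), mk(20, m2), mk(0, m0),
                                     mk(0, m0)), spacing = rep(1, 3)),
                  class = "wedge_set")
  asm <- assemble_wedges(ws)
  expect_equal(asm$volume[1, 1, 1], 10)
  expect_equal(asm$volume[8, 1, 1], 20)
  expect_equal(asm$volume[4, 1, 1], 15)   # covered by both -> average
  expect_equal(asm$volume[5, 1, 1], 15)
  ws$wedges <- ws$wedges[1:3]
  expect_error(assemble_wedges(ws), class = "echoasd_config_error")
})
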