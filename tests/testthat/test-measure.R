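# Surface extraction, rim extraction, and defect morphometry.

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  t(apply(e, 1, sort))
}

test_that("sphere surface area is within 3% of the closed form", {
  n <- 48; sp <- 0.5; r <- 10
  g <- coord_grids(c(n, n, n), sp)
  mask <- (g$X^2 + g$Y^2 + g$Z^2) <= r^2
  mesh <- marching_cubes(mask, spacing = sp)
  expect_lt(abs(mesh_surface_area(mesh) / (4 * pi * r^2) - 1), 0.03)
})

test_that("extracted surfaces are watertight with Euler characteristic 2", {
  n <- 24
  g <- coord_grids(c(n, n, n), 1)
  mask <- (g$X^2 + g$Y^2 + g$Z^2) <= 8^2
  mesh <- marching_cubes(mask, spacing = 1)
  ed <- mesh_edges(mesh)
  counts <- table(paste(ed[, 1], ed[, 2]))
  expect_true(all(counts == 2))            # watertight
  n_edges <- length(counts)
  expect_equal(nrow(mesh$vertices) - n_edges + nrow(mesh$faces), 2)
})

test_that("a single isolated voxel yields a small closed surface", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  mesh <- marching_cubes(m, spacing = 1)
  expect_gt(nrow(mesh$faces), 0)
  ed <- mesh_edges(mesh)
  expect_true(all(table(paste(ed[, 1], ed[, 2])) == 2))
  expect_error(marching_cubes(array(FALSE, c(4, 4, 4)), spacing = 1),
               class = "echoasd_geometry_error")
})

test_that("phantom rim lies on the true circle within one voxel", {
  spec <- phantom_spec(defect_long = 10, defect_short = 10)
  ph <- generate_phantom(spec)
  plane <- phantom_septum_plane(spec)
  rim <- extract_rim(as.array(ph$labels) == 2, plane, "left_atrial",
                     spacing = spec$spacing)
  expect_true(rim$found)
  expect_gte(nrow(rim$points), 16)
  radii <- sqrt(rowSums(sweep(rim$points, 2, rim$plane$point)^2))
  expect_true(all(abs(radii - 5) <= spec$spacing))
  expect_lte(rim$planarity, spec$spacing)
})

test_that("defect metrics recover circle and ellipse closed forms", {
  mk_rim <- function(a, b, n = 128) {
    t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    pts <- cbind(a * cos(t) + 4, b * sin(t) - 1, rep(2, n))
    structure(list(found = TRUE, points = pts,
                   plane = list(point = c(4, -1, 2), normal = c(0, 0, 1)),
                   face = "left_atrial", planarity = 0),
              class = "defect_rim")
  }
  mc <- defect_metrics(mk_rim(5, 5))
  expect_lt(abs(mc$long_diameter - 10), 0.1)
  expect_lt(abs(mc$short_diameter - 10), 0.1)
  expect_lt(abs(mc$area / (pi * 25) - 1), 0.05)
  me <- defect_metrics(mk_rim(6, 3))
  expect_lt(abs(me$long_diameter - 12), 0.1)
  expect_lt(abs(me$short_diameter - 6), 0.1)
  expect_lt(abs(me$area / (pi * 18) - 1), 0.05)
  expect_lte(me$short_diameter, me$long_diameter)
  expect_lte(me$area, pi * (me$long_diameter / 2)^2)
  two <- mk_rim(5, 5, n = 2)
  expect_error(defect_metrics(two), class = "echoasd_geometry_error")
})

test_that("metrics are invariant under rigid rotation of the septum", {
  base <- list(defect_long = 9, defect_short = 6, defect_angle = 25)
  get <- function(normal) {
    spec <- do.call(phantom_spec, c(base, list(septum_normal = normal)))
    ph <- generate_phantom(spec)
    rim <- extract_rim(as.array(ph$labels) == 2, phantom_septum_plane(spec),
                       "left_atrial", spacing = spec$spacing)
    m <- defect_metrics(rim)
    c(m$long_diameter, m$short_diameter)
  }
  m0 <- get(c(1, 0, 0))
  m30 <- get(c(cos(pi / 6), sin(pi / 6), 0))
  expect_true(all(abs(m0 - m30) <= 0.5))   # one voxel at 0.5 mm spacing
})

test_that("full pipeline recovers defect sizes within 10% (15% area)", {
  for (cs in list(c(6, 4.2, 20, 42), c(14, 9.8, 60, 77))) {
    spec <- phantom_spec(defect_long = cs[1], defect_short = cs[2],
                         defect_angle = cs[3])
    ph <- generate_phantom(spec)
    acq <- acquisition_config(slice_width = 120, slice_depth = 64,
                              seed = cs[4])
    vol <- scan_convert(simulate_tto(ph$volume, acq))
    seg <- segment_volume(multiscale_filter(vol),
                          levelset_config(iterations = 150))
    truth <- phantom_true_metrics(spec)
    for (face in c("left_atrial", "right_atrial")) {
      rim <- extract_rim(seg$mask, phantom_septum_plane(spec), face,
                         spacing = spec$spacing)
      m <- defect_metrics(rim)
      expect_lte(abs(m$long_diameter - truth$long_diameter) /
                   truth$long_diameter, 0.10)
      expect_lte(abs(m$short_diameter - truth$short_diameter) /
                   truth$short_diameter, 0.10)
      expect_lte(abs(m$area - truth$area) / truth$area, 0.15)
    }
  }
})

test_that("point distances are Euclidean in physical units", {
  expect_equal(point_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(point_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  # voxel (2,1,1) -> (1,1,1) at 0.5 mm spacing is 0.5 mm apart
  p <- (c(2, 1, 1) - 1) * 0.5; q <- (c(1, 1, 1) - 1) * 0.5
  expect_equal(point_distance(p, q), 0.5)
  expect_error(point_distance(c(1, 2), c(1, 2, 3)),
               class = "echoasd_config_error")
})
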