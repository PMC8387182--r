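# Median-term anisotropic diffusion and the multiscale despeckler.

test_that("constant volumes are a fixed point of the diffusion", {
  vol <- array(123, c(16, 16, 8))
  out <- median_aniso_diffuse(vol, diffusion_config(iterations = 30))
  expect_equal(out, vol, tolerance = 1e-12)
})

test_that("filtering narrows the histogram of a noisy homogeneous region", {
  set.seed(2)
  vol <- array(100 + rnorm(16 * 16 * 8, sd = 12), c(16, 16, 8))
  out <- median_aniso_diffuse(vol, diffusion_config(iterations = 20))
  expect_lt(histogram_width(out), histogram_width(vol))
})

test_that("edges survive while flat-region variance collapses", {
  set.seed(5)
  n <- c(40, 20, 10)
  vol <- array(50, n)
  vol[21:40, , ] <- 150                     # step edge of height 100
  vol <- vol + rnorm(prod(n), sd = 5)
  cfg <- diffusion_config(iterations = 20, kappa = 10)
  out <- median_aniso_diffuse(vol, cfg)
  edge_grad <- function(x) mean(abs(x[21, , ] - x[20, , ]))
  expect_gte(edge_grad(out), 0.5 * edge_grad(vol))
  flat <- array(FALSE, n); flat[5:16, , ] <- TRUE
  expect_lte(stats::var(out[flat]), 0.5 * stats::var(vol[flat]))
})

test_that("pure diffusion conserves the mean and obeys the maximum principle", {
  set.seed(6)
  vol <- array(runif(20 * 20 * 10, 0, 255), c(20, 20, 10))
  out <- median_aniso_diffuse(vol, diffusion_config(iterations = 25, gamma = 0))
  expect_lt(abs(mean(out) - mean(vol)) / mean(vol), 1e-3)
  expect_gte(min(out), min(vol) - 1e-9)
  expect_lte(max(out), max(vol) + 1e-9)
  # with the median term the range stays inside the input range too
  out2 <- median_aniso_diffuse(vol, diffusion_config(iterations = 25))
  expect_gte(min(out2), min(vol) - 1e-9)
  expect_lte(max(out2), max(vol) + 1e-9)
})

test_that("stability bound on dt is enforced", {
  vol <- array(1, c(8, 8, 8))
  expect_error(median_aniso_diffuse(vol, diffusion_config(dt = 0.3)),
               class = "echoasd_config_error")
  expect_error(diffusion_config(median_window = 4),
               class = "echoasd_config_error")
})

test_that("one pyramid level reduces to single-scale filtering", {
  set.seed(9)
  vol <- array(runif(16 * 16 * 8, 0, 200), c(16, 16, 8))
  cfg1 <- diffusion_config(iterations = 10, levels = 1)
  expect_equal(multiscale_filter(vol, cfg1),
               median_aniso_diffuse(vol, cfg1), tolerance = 1e-12)
  expect_error(multiscale_filter(array(1, c(8, 8, 4)),
                                 diffusion_config(levels = 5)),
               class = "echoasd_config_error")
})

test_that("multiscale beats single-scale on a speckled uniform phantom at equal work", {
  # correlated speckle grains (the PSF-scale texture the coarse level turns
  # into quasi-impulses); multiscale runs its/2 coarse + its/4 fine passes
  set.seed(7)
  n <- c(64, 64, 32)
  g <- array(rnorm(prod(n)), n)
  g <- echoasd:::cpp_gaussian_smooth(g, n, 1.2)
  g <- g / sd(g)
  noisy <- array(100 * pmax(0, 1 + 0.2 * g), n)
  ms <- multiscale_filter(noisy, diffusion_config(iterations = 20))
  ss <- median_aniso_diffuse(noisy, diffusion_config(iterations = 15))
  expect_lt(sd(ms), sd(ss))
})

test_that("multiscale filtering leaves a noiseless phantom nearly unchanged", {
  spec <- phantom_spec()          # pipeline scale: 120 x 120 x 64 at 0.5 mm
  ph <- generate_phantom(spec)
  out <- multiscale_filter(ph$volume)
  expect_lte(mean(abs(as.array(out) - as.array(ph$volume))), 2)
})

test_that("histogram width has its closed forms and invariances", {
  expect_equal(histogram_width(array(7, c(5, 5, 2))), 0)
  x <- array(rep(c(0, 100), each = 50), c(10, 10, 1))
  n <- 100
  expect_equal(histogram_width(x), 50 * sqrt(n / (n - 1)), tolerance = 1e-12)
  expect_equal(histogram_width(x + 31.4), histogram_width(x), tolerance = 1e-12)
  mask <- array(c(TRUE, FALSE), c(10, 10, 1))
  expect_equal(histogram_width(x, mask), sd(x[mask]))
})
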