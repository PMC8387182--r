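# Myocardium / cardiac-cavity segmentation: intensity fuzzy c-means supplies
# the membership field, which both initializes the level set and controls its
# stop function; the level set then evolves without reinitialization.

#' Fuzzy c-means clustering of voxel intensities
#'
#' Standard FCM on the intensity distribution: memberships
#' `u_ci = 1 / sum_k (d_ci / d_ki)^(2/(m-1))` and centroids
#' `v_c = sum(u^m x) / sum(u^m)`, iterated until the maximum centroid shift
#' falls below `tol`. Because the feature is the scalar intensity, the update
#' is computed on the value histogram, which makes the cost independent of
#' volume size.
#'
#' @param volume numeric array or `cartesian_volume`; must not be constant.
#' @param n_clusters number of clusters (2 for myocardium vs cavity).
#' @param m fuzzifier, > 1 (default 2).
#' @param tol convergence tolerance on centroid shift, gray levels.
#' @param max_iter iteration cap.
#' @param seed unused (initialization is deterministic from intensity
#'   quantiles); accepted so callers can treat all stages uniformly.
#' @return object of class `fcm_result`: `membership` (list of arrays, one per
#'   cluster, summing to 1 voxel-wise), `centroids` (ascending), and
#'   `objective_trace`.
#' @export
fcm <- function(volume, n_clusters = 2L, m = 2, tol = 1e-4, max_iter = 100L,
                seed = NULL) {
  x <- as.numeric(volume)
  if (m <= 1) config_error("fuzzifier m must exceed 1")
  vals <- sort(unique(x))
  if (length(vals) < n_clusters)
    numeric_error("volume has %d distinct values; cannot form %d clusters (degenerate distances)",
                  length(vals), n_clusters)
  w <- tabulate(match(x, vals), nbins = length(vals))
  # deterministic init: spread centroids evenly over the intensity range
  # (quantile placement degenerates when one value dominates the histogram)
  rng <- range(vals)
  v <- rng[1] + (seq_len(n_clusters) - 0.5) / n_clusters * diff(rng)
  p <- 2 / (m - 1)
  obj <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(vals, v, function(a, b) (a - b)^2)
    d2 <- pmax(d2, 1e-12)
    inv <- d2^(-p / 2)           # (1/d)^p with d the Euclidean distance
    u <- inv / rowSums(inv)
    um <- u^m
    obj <- c(obj, sum(w * rowSums(um * d2)))
    v_new <- colSums(w * um * vals) / colSums(w * um)
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < tol) break
  }
  ord <- order(v)
  v <- v[ord]
  u <- u[, ord, drop = FALSE]
  dm <- dim(volume)
  idx <- match(x, vals)
  membership <- lapply(seq_len(n_clusters), function(c) {
    arr <- u[idx, c]
    if (!is.null(dm)) dim(arr) <- dm
    arr
  })
  structure(list(membership = membership, centroids = v,
                 objective_trace = obj, iterations = it),
            class = "fcm_result")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("<fcm_result> %d clusters, centroids: %s, %d iterations\n",
              length(x$centroids), paste(signif(x$centroids, 5), collapse = ", "),
              x$iterations))
  invisible(x)
}

#' Initialize a level set from a fuzzy membership field
#'
#' `phi0 = -c0 * (2 u - 1)`: negative (inside) where the target-cluster
#' membership exceeds 0.5, zero exactly at the fuzzy class boundary.
#'
#' @param u_target membership array of the cavity cluster, values in `[0, 1]`.
#' @param c0 initial step height (default 2).
#' @return numeric array `phi0` of the same shape.
#' @export
init_levelset <- function(u_target, c0 = 2) {
  -c0 * (2 * as.array(u_target) - 1)
}

#' Stop function controlled by edges and fuzzy membership
#'
#' `S = g * (1 - 4 u (1 - u))` with the edge indicator
#' `g = 1 / (1 + |grad(G_sigma * I)|^2 / kappa_g^2)`. S vanishes at strong
#' image edges and at fuzzy class boundaries (u near 0.5) and approaches g in
#' pure-class regions, so the evolving interface halts where either cue says
#' "boundary".
#'
#' @param volume intensity array or `cartesian_volume`.
#' @param u_target cavity-cluster membership array, same shape.
#' @param sigma Gaussian pre-smoothing width for the gradient, voxels.
#' @param kappa_g gradient scale of the edge indicator, gray levels.
#' @return numeric array S with values in `[0, 1]`.
#' @export
stop_function <- function(volume, u_target, sigma = 1, kappa_g = 10) {
  x <- vol_data_any(volume)
  u <- vol_data_any(u_target)
  if (!identical(dim(x), dim(u)))
    config_error("volume and membership shapes differ")
  sm <- cpp_gaussian_smooth(x, dim(x), sigma)
  gmag <- cpp_gradient_magnitude(sm, dim(x))
  g <- 1 / (1 + (gmag / kappa_g)^2)
  g * (1 - 4 * u * (1 - u))
}

vol_data_any <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  array(as.numeric(x), dim = dim(x))
}

#' Level-set configuration
#'
#' Coefficients of the without-reinitialization variational flow. The
#' distance-regularization weight must satisfy `mu * dt < 0.25`, and more
#' sharply `mu * dt <= 1 / (2 * ndim)` for the explicit scheme in `ndim`
#' dimensions (checked against the data in [evolve_levelset()]).
#'
#' @param mu distance-regularization weight.
#' @param lam edge-weighted length term weight.
#' @param nu weighted area (balloon) term weight; positive shrinks the
#'   interface from outside.
#' @param epsilon smoothing width of the regularized Heaviside/Dirac.
#' @param dt time step.
#' @param iterations evolution steps.
#' @param c0 initial step height used by [init_levelset()].
#' @return object of class `levelset_config`.
#' @export
levelset_config <- function(mu = 0.01, lam = 5, nu = 1.5, epsilon = 1.5,
                            dt = 5, iterations = 300L, c0 = 2) {
  if (any(c(mu, lam, epsilon, dt) < 0))
    config_error("level-set weights must be non-negative")
  if (mu * dt >= 0.25)
    config_error("stability requires mu * dt < 0.25 (got %g)", mu * dt)
  structure(list(mu = mu, lam = lam, nu = nu, epsilon = epsilon, dt = dt,
                 iterations = as.integer(iterations), c0 = c0),
            class = "levelset_config")
}

#' Evolve a level set without reinitialization
#'
#' Integrates
#' `dphi/dt = mu (lap phi - div(grad phi / |grad phi|))
#'   + lam delta_eps(phi) div(S grad phi / |grad phi|) + nu S delta_eps(phi)`
#' with Neumann boundaries. The distance-regularization term keeps
#' `|grad phi|` near 1, so no periodic signed-distance recomputation is
#' needed.
#'
#' @param phi0 initial level-set array.
#' @param S stop-function array, same shape.
#' @param cfg a [levelset_config()].
#' @param balloon optional weight field of the area term, replacing `S` there
#'   (the length term always uses `S`). The default (`balloon = S`) gives the
#'   classic stop-modulated shrink from outside; passing `1 - 2 * u` for a
#'   cavity membership `u` folds the fuzzy membership into the area
#'   functional, so the flow expands where `u > 0.5`, shrinks where
#'   `u < 0.5`, and is stationary at the fuzzy class boundary.
#' @param track_energy record the discretized energy each iteration (adds
#'   roughly 30 percent cost).
#' @return list with `phi`, `mask` (logical, `phi < 0` = cavity), `energy`
#'   trace (empty unless tracked) and `iterations`.
#' @export
evolve_levelset <- function(phi0, S, cfg = levelset_config(), balloon = NULL,
                            track_energy = FALSE) {
  stopifnot(inherits(cfg, "levelset_config"))
  phi0 <- vol_data_any(phi0)
  S <- vol_data_any(S)
  if (!identical(dim(phi0), dim(S)))
    config_error("phi0 and S shapes differ")
  nd <- max(1L, sum(dim(phi0) > 1L))
  if (cfg$mu * cfg$dt > 1 / (2 * nd) + 1e-12)
    config_error("stability in %dD requires mu * dt <= %g (got %g)",
                 nd, 1 / (2 * nd), cfg$mu * cfg$dt)
  if (is.null(balloon)) {
    balloon <- S
  } else {
    balloon <- vol_data_any(balloon)
    if (!identical(dim(balloon), dim(phi0)))
      config_error("balloon field shape differs from phi0")
  }
  res <- cpp_evolve_levelset(phi0, S, balloon, dim(phi0), cfg$mu, cfg$lam,
                             cfg$nu, cfg$epsilon, cfg$dt, cfg$iterations,
                             track_energy)
  if (!is.null(res$failed_at))
    numeric_error("level set produced non-finite values at iteration %d",
                  res$failed_at)
  list(phi = res$phi, mask = res$phi < 0, energy = res$energy,
       iterations = res$iterations)
}

#' Segment a volume into myocardium and cavity
#'
#' Convenience pipeline stage: 2-cluster FCM on intensities, level set
#' initialized from the cavity membership, stop function from edges and
#' membership, evolution without reinitialization with the membership-signed
#' area term (`balloon = 1 - 2 u`), so the interface settles on the fuzzy
#' class boundary instead of drifting through weak stops. By default the
#' cavity is the darker cluster (the blood pool in ultrasound).
#'
#' @param volume a `cartesian_volume`.
#' @param cfg a [levelset_config()].
#' @param cavity which intensity cluster is the cavity: "darker" or
#'   "brighter".
#' @param sigma,kappa_g stop-function parameters, see [stop_function()].
#' @return list with `mask` (logical cavity array), `phi`, `fcm`, `energy`.
#' @export
segment_volume <- function(volume, cfg = levelset_config(),
                           cavity = c("darker", "brighter"),
                           sigma = 1, kappa_g = 10) {
  cavity <- match.arg(cavity)
  fc <- fcm(volume, n_clusters = 2L)
  u <- fc$membership[[if (cavity == "darker") 1L else 2L]]
  phi0 <- init_levelset(u, cfg$c0)
  S <- stop_function(volume, u, sigma = sigma, kappa_g = kappa_g)
  ev <- evolve_levelset(phi0, S, cfg, balloon = 1 - 2 * u)
  list(mask = ev$mask, phi = ev$phi, fcm = fc, energy = ev$energy)
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical arrays of equal shape.
#' @return `2 |a & b| / (|a| + |b|)`; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
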