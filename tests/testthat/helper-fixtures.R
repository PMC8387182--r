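# Shared fixtures: small analytic volumes, a rotational oracle stack builder,
# and a minimal DICOM multiframe fixture writer (explicit VR little endian).

coord_grids <- function(n, spacing = 1, centered = TRUE) {
  ax <- function(k) {
    v <- (seq_len(n[k]) - 1) * spacing
    if (centered) v - (n[k] - 1) / 2 * spacing else v
  }
  list(X = array(ax(1), n),
       Y = array(rep(ax(2), each = n[1]), n),
       Z = array(rep(ax(3), each = n[1] * n[2]), n))
}

# dark ball in a bright surround: a background-free two-class volume
two_class_ball <- function(n = c(48, 48, 24), radius = 10, dark = 30,
                           bright = 180, noise_sd = 0, seed = 1) {
  g <- coord_grids(n)
  vol <- array(bright, n)
  ball <- (g$X^2 + g$Y^2 + g$Z^2) <= radius^2
  vol[ball] <- dark
  if (noise_sd > 0) {
    set.seed(seed)
    vol <- vol + rnorm(length(vol), sd = noise_sd)
  }
  list(volume = vol, truth = ball)
}

# analytic slice stack for a trivariate field f(x, y, z) sampled the way the
# rotational probe would: an oracle independent of simulate_tto
analytic_stack <- function(f, W, D, step, spacing = 1) {
  n_slices <- 180 %/% step
  angles <- (seq_len(n_slices) - 1) * step
  half <- (W - 1) / 2
  slices <- array(0, dim = c(W, D, n_slices))
  for (s in seq_len(n_slices)) {
    th <- angles[s] * pi / 180
    off <- (seq_len(W) - 1) - half
    for (d in seq_len(D)) {
      slices[, d, s] <- f(off * cos(th), off * sin(th), d - 1)
    }
  }
  structure(list(slices = slices, angles = angles,
                 spacing = rep(spacing, 3), gray_levels = 256L),
            class = "slice_stack")
}

# evaluate a trivariate field on the scan-converted output grid (0 outside
# the scanned disc), for comparison against scan_convert()
analytic_volume <- function(f, W, D) {
  half <- (W - 1) / 2
  xs <- (seq_len(W) - 1) - half
  X <- array(xs, c(W, W, D))
  Y <- array(rep(xs, each = W), c(W, W, D))
  Z <- array(rep(0:(D - 1), each = W * W), c(W, W, D))
  out <- f(X, Y, Z)
  out[sqrt(X^2 + Y^2) > half] <- 0
  out
}

# ---- DICOM fixture writer ------------------------------------------------

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                endian = "little")

dcm_element <- function(group, element, vr, value) {
  if (vr %in% c("IS", "DS", "UI")) {
    v <- charToRaw(as.character(value))
    if (length(v) %% 2 == 1) v <- c(v, charToRaw(" "))
  } else if (vr == "US") {
    v <- dcm_u16(value)
  } else if (vr == "OW") {
    v <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else {
    stop("unsupported VR in fixture writer: ", vr)
  }
  hdr <- c(dcm_u16(group), dcm_u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)), dcm_u32(length(v)), v)
  } else {
    c(hdr, dcm_u16(length(v)), v)
  }
}

# volumes: list of x-y-z integer arrays (one per time point), equal shapes
write_dicom_fixture <- function(path, volumes, spacing = c(1, 1, 1),
                                shuffle = FALSE, drop_rows_tag = FALSE) {
  d <- dim(volumes[[1]])
  nt <- length(volumes)
  frames <- integer(0)
  for (t in seq_len(nt)) {
    vol <- volumes[[t]]
    for (z in seq_len(d[3])) {
      # row-major per frame: row = height (y), columns (x) fastest
      frames <- c(frames, as.integer(vol[, , z]))
    }
  }
  els <- list(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.3.1"),
    dcm_element(0x0018, 0x0088, "DS", format(spacing[3])),
    dcm_element(0x0020, 0x0105, "IS", as.character(nt)),
    dcm_element(0x0028, 0x0008, "IS", as.character(d[3] * nt)),
    dcm_element(0x0028, 0x0010, "US", d[2]),          # Rows = height (y)
    dcm_element(0x0028, 0x0011, "US", d[1]),          # Columns = width (x)
    dcm_element(0x0028, 0x0030, "DS",
                paste(format(spacing[2]), format(spacing[1]), sep = "\\")),
    dcm_element(0x7FE0, 0x0010, "OW", frames))
  if (drop_rows_tag) els[[5]] <- NULL
  if (shuffle) els <- els[c(4, 1, 2, 3, 5:length(els))]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"), con)
  for (e in els) writeBin(e, con)
  invisible(path)
}
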