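# Defect surface extraction and 3D morphometry: triangulated iso-surface of
# the cavity mask, the defect rim on each atrial face of the septum, and the
# three clinical metrics (long diameter, short diameter, area).

#' Triangle mesh container
#'
#' @param vertices numeric matrix, one mm-coordinate row per vertex.
#' @param faces integer matrix of 1-based vertex index triples.
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    config_error("vertices and faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    config_error("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Surface area of a triangle mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return total area in mm^2.
#' @export
mesh_surface_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0) return(0)
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Extract the iso-surface of a binary mask
#'
#' Marching tetrahedra over the Kuhn decomposition of each cell: watertight by
#' construction and free of the classic ambiguous configurations. The mask is
#' padded by one background layer so closed objects yield closed surfaces.
#' With `smoothing = "box"` (the default) the binary field is pre-smoothed
#' with a 3x3x3 mean filter before interpolation, which removes the staircase
#' bias of binary iso-surfaces (about +9 percent on a sphere's area) while
#' leaving the surface position unbiased; if smoothing erases a feature
#' entirely (e.g. a single voxel) the extraction falls back to the raw binary
#' field so every non-empty mask produces a surface.
#'
#' @param mask logical/0-1 array or `cartesian_volume`.
#' @param spacing voxel size in mm (taken from the volume when present).
#' @param iso iso-level (default 0.5).
#' @param smoothing `"box"` or `"none"`.
#' @return a [triangle_mesh()] in physical mm coordinates.
#' @export
marching_cubes <- function(mask, spacing = NULL, iso = 0.5,
                           smoothing = c("box", "none")) {
  smoothing <- match.arg(smoothing)
  if (is.null(spacing)) spacing <- vol_spacing(mask)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  m <- vol_data_any(mask)
  if (sum(m != 0) == 0) geometry_error("mask is empty; no surface to extract")
  d <- dim(m) + 2L
  padded <- array(0, dim = d)
  padded[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- (m != 0) * 1
  field <- if (smoothing == "box") cpp_box_smooth(padded, d, 3L) else padded
  res <- cpp_marching_tets(field, d, iso)
  if (nrow(res$faces) == 0 && smoothing == "box") {
    res <- cpp_marching_tets(padded, d, iso)
  }
  verts <- res$vertices
  verts <- sweep(verts, 2, c(1, 1, 1))          # remove the padding offset
  verts <- sweep(verts, 2, spacing, "*")
  triangle_mesh(verts, res$faces)
}

# 4-connected components of a logical matrix; returns an integer label matrix.
label_components <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  queue <- integer(nr * nc)
  for (start in which(m)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    qh <- 1L; qt <- 1L
    queue[1L] <- start
    lab[start] <- cur
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      i <- ((p - 1L) %% nr) + 1L
      j <- ((p - 1L) %/% nr) + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < nr) p + 1L,
                  if (j > 1L) p - nr, if (j < nc) p + nr)) {
        if (m[q] && lab[q] == 0L) {
          lab[q] <- cur
          qt <- qt + 1L
          queue[qt] <- q
        }
      }
    }
  }
  lab
}

#' Extract the defect rim on one atrial face of the septum
#'
#' Resamples the cavity mask on the face plane (the septum mid-plane offset by
#' plus or minus half the septum thickness, pulled one voxel inside the slab
#' so the samples sit clear of the face's partial-volume shell and of the
#' chamber itself), keeps the connected cavity
#' components that do not touch the sampling window border (the through-hole;
#' the open space around the heart always reaches the border), and returns the
#' ordered closed boundary contour of the largest one in 3D mm coordinates.
#'
#' @param mask logical cavity array or `cartesian_volume`.
#' @param septum_plane list with `point` (mm), `normal` (unit) and
#'   `thickness` (mm), e.g. from [phantom_septum_plane()].
#' @param face `"left_atrial"` (positive normal side) or `"right_atrial"`.
#' @param spacing voxel size in mm (taken from the volume when present).
#' @return object of class `defect_rim` with `points` (n x 3 mm, ordered,
#'   closed), `plane`, `face`, `planarity` (max point-to-plane distance), and
#'   `found = TRUE`; or `found = FALSE` when the septum has no through-hole.
#' @export
extract_rim <- function(mask, septum_plane,
                        face = c("left_atrial", "right_atrial"),
                        spacing = NULL) {
  face <- match.arg(face)
  if (is.null(spacing)) spacing <- vol_spacing(mask)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  h <- min(spacing)
  m <- vol_data_any(mask)
  d <- dim(m)
  n <- septum_plane$normal / sqrt(sum(septum_plane$normal^2))
  side <- if (face == "left_atrial") 1 else -1
  off <- side * max(septum_plane$thickness / 2 - h, 0)
  p0 <- septum_plane$point + off * n
  b <- plane_basis(n)

  corners <- as.matrix(expand.grid(x = c(0, (d[1] - 1) * spacing[1]),
                                   y = c(0, (d[2] - 1) * spacing[2]),
                                   z = c(0, (d[3] - 1) * spacing[3])))
  rel <- sweep(corners, 2, p0)
  ur <- range(rel %*% b$e1)
  vr <- range(rel %*% b$e2)
  us <- seq(ur[1], ur[2], by = h)
  vs <- seq(vr[1], vr[2], by = h)
  pts <- cbind(rep(us, times = length(vs)), rep(vs, each = length(us)))
  xyz <- cbind(p0[1] + pts[, 1] * b$e1[1] + pts[, 2] * b$e2[1],
               p0[2] + pts[, 1] * b$e1[2] + pts[, 2] * b$e2[2],
               p0[3] + pts[, 1] * b$e1[3] + pts[, 2] * b$e2[3])
  vox <- sweep(xyz, 2, spacing, "/")
  vals <- cpp_sample_points(m * 1, d, vox, FALSE)
  plane_mask <- matrix(vals >= 0.5, nrow = length(us))

  lab <- label_components(plane_mask)
  if (max(lab) == 0L)
    return(structure(list(found = FALSE, face = face, plane = septum_plane),
                     class = "defect_rim"))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  keep <- setdiff(seq_len(max(lab)), border)
  if (length(keep) == 0L)
    return(structure(list(found = FALSE, face = face, plane = septum_plane),
                     class = "defect_rim"))
  sizes <- vapply(keep, function(k) sum(lab == k), 0L)
  chosen <- keep[which.max(sizes)]
  # contour the continuous resampled field (sub-voxel boundary), suppressing
  # every other cavity component so only the hole's contour remains
  field <- matrix(vals, nrow = length(us))
  field[plane_mask & lab != chosen] <- 0
  cl <- grDevices::contourLines(x = us, y = vs, z = field, levels = 0.5)
  if (length(cl) == 0L)
    return(structure(list(found = FALSE, face = face, plane = septum_plane),
                     class = "defect_rim"))
  # keep the contour enclosing the chosen component's centroid
  idx <- which(lab == chosen, arr.ind = TRUE)
  cu <- mean(us[idx[, 1]]); cv <- mean(vs[idx[, 2]])
  enclosing <- vapply(cl, function(cc) {
    crossings <- sum(diff(cc$y > cv) != 0 &
                       (cc$x[-1] + cc$x[-length(cc$x)]) / 2 > cu)
    crossings %% 2 == 1
  }, TRUE)
  if (!any(enclosing))
    enclosing <- vapply(cl, function(cc) length(cc$x), 0L) ==
      max(vapply(cl, function(cc) length(cc$x), 0L))
  cc <- cl[[which(enclosing)[1]]]
  uv <- cbind(cc$x, cc$y)
  pts3 <- cbind(p0[1] + uv[, 1] * b$e1[1] + uv[, 2] * b$e2[1],
                p0[2] + uv[, 1] * b$e1[2] + uv[, 2] * b$e2[2],
                p0[3] + uv[, 1] * b$e1[3] + uv[, 2] * b$e2[3])
  ctr <- colMeans(pts3)
  planarity <- max(abs(sweep(pts3, 2, ctr) %*% n))
  structure(list(found = TRUE, points = pts3,
                 plane = list(point = p0, normal = n), face = face,
                 planarity = planarity),
            class = "defect_rim")
}

#' @export
print.defect_rim <- function(x, ...) {
  if (!isTRUE(x$found)) {
    cat(sprintf("<defect_rim> no defect found on the %s face\n", x$face))
  } else {
    cat(sprintf("<defect_rim> %s face, %d points, planarity %.3g mm\n",
                x$face, nrow(x$points), x$planarity))
  }
  invisible(x)
}

# minimum Feret width of a convex hull (rotating calipers: the width is the
# smallest over hull edges of the farthest point distance from the edge line)
min_feret_width <- function(hull) {
  nh <- nrow(hull)
  wmin <- Inf
  for (i in seq_len(nh)) {
    p <- hull[i, ]
    q <- hull[if (i == nh) 1L else i + 1L, ]
    e <- q - p
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    nrm <- c(-e[2], e[1]) / len
    dist <- abs(sweep(hull, 2, p) %*% nrm)
    wmin <- min(wmin, max(dist))
  }
  wmin
}

#' Defect metrics from a rim contour
#'
#' Projects the ordered rim onto its least-squares plane and measures the
#' maximum Feret diameter (long diameter), the minimum Feret width by rotating
#' calipers (short diameter), and the shoelace polygon area.
#'
#' @param rim a `defect_rim` with `found = TRUE`.
#' @return object of class `defect_metrics`: `long_diameter`, `short_diameter`
#'   (mm), `area` (mm^2), `face`.
#' @export
defect_metrics <- function(rim) {
  stopifnot(inherits(rim, "defect_rim"))
  if (!isTRUE(rim$found))
    geometry_error("rim reports no defect; nothing to measure")
  pts <- rim$points
  # drop the duplicated closing point if present
  if (nrow(pts) > 1 && sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9)
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 3) geometry_error("rim has fewer than 3 distinct points")
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  sv <- svd(cen, nu = 0, nv = 3)
  xy <- cen %*% sv$v[, 1:2, drop = FALSE]   # least-squares plane coordinates
  hull_idx <- grDevices::chull(xy)
  hull <- xy[hull_idx, , drop = FALSE]
  dmat <- as.matrix(stats::dist(hull))
  long <- max(dmat)
  short <- min_feret_width(hull)
  n <- nrow(xy)
  nxt <- c(seq_len(n)[-1], 1L)
  area <- abs(sum(xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2])) / 2
  structure(list(long_diameter = long, short_diameter = short, area = area,
                 face = rim$face),
            class = "defect_metrics")
}

#' @export
print.defect_metrics <- function(x, ...) {
  cat(sprintf("<defect_metrics> %s: long %.2f mm, short %.2f mm, area %.2f mm^2\n",
              x$face, x$long_diameter, x$short_diameter, x$area))
  invisible(x)
}

#' Euclidean distance between two points
#'
#' @param p,q numeric coordinate vectors in mm.
#' @return distance in mm.
#' @export
point_distance <- function(p, q) {
  if (length(p) != length(q)) config_error("points have different dimensions")
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}
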