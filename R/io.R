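# Readers and writers for the formats the pipeline touches: NRRD and
# MetaImage volumes, PGM slice-stack directories with a JSON manifest, a
# minimal DICOM multiframe reader (explicit VR little endian), and ASCII
# STL / PLY meshes.  The internal canonical axis order is (x, y, z[, t]);
# every reader normalizes to it at the boundary.

nrrd_type_of <- function(x) {
  v <- as.numeric(x)
  if (all(v == round(v))) {
    if (min(v) >= 0 && max(v) <= 255) return("uint8")
    if (min(v) >= -2^31 && max(v) < 2^31) return("int32")
  }
  "double"
}

nrrd_bin <- list(
  uint8  = list(size = 1L, what = "integer", signed = FALSE),
  int16  = list(size = 2L, what = "integer", signed = TRUE),
  uint16 = list(size = 2L, what = "integer", signed = FALSE),
  int32  = list(size = 4L, what = "integer", signed = TRUE),
  float  = list(size = 4L, what = "double", signed = TRUE),
  double = list(size = 8L, what = "double", signed = TRUE))

#' Write a volume to NRRD or MetaImage
#'
#' The format is chosen by extension: `.nrrd` (detached-header-free NRRD,
#' raw or ascii encoding) or `.mha` (MetaImage with local data). Integer
#' volumes are stored losslessly in the narrowest sufficient integer type.
#'
#' @param path output file ending in `.nrrd` or `.mha`.
#' @param volume a `cartesian_volume`.
#' @param encoding `"raw"` or `"ascii"` (NRRD only).
#' @return `path`, invisibly.
#' @export
write_volume <- function(path, volume, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(volume, "cartesian_volume"))
  ext <- tolower(sub(".*\\.", "", path))
  d <- dim(volume)
  sp <- vol_spacing(volume)
  type <- nrrd_type_of(volume)
  v <- as.numeric(volume)
  if (ext == "nrrd") {
    hdr <- c("NRRD0004",
             paste("type:", type),
             "dimension: 3",
             paste("sizes:", paste(d, collapse = " ")),
             paste("spacings:", paste(format(sp, digits = 17), collapse = " ")),
             "endian: little",
             paste("encoding:", encoding),
             "")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    if (encoding == "ascii") {
      writeLines(paste(format(v, digits = 17, trim = TRUE), collapse = " "), con)
    } else {
      b <- nrrd_bin[[type]]
      if (b$what == "integer") writeBin(as.integer(v), con, size = b$size,
                                        endian = "little")
      else writeBin(v, con, size = b$size, endian = "little")
    }
  } else if (ext == "mha") {
    met <- c(uint8 = "MET_UCHAR", int16 = "MET_SHORT", uint16 = "MET_USHORT",
             int32 = "MET_INT", float = "MET_FLOAT", double = "MET_DOUBLE")
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False",
             paste("DimSize =", paste(d, collapse = " ")),
             paste("ElementSpacing =",
                   paste(format(sp, digits = 17), collapse = " ")),
             paste("ElementType =", met[[type]]),
             "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    b <- nrrd_bin[[type]]
    if (b$what == "integer") writeBin(as.integer(v), con, size = b$size,
                                      endian = "little")
    else writeBin(v, con, size = b$size, endian = "little")
  } else {
    format_error("unknown volume extension '.%s' (use .nrrd or .mha)", ext)
  }
  invisible(path)
}

read_payload <- function(bytes, type, n, endian = "little") {
  b <- nrrd_bin[[type]]
  if (is.null(b)) format_error("unsupported element type '%s'", type)
  if (length(bytes) < n * b$size)
    format_error("truncated data: expected %d bytes, found %d",
                 n * b$size, length(bytes))
  if (b$size <= 2L && b$what == "integer") {
    readBin(bytes, "integer", n = n, size = b$size, signed = b$signed,
            endian = endian)
  } else {
    readBin(bytes, b$what, n = n, size = b$size, endian = endian)
  }
}

#' Read a volume from NRRD or MetaImage
#'
#' @param path file ending in `.nrrd` or `.mha`.
#' @return a `cartesian_volume`.
#' @export
read_volume <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  raw <- readBin(path, raw(), file.info(path)$size)
  if (ext == "nrrd") {
    nl <- which(raw == as.raw(10L))
    # header ends at the first blank line
    blank <- nl[which(diff(c(0L, nl)) == 1L)][1]
    if (is.na(blank)) format_error("NRRD header has no terminating blank line")
    hdr <- strsplit(rawToChar(raw[seq_len(blank)]), "\n")[[1]]
    if (!startsWith(hdr[1], "NRRD")) format_error("not a NRRD file")
    fields <- hdr[grepl(":", hdr, fixed = TRUE)]
    kv <- do.call(rbind, strsplit(fields, ":\\s*"))
    get <- function(k) kv[match(k, kv[, 1]), 2]
    type <- get("type")
    sizes <- as.integer(strsplit(get("sizes"), "\\s+")[[1]])
    sp <- as.numeric(strsplit(get("spacings"), "\\s+")[[1]])
    enc <- get("encoding")
    payload <- raw[(blank + 1):length(raw)]
    n <- prod(sizes)
    v <- if (identical(enc, "ascii")) {
      as.numeric(strsplit(trimws(rawToChar(payload)), "\\s+")[[1]])
    } else {
      read_payload(payload, type, n)
    }
    if (length(v) < n) format_error("NRRD payload shorter than sizes imply")
    cartesian_volume(array(v[seq_len(n)], dim = sizes), sp)
  } else if (ext == "mha") {
    # header lines up to and including ElementDataFile, then binary payload
    txt_end <- 0L
    pos <- 1L
    hdr <- character(0)
    repeat {
      nl <- which(raw[pos:length(raw)] == as.raw(10L))[1]
      if (is.na(nl)) format_error("malformed MetaImage header")
      line <- rawToChar(raw[pos:(pos + nl - 2)])
      hdr <- c(hdr, line)
      pos <- pos + nl
      if (grepl("^ElementDataFile", line)) { txt_end <- pos - 1L; break }
    }
    kv <- do.call(rbind, strsplit(hdr, "\\s*=\\s*"))
    get <- function(k) kv[match(k, kv[, 1]), 2]
    sizes <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
    sp <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
    met <- c(MET_UCHAR = "uint8", MET_SHORT = "int16", MET_USHORT = "uint16",
             MET_INT = "int32", MET_FLOAT = "float", MET_DOUBLE = "double")
    type <- met[[get("ElementType")]]
    if (!identical(get("ElementDataFile"), "LOCAL"))
      format_error("only ElementDataFile = LOCAL is supported")
    v <- read_payload(raw[(txt_end + 1):length(raw)], type, prod(sizes))
    cartesian_volume(array(v, dim = sizes), sp)
  } else {
    format_error("unknown volume extension '.%s'", ext)
  }
}

#' Write a slice stack as PGM files plus a JSON manifest
#'
#' @param dir output directory (created if needed).
#' @param stack a `slice_stack`.
#' @return `dir`, invisibly.
#' @export
write_slice_stack <- function(dir, stack) {
  stopifnot(inherits(stack, "slice_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(stack$slices)
  if (max(stack$slices) > 255 || min(stack$slices) < 0)
    format_error("PGM stacks require intensities in [0, 255]")
  files <- sprintf("slice_%04d.pgm", seq_len(d[3]) - 1)
  for (s in seq_len(d[3])) {
    con <- file(file.path(dir, files[s]), "wb")
    writeLines(c("P5", paste(d[1], d[2]), "255"), con, sep = "\n")
    writeBin(as.raw(as.integer(stack$slices[, , s])), con)
    close(con)
  }
  manifest <- list(files = files, angles = stack$angles,
                   spacing = stack$spacing, gray_levels = stack$gray_levels,
                   width = d[1], depth = d[2])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a slice stack written by [write_slice_stack()]
#'
#' @param dir directory holding `manifest.json` and the PGM slices.
#' @return a `slice_stack`.
#' @export
read_slice_stack <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) format_error("no manifest.json in %s", dir)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  slices <- array(0, dim = c(man$width, man$depth, length(man$files)))
  for (s in seq_along(man$files)) {
    raw <- readBin(file.path(dir, man$files[s]), raw(),
                   file.info(file.path(dir, man$files[s]))$size)
    if (rawToChar(raw[1:2]) != "P5")
      format_error("%s is not a binary PGM", man$files[s])
    nl <- which(raw == as.raw(10L))
    datapos <- nl[3] + 1L
    hdr <- strsplit(rawToChar(raw[seq_len(nl[3])]), "\\s+")[[1]]
    w <- as.integer(hdr[2]); h <- as.integer(hdr[3])
    px <- as.integer(raw[datapos:(datapos + w * h - 1L)])
    slices[, , s] <- array(px, dim = c(w, h))
  }
  structure(list(slices = slices, angles = as.numeric(man$angles),
                 spacing = as.numeric(man$spacing),
                 gray_levels = as.integer(man$gray_levels)),
            class = "slice_stack")
}

dicom_tag <- function(group, element) sprintf("(%04X,%04X)", group, element)

#' Read a DICOM multiframe full-volume file
#'
#' Minimal explicit-VR little-endian reader for the generic multiframe layout:
#' frames are stored in the order height, width, depth, time, so the file
#' separates into one Cartesian volume per time point with no resampling.
#' Data elements must be ordered by ascending tag; out-of-order elements and
#' missing required tags raise a format error naming the offender.
#'
#' @param path a `.dcm` file.
#' @return list with `volumes` (one `cartesian_volume` per time point, axes
#'   `(x, y, z)`) and `header` (shape, spacing, axis_order, frame_count).
#' @export
read_dicom_fullvolume <- function(path) {
  raw <- readBin(path, raw(), file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    format_error("missing DICM magic; not a DICOM part-10 file")
  pos <- 133L
  u16 <- function(p) readBin(raw[p:(p + 1L)], "integer", size = 2,
                             signed = FALSE, endian = "little")
  u32 <- function(p) readBin(raw[p:(p + 3L)], "integer", size = 4,
                             endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elems <- list()
  last_key <- -1
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    if (vstart + len - 1L > length(raw))
      format_error("element %s overruns the file", dicom_tag(group, element))
    key <- group * 65536 + element
    if (group != 2L) {  # file meta group is not part of the data set
      if (key <= last_key)
        format_error("data elements out of order at %s (tags must ascend)",
                     dicom_tag(group, element))
      last_key <- key
      elems[[dicom_tag(group, element)]] <-
        list(vr = vr, value = if (len > 0) raw[vstart:(vstart + len - 1L)]
             else raw(0))
    }
    pos <- vstart + len
  }
  need <- function(group, element, what) {
    tag <- dicom_tag(group, element)
    e <- elems[[tag]]
    if (is.null(e)) format_error("missing required tag %s (%s)", tag, what)
    e
  }
  as_str <- function(e) trimws(rawToChar(e$value))
  rows <- u16_val <- function(e) readBin(e$value, "integer", size = 2,
                                         signed = FALSE, endian = "little")
  rows <- u16_val(need(0x0028, 0x0010, "Rows"))
  cols <- u16_val(need(0x0028, 0x0011, "Columns"))
  nframes <- as.integer(as_str(need(0x0028, 0x0008, "NumberOfFrames")))
  nt <- 1L
  if (!is.null(elems[["(0020,0105)"]]))
    nt <- as.integer(as_str(elems[["(0020,0105)"]]))
  if (nframes %% nt != 0)
    format_error("frame count %d is not divisible by %d time positions",
                 nframes, nt)
  nz <- nframes %/% nt
  sp_xy <- c(1, 1)
  if (!is.null(elems[["(0028,0030)"]]))
    sp_xy <- rev(as.numeric(strsplit(as_str(elems[["(0028,0030)"]]),
                                     "\\\\")[[1]]))  # row\col -> (x, y)
  sp_z <- 1
  if (!is.null(elems[["(0018,0088)"]]))
    sp_z <- as.numeric(as_str(elems[["(0018,0088)"]]))
  px_elem <- need(0x7FE0, 0x0010, "PixelData")
  px <- readBin(px_elem$value, "integer", n = length(px_elem$value) / 2,
                size = 2, signed = FALSE, endian = "little")
  if (length(px) < rows * cols * nframes)
    format_error("PixelData holds %d samples; %d expected",
                 length(px), rows * cols * nframes)
  volumes <- vector("list", nt)
  spacing <- c(sp_xy, sp_z)
  for (t in seq_len(nt)) {
    vol <- array(0, dim = c(cols, rows, nz))
    for (z in seq_len(nz)) {
      f <- (t - 1L) * nz + z
      frame <- px[((f - 1L) * rows * cols + 1L):(f * rows * cols)]
      # frame is row-major (height then width); transpose to (x, y)
      vol[, , z] <- t(matrix(frame, nrow = rows, byrow = TRUE))
    }
    volumes[[t]] <- cartesian_volume(vol, spacing)
  }
  list(volumes = volumes,
       header = list(shape = c(rows, cols, nz, nt), spacing = spacing,
                     axis_order = c("height", "width", "depth", "time"),
                     frame_count = nframes))
}

#' Write a triangle mesh to STL or PLY (ASCII)
#'
#' @param path output file ending in `.stl` or `.ply`.
#' @param mesh a [triangle_mesh()]; must have at least one face.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(path, mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0) format_error("refusing to write an empty mesh")
  ext <- tolower(sub(".*\\.", "", path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      p <- v[f[i, ], , drop = FALSE]
      nrm <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) -
                 (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
               (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) -
                 (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
               (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                 (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
      len <- sqrt(sum(nrm^2))
      if (len > 0) nrm <- nrm / len
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                           nrm[1], nrm[2], nrm[3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           p[, 1], p[, 2], p[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else {
    format_error("unknown mesh extension '.%s' (use .stl or .ply)", ext)
  }
  invisible(path)
}

#' Read a triangle mesh written by [write_mesh()]
#'
#' STL vertices are welded on read (identical coordinates collapse to one
#' vertex), so a written mesh round-trips with its vertex and face counts.
#'
#' @param path `.stl` or `.ply` file.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  lines <- readLines(path)
  if (ext == "stl") {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(p) as.numeric(p[2:4])))
    key <- apply(coords, 1, paste, collapse = ",")
    uniq <- !duplicated(key)
    idx <- match(key, key[uniq])
    verts <- coords[uniq, , drop = FALSE]
    faces <- matrix(idx, ncol = 3, byrow = TRUE)
    triangle_mesh(verts, faces)
  } else if (ext == "ply") {
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    start <- which(lines == "end_header") + 1L
    verts <- do.call(rbind, lapply(strsplit(lines[start:(start + nv - 1L)],
                                            "\\s+"), as.numeric))
    fl <- strsplit(lines[(start + nv):(start + nv + nf - 1L)], "\\s+")
    faces <- do.call(rbind, lapply(fl, function(p) as.integer(p[2:4]) + 1L))
    triangle_mesh(verts, faces)
  } else {
    format_error("unknown mesh extension '.%s'", ext)
  }
}
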