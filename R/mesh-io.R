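# Mesh, manifest and point-cloud I/O.
#
# STL (ASCII and binary little-endian) and ASCII PLY are parsed directly:
# both are simple fixed layouts and the loaded soup is merged/validated by
# aaa_mesh(). Manifests are JSON. All coordinates are centimetres.

#' Read a triangulated surface mesh
#'
#' Reads an STL (ASCII or binary) or ASCII PLY file, merges coincident
#' vertices, drops degenerate triangles, repairs the face orientation to a
#' positive signed volume and validates watertightness.
#'
#' @param path Path to an `.stl` or `.ply` file.
#' @param layer `"lumen"` or `"outer_wall"`.
#' @return A validated [aaa_mesh()].
#' @export
read_mesh <- function(path, layer = "outer_wall") {
  if (!file.exists(path)) stop_format("mesh file not found: %s", path)
  head <- readBin(path, "raw", n = 16L)
  txt5 <- rawToChar(head[seq_len(min(5L, length(head)))])
  parsed <-
    if (identical(tolower(txt5), "ply\r\n") || startsWith(tolower(txt5), "ply")) {
      read_ply_ascii(path)
    } else if (is_binary_stl(path)) {
      read_stl_binary(path)
    } else if (identical(tolower(txt5), "solid")) {
      read_stl_ascii(path)
    } else {
      stop_format("unrecognized mesh format (expected STL or PLY): %s", path)
    }
  aaa_mesh(parsed$vertices, parsed$faces, layer = layer, validate = TRUE)
}

# A binary STL is 84 + 50 * n_triangles bytes with the count at offset 80.
#' @noRd
is_binary_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 84) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  isTRUE(sz == 84 + 50 * as.numeric(ntri))
}

#' @noRd
read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (ntri < 1L) stop_format("binary STL with no triangles: %s", path)
  rec <- readBin(con, "raw", n = 50L * ntri)
  if (length(rec) < 50L * ntri) stop_format("truncated binary STL: %s", path)
  m <- matrix(rec, nrow = 50L)
  fl <- readBin(as.vector(m[1:48, ]), "double", n = 12L * ntri, size = 4L, endian = "little")
  fl <- matrix(fl, nrow = 12L)           # per tri: normal(3), v1(3), v2(3), v3(3)
  verts <- t(matrix(fl[4:12, ], nrow = 3L))
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

#' @noRd
read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop_format("malformed ASCII STL (vertex count %d not a multiple of 3): %s",
                length(vl), path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
  verts <- do.call(rbind, nums)
  if (anyNA(verts)) stop_format("non-numeric vertex in ASCII STL: %s", path)
  ntri <- nrow(verts) / 3L
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

#' @noRd
read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop_format("PLY without end_header: %s", path)
  header <- trimws(lines[seq_len(endh)])
  if (any(grepl("^format\\s+binary", header)))
    stop_format("binary PLY not supported: %s", path)
  nv <- as.integer(sub("^element\\s+vertex\\s+", "", grep("^element\\s+vertex", header, value = TRUE)))
  nf <- as.integer(sub("^element\\s+face\\s+", "", grep("^element\\s+face", header, value = TRUE)))
  if (length(nv) != 1L || length(nf) != 1L)
    stop_format("PLY missing vertex/face elements: %s", path)
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fparts, function(p) {
    k <- as.integer(p[1])
    if (k != 3L) stop_format("non-triangular PLY face (%d vertices)", k)
    as.integer(p[2:4]) + 1L
  }))
  list(vertices = verts, faces = faces)
}

#' Write a mesh as ASCII STL or ASCII PLY
#'
#' Coordinates are written with 17 significant digits so that an
#' ASCII-STL/PLY round trip reproduces the double-precision values bitwise.
#'
#' @param mesh An [aaa_mesh()].
#' @param path Output path; format chosen by extension (`.stl` / `.ply`)
#'   unless `format` is given.
#' @param format `"stl"` or `"ply"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "stl"
  v <- mesh$vertices; f <- mesh$faces
  con <- tryCatch(file(path, "wt"), error = function(e) stop_io("cannot open %s for writing", path))
  on.exit(close(con))
  if (format == "stl") {
    writeLines("solid aaafc", con)
    tri <- cbind(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE], v[f[, 3], , drop = FALSE])
    block <- sprintf(paste0(
      " facet normal 0 0 0\n  outer loop\n",
      "   vertex %.17g %.17g %.17g\n   vertex %.17g %.17g %.17g\n   vertex %.17g %.17g %.17g\n",
      "  endloop\n endfacet"),
      tri[, 1], tri[, 2], tri[, 3], tri[, 4], tri[, 5], tri[, 6], tri[, 7], tri[, 8], tri[, 9])
    writeLines(block, con)
    writeLines("endsolid aaafc", con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

#' Load a longitudinal patient series from a JSON manifest
#'
#' The manifest lists, per imaging session, either an acquisition `date`
#' (ISO `YYYY-MM-DD`) or a `day` offset, plus the wall and lumen mesh paths
#' (relative to the manifest). Times are converted to days since the
#' earliest scan and sessions sorted in time. Consecutive scans are checked
#' for > 50% bounding-box overlap (the pipeline assumes co-registered
#' meshes) with a warning otherwise.
#'
#' @param manifest_path Path to the JSON manifest.
#' @return An object of class `aaa_series`: `patient_id`, `times` (days,
#'   first = 0) and `scans`, a list of `list(time, wall, lumen)`.
#' @export
load_patient_series <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop_io("manifest not found: %s", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  scans <- man$scans
  if (is.null(scans) || length(scans) < 2L)
    stop_insufficient("patient series needs >= 2 scans, manifest has %d",
                      length(scans %||% list()))
  root <- dirname(normalizePath(manifest_path))
  days <- vapply(scans, function(s) {
    if (!is.null(s$day)) as.numeric(s$day)
    else if (!is.null(s$date)) as.numeric(as.Date(s$date))
    else stop_validation("scan entry lacks both 'date' and 'day'")
  }, numeric(1))
  days <- days - min(days)
  if (anyDuplicated(days)) stop_validation("duplicate acquisition times in manifest")
  ord <- order(days)
  scans <- scans[ord]; days <- days[ord]
  loaded <- lapply(seq_along(scans), function(j) {
    s <- scans[[j]]
    list(time = days[j],
         wall = read_mesh(file.path(root, s$wall_mesh), layer = "outer_wall"),
         lumen = read_mesh(file.path(root, s$lumen_mesh), layer = "lumen"))
  })
  for (j in seq_len(length(loaded) - 1L)) {
    ov <- bbox_overlap(loaded[[j]]$wall, loaded[[j + 1L]]$wall)
    if (ov < 0.5)
      warning(sprintf("scans %d and %d overlap by only %.0f%% of bounding box; meshes may not be co-registered",
                      j, j + 1L, 100 * ov), call. = FALSE)
  }
  structure(list(patient_id = man$patient_id %||% "unknown",
                 times = days, scans = loaded),
            class = "aaa_series")
}

#' @export
print.aaa_series <- function(x, ...) {
  cat(sprintf("<aaa_series> patient %s: %d scans at days {%s}\n",
              x$patient_id, length(x$scans), paste(x$times, collapse = ", ")))
  invisible(x)
}

# fractional overlap of axis-aligned bounding boxes (intersection / smaller box)
#' @noRd
bbox_overlap <- function(m1, m2) {
  b1 <- apply(m1$vertices, 2, range); b2 <- apply(m2$vertices, 2, range)
  lo <- pmax(b1[1, ], b2[1, ]); hi <- pmin(b1[2, ], b2[2, ])
  if (any(hi <= lo)) return(0)
  v1 <- prod(b1[2, ] - b1[1, ]); v2 <- prod(b2[2, ] - b2[1, ])
  prod(hi - lo) / min(v1, v2)
}

#' Write a point cloud to CSV or ASCII PLY
#'
#' CSV output carries a header naming the coordinate convention
#' (`x_cm,y_cm,z_cm` for Cartesian, `r_cm,theta_rad,z_cm` for unwrapped
#' clouds) and preserves full double precision.
#'
#' @param points Numeric matrix with 3 columns.
#' @param path Output path.
#' @param format `"csv"` or `"ply"`.
#' @param coords `"cartesian"` or `"cylindrical"` (sets the CSV header).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(points, path, format = c("csv", "ply"),
                              coords = c("cartesian", "cylindrical")) {
  format <- match.arg(format); coords <- match.arg(coords)
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop_validation("refusing to write an empty point cloud")
  if (ncol(points) != 3L) stop_validation("point cloud must have 3 columns")
  con <- tryCatch(file(path, "wt"), error = function(e) stop_io("cannot open %s for writing", path))
  on.exit(close(con))
  if (format == "csv") {
    hdr <- if (coords == "cartesian") "x_cm,y_cm,z_cm" else "r_cm,theta_rad,z_cm"
    writeLines(hdr, con)
    writeLines(sprintf("%.17g,%.17g,%.17g", points[, 1], points[, 2], points[, 3]), con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(points)),
                 "property double x", "property double y", "property double z",
                 "element face 0", "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(sprintf("%.17g %.17g %.17g", points[, 1], points[, 2], points[, 3]), con)
  }
  invisible(path)
}

#' Read a point cloud written by [write_point_cloud()]
#'
#' @param path CSV or ASCII PLY path.
#' @return Numeric matrix with 3 columns; the CSV header is kept as the
#'   `header` attribute.
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stop_io("point cloud not found: %s", path)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    p <- read_ply_ascii_points(path)
    return(p)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[[1]]
  vals <- do.call(rbind, lapply(strsplit(lines[-1], ","), as.numeric))
  structure(vals, header = hdr)
}

#' @noRd
read_ply_ascii_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(lines))
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex", trimws(lines[seq_len(endh)]), value = TRUE)))
  body <- lines[endh + seq_len(nv)]
  do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), function(p) as.numeric(p[1:3])))
}
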