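# Centerline extraction, Fourier smoothing, and station resampling.
#
# A centerline is the ordered sequence of cross-section area centroids of a
# layer surface, proximal (renal) to distal (iliac), stored as a K x 3
# matrix of stations (c_x, c_y, c_z) in cm with strictly increasing c_z.

#' Construct a centerline
#'
#' @param stations Numeric K x 3 matrix of (c_x, c_y, c_z) in cm, c_z
#'   strictly increasing, K >= 3.
#' @param layer `"lumen"` or `"outer_wall"`.
#' @return Object of class `aaa_centerline`.
#' @export
aaa_centerline <- function(stations, layer = "outer_wall") {
  stations <- as.matrix(stations)
  storage.mode(stations) <- "double"
  dimnames(stations) <- NULL
  layer <- match.arg(layer, LAYERS)
  if (ncol(stations) != 3L) stop_validation("centerline stations must have 3 columns")
  if (nrow(stations) < 3L) stop_validation("centerline needs >= 3 stations, got %d", nrow(stations))
  if (any(diff(stations[, 3]) <= 0)) stop_validation("centerline c_z must be strictly increasing")
  structure(list(stations = stations, layer = layer), class = "aaa_centerline")
}

#' @export
print.aaa_centerline <- function(x, ...) {
  z <- x$stations[, 3]
  cat(sprintf("<aaa_centerline> %s: K=%d stations, z in [%.3f, %.3f] cm\n",
              x$layer, nrow(x$stations), z[1], z[length(z)]))
  invisible(x)
}

#' Extract a raw slice-centroid centerline from a surface
#'
#' Slices the surface at `n_levels` evenly spaced z values in
#' `[z_min, z_max]` and takes the area centroid of the cross-section
#' contour (largest-area loop if the plane cuts several) as the station.
#'
#' @param mesh An [aaa_mesh()].
#' @param z_min,z_max Axial range (cm), strictly inside the mesh z-extent.
#' @param n_levels Number of slicing levels (>= 3).
#' @return An [aaa_centerline()].
#' @export
extract_raw_centerline <- function(mesh, z_min = NULL, z_max = NULL, n_levels = 100L) {
  zr <- mesh_z_range(mesh)
  eps <- 1e-4 * (zr[2] - zr[1])
  z_min <- z_min %||% (zr[1] + eps)
  z_max <- z_max %||% (zr[2] - eps)
  if (n_levels < 3L) stop_validation("n_levels must be >= 3")
  if (z_min < zr[1] || z_max > zr[2] || z_min >= z_max)
    stop_validation("[z_min, z_max] = [%g, %g] must lie within the mesh z-extent [%g, %g]",
                    z_min, z_max, zr[1], zr[2])
  zs <- seq(z_min, z_max, length.out = n_levels)
  st <- matrix(NA_real_, n_levels, 3L)
  for (k in seq_len(n_levels)) {
    ct <- tryCatch(slice_at_level(mesh, zs[k]),
                   aaafc_error = function(e)
                     stop_coverage("empty cross-section at level %d (z = %g): %s",
                                   k, zs[k], conditionMessage(e)))
    cen <- contour_centroid(ct)
    st[k, ] <- c(cen, zs[k])
  }
  aaa_centerline(st, layer = mesh$layer)
}

#' Smooth centerline coordinates with a truncated Fourier series
#'
#' Replaces c_x(s) and c_y(s) with their least-squares projection onto a
#' mean plus `n_harmonics` sine/cosine pairs in the normalized axial
#' parameter s in \[0, 1\] mapped linearly from c_z; c_z is unchanged.
#'
#' @param cl An [aaa_centerline()].
#' @param n_harmonics Number of harmonics (default 5).
#' @return Smoothed [aaa_centerline()].
#' @export
fourier_smooth <- function(cl, n_harmonics = 5L) {
  st <- cl$stations
  K <- nrow(st)
  if (K < 2L * n_harmonics + 1L)
    stop_identifiability("n_harmonics = %d needs K >= %d stations, got %d",
                         n_harmonics, 2L * n_harmonics + 1L, K)
  z <- st[, 3]
  s <- (z - z[1]) / (z[K] - z[1])
  X <- cbind(1, do.call(cbind, lapply(seq_len(n_harmonics), function(m)
    cbind(cos(2 * pi * m * s), sin(2 * pi * m * s)))))
  for (j in 1:2) {
    fit <- stats::lm.fit(X, st[, j])
    st[, j] <- X %*% fit$coefficients
  }
  aaa_centerline(st, layer = cl$layer)
}

#' Resample a centerline to K stations
#'
#' Linear interpolation of c_x and c_y in z at `K` evenly spaced z values,
#' or at a supplied `z_grid` (used to force one patient-common lattice
#' across scans).
#'
#' @param cl An [aaa_centerline()].
#' @param K Number of output stations (ignored when `z_grid` given).
#' @param z_grid Optional explicit station z values inside the centerline
#'   extent.
#' @return Resampled [aaa_centerline()].
#' @export
resample_stations <- function(cl, K = 100L, z_grid = NULL) {
  st <- cl$stations
  z <- st[, 3]
  if (is.null(z_grid)) {
    if (!is_count(K, 2L)) stop_validation("K must be an integer >= 2")
    z_grid <- seq(z[1], z[length(z)], length.out = K)
  }
  if (min(z_grid) < z[1] - 1e-12 || max(z_grid) > z[length(z)] + 1e-12)
    stop_extrapolation("z_grid [%g, %g] outside centerline extent [%g, %g]",
                       min(z_grid), max(z_grid), z[1], z[length(z)])
  x <- stats::approx(z, st[, 1], xout = z_grid)$y
  y <- stats::approx(z, st[, 2], xout = z_grid)$y
  out <- cbind(x, y, z_grid)
  if (nrow(out) < 3L) {
    # degenerate 2-station grid: keep as bare matrix with class for chaining
    return(structure(list(stations = out, layer = cl$layer), class = "aaa_centerline"))
  }
  aaa_centerline(out, layer = cl$layer)
}

#' Write / read a centerline as CSV
#'
#' Columns `station_index, c_x, c_y, c_z` (cm); a `#`-comment records the
#' layer and K.
#'
#' @param cl An [aaa_centerline()].
#' @param path CSV path.
#' @return `path` (write) or an [aaa_centerline()] (read).
#' @export
write_centerline_csv <- function(cl, path) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(sprintf("# layer=%s K=%d", cl$layer, nrow(cl$stations)), con)
  writeLines("station_index,c_x,c_y,c_z", con)
  st <- cl$stations
  writeLines(sprintf("%d,%.17g,%.17g,%.17g", seq_len(nrow(st)), st[, 1], st[, 2], st[, 3]), con)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[[1]]
  layer <- sub("^# layer=(\\S+).*", "\\1", meta)
  vals <- utils::read.csv(textConnection(lines[-1]))
  aaa_centerline(as.matrix(vals[, c("c_x", "c_y", "c_z")]), layer = layer)
}
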