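# Slicing-based cylindrical parameterization and its inverse.
#
# A surface is unwrapped onto the fixed (z_k, theta_i) lattice: at each
# centerline station the constant-z cross-section is extracted, resampled
# uniformly, translated to the local centerline origin, mapped to polar
# coordinates and interpolated (periodically in theta) onto the angular
# lattice. The temporal change of a patient's anatomy is carried entirely
# by the resulting K x N radius matrix.

#' Construct a cylindrical grid
#'
#' @param radii K x N matrix of radii (cm), all finite and positive.
#' @param z_axis K station levels (cm), strictly increasing.
#' @param theta_grid N lattice angles; defaults to [theta_axis()].
#' @param layer `"lumen"` or `"outer_wall"`.
#' @return Object of class `aaa_grid`.
#' @export
aaa_grid <- function(radii, z_axis, theta_grid = NULL, layer = "outer_wall") {
  radii <- as.matrix(radii)
  dimnames(radii) <- NULL
  layer <- match.arg(layer, LAYERS)
  K <- nrow(radii); N <- ncol(radii)
  theta_grid <- theta_grid %||% theta_axis(N)
  if (length(z_axis) != K) stop_lattice("z_axis length %d != K = %d", length(z_axis), K)
  if (length(theta_grid) != N) stop_lattice("theta length %d != N = %d", length(theta_grid), N)
  if (any(diff(z_axis) <= 0)) stop_lattice("z_axis must be strictly increasing")
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop_validation("grid radii must be finite and positive")
  structure(list(radii = radii, z_axis = as.numeric(z_axis),
                 theta = as.numeric(theta_grid), layer = layer),
            class = "aaa_grid")
}

#' @export
print.aaa_grid <- function(x, ...) {
  cat(sprintf("<aaa_grid> %s: K=%d x N=%d nodes, r in [%.3f, %.3f] cm\n",
              x$layer, nrow(x$radii), ncol(x$radii), min(x$radii), max(x$radii)))
  invisible(x)
}

#' Cylindrical parameterization of a surface about a centerline
#'
#' For each station k the surface is sliced at z_k, the contour resampled
#' to N points at uniform arclength (starting at the smallest angle about
#' the station), translated to the station origin, mapped to polar
#' coordinates and interpolated onto the angular lattice. Cross-sections
#' must be star-shaped about their station; violations raise a warning and
#' are resolved by keeping, per angle, the outermost sample.
#'
#' @param mesh An [aaa_mesh()].
#' @param cl An [aaa_centerline()] whose stations define z_k; stations must
#'   lie inside the mesh at every level.
#' @param N Angular lattice size (default 100, giving the default
#'   100 x 100 = 10,000-node lattice).
#' @return List with `grid` (an [aaa_grid()]) and `slices` (the raw
#'   resampled Cartesian contours S_k, one [aaa_contour()] per station).
#' @export
parameterize_surface <- function(mesh, cl, N = 100L) {
  st <- cl$stations
  K <- nrow(st)
  radii <- matrix(NA_real_, K, N)
  th_grid <- theta_axis(N)
  slices <- vector("list", K)
  for (k in seq_len(K)) {
    res <- tryCatch({
      center <- st[k, 1:2]
      ct <- slice_at_level(mesh, st[k, 3], center = center)
      ct <- resample_contour(ct, N, center = center)
      samples <- to_cylindrical(ct, center)
      if (theta_backtracks(samples[, 2]) > 2L) {
        warning(sprintf("station %d: cross-section not star-shaped; keeping outer envelope", k),
                call. = FALSE)
        samples <- theta_envelope(samples, nbins = 4L * N)
      }
      list(row = grid_row_interpolate(samples, th_grid), slice = ct)
    }, aaafc_error = function(e)
      aaafc_stop(class(e)[1], "station %d (z = %g): %s", k, st[k, 3], conditionMessage(e)))
    radii[k, ] <- res$row
    slices[[k]] <- res$slice
  }
  list(grid = aaa_grid(radii, z_axis = st[, 3], theta_grid = th_grid, layer = mesh$layer),
       slices = slices)
}

#' Back-project a cylindrical grid to a Cartesian point cloud
#'
#' Node (k, i) maps to
#' `(c_x_k + r_ki * cos(theta_i), c_y_k + r_ki * sin(theta_i), z_k)`.
#'
#' @param grid An [aaa_grid()].
#' @param cl An [aaa_centerline()] with the same K stations at the same z_k.
#' @return (K*N) x 3 matrix of Cartesian points, nodes in row-major
#'   (station-fastest) order `n = (k - 1) * N + i`.
#' @export
inverse_map <- function(grid, cl) {
  st <- cl$stations
  K <- nrow(grid$radii); N <- ncol(grid$radii)
  if (nrow(st) != K) stop_lattice("centerline K = %d != grid K = %d", nrow(st), K)
  if (max(abs(st[, 3] - grid$z_axis)) > 1e-9)
    stop_lattice("centerline z stations do not match the grid z_axis")
  ct <- cos(grid$theta); snt <- sin(grid$theta)
  x <- st[, 1] + grid$radii * matrix(ct, K, N, byrow = TRUE)
  y <- st[, 2] + grid$radii * matrix(snt, K, N, byrow = TRUE)
  z <- matrix(st[, 3], K, N)
  cbind(as.vector(t(x)), as.vector(t(y)), as.vector(t(z)))
}

#' Unwrapped (r, theta, z) point cloud of a grid
#'
#' @param grid An [aaa_grid()].
#' @return (K*N) x 3 matrix with columns r (cm), theta (rad), z (cm), in
#'   the same node order as [inverse_map()].
#' @export
unwrapped_cloud <- function(grid) {
  K <- nrow(grid$radii); N <- ncol(grid$radii)
  cbind(as.vector(t(grid$radii)),
        rep(grid$theta, times = K),
        rep(grid$z_axis, each = N))
}

#' Constant-z Cartesian contours reconstructed from a grid
#'
#' One closed N-point contour per station, back-projected about the given
#' centerline; used for hydraulic-diameter and volume scalars so that
#' forecast and ground truth pass through the same representation.
#'
#' @param grid An [aaa_grid()].
#' @param cl Matching [aaa_centerline()].
#' @return List of K [aaa_contour()] objects.
#' @export
grid_contours <- function(grid, cl) {
  pts <- inverse_map(grid, cl)
  N <- ncol(grid$radii)
  lapply(seq_len(nrow(grid$radii)), function(k) {
    aaa_contour(pts[(k - 1L) * N + seq_len(N), , drop = FALSE])
  })
}

#' Write / read a cylindrical grid as long-format CSV
#'
#' Columns `k, i, z_k, theta_i, r`; a `#`-comment records layer and lattice
#' size.
#'
#' @param grid An [aaa_grid()].
#' @param path CSV path.
#' @return `path` (write) or an [aaa_grid()] (read).
#' @export
write_grid_csv <- function(grid, path) {
  K <- nrow(grid$radii); N <- ncol(grid$radii)
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(sprintf("# layer=%s K=%d N=%d", grid$layer, K, N), con)
  writeLines("k,i,z_k,theta_i,r", con)
  k <- rep(seq_len(K), each = N); i <- rep(seq_len(N), times = K)
  writeLines(sprintf("%d,%d,%.17g,%.17g,%.17g", k, i,
                     grid$z_axis[k], grid$theta[i], t(grid$radii)[cbind(i, k)]), con)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  layer <- sub("^# layer=(\\S+).*", "\\1", lines[[1]])
  d <- utils::read.csv(textConnection(lines[-1]))
  K <- max(d$k); N <- max(d$i)
  radii <- matrix(NA_real_, K, N)
  radii[cbind(d$k, d$i)] <- d$r
  z <- sort(unique(d$z_k))
  th <- sort(unique(d$theta_i))
  aaa_grid(radii, z_axis = z, theta_grid = th, layer = layer)
}
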