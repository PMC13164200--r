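# Constant-z slicing of triangulated surfaces and contour operations.
#
# A contour is an ordered closed loop of M points at constant z, oriented
# counter-clockwise viewed from +z. Slicing intersects each triangle with
# the plane z = z0, chains the resulting segments into loops (endpoint
# matching within 1e-6 of the bounding-box diagonal) and returns one loop.

#' Construct a planar contour
#'
#' @param points M x 3 matrix of ordered points sharing one z.
#' @param z Slice level (cm); defaults to the common point z.
#' @return Object of class `aaa_contour` (closed loop, CCW from +z).
#' @export
aaa_contour <- function(points, z = NULL) {
  points <- as.matrix(points)
  dimnames(points) <- NULL
  if (nrow(points) < 3L) stop_geometry("contour needs >= 3 points, got %d", nrow(points))
  z <- z %||% points[1, 3]
  if (max(abs(points[, 3] - z)) > 1e-9)
    stop_geometry("contour points do not share z = %g within 1e-9", z)
  structure(list(points = points, z = z, closed = TRUE), class = "aaa_contour")
}

#' @export
print.aaa_contour <- function(x, ...) {
  cat(sprintf("<aaa_contour> %d points at z = %.4f cm, perimeter %.4f cm\n",
              nrow(x$points), x$z, contour_perimeter(x)))
  invisible(x)
}

#' Polygon area, perimeter and area centroid of a contour
#'
#' Shoelace area of the (x, y) projection; the loop is closed implicitly.
#'
#' @param contour An [aaa_contour()].
#' @return `contour_area`: signed area (positive for CCW) in cm^2;
#'   `contour_perimeter`: length in cm; `contour_centroid`: (x, y) area
#'   centroid.
#' @export
contour_area <- function(contour) {
  p <- contour$points
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' @rdname contour_area
#' @export
contour_perimeter <- function(contour) {
  p <- contour$points
  d <- rbind(diff(p[, 1:2, drop = FALSE]), p[1, 1:2] - p[nrow(p), 1:2])
  sum(sqrt(rowSums(d^2)))
}

#' @rdname contour_area
#' @export
contour_centroid <- function(contour) {
  p <- contour$points
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-14) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' Intersect a surface with the plane z = z0
#'
#' Triangle-plane intersection segments are chained into closed loops. When
#' the plane cuts several loops, the loop whose area centroid is nearest
#' `center` is returned (the largest-area loop when `center` is `NULL`).
#' The result is oriented counter-clockwise viewed from +z.
#'
#' @param mesh An [aaa_mesh()].
#' @param z Slice level (cm), strictly inside the mesh z-extent.
#' @param center Optional (x, y) point selecting among multiple loops.
#' @return An [aaa_contour()].
#' @export
slice_at_level <- function(mesh, z, center = NULL) {
  zr <- mesh_z_range(mesh)
  if (z <= zr[1] || z >= zr[2])
    stop_geometry("slice level z = %g not strictly inside mesh z-extent [%g, %g]",
                  z, zr[1], zr[2])
  v <- mesh$vertices; f <- mesh$faces
  segs <- tri_plane_segments(v, f, z, eps = 1e-9 * max(1, abs(zr[2] - zr[1])))
  if (is.null(segs)) stop_geometry("no intersection at z = %g", z)
  loops <- chain_segments(segs, tol = 1e-6 * bbox_diag(mesh))
  contours <- lapply(loops, function(P) aaa_contour(cbind(P, z), z = z))
  pick <- if (is.null(center)) {
    which.max(vapply(contours, function(ct) abs(contour_area(ct)), numeric(1)))
  } else {
    cents <- t(vapply(contours, contour_centroid, numeric(2)))
    which.min((cents[, 1] - center[1])^2 + (cents[, 2] - center[2])^2)
  }
  ct <- contours[[pick]]
  if (contour_area(ct) < 0) ct$points <- ct$points[rev(seq_len(nrow(ct$points))), , drop = FALSE]
  ct
}

# Triangle-plane intersection segments, robust to vertices lying exactly
# on the plane (within eps): vertices are classified below / on / above;
# straddling triangles contribute the segment of their two edge crossings,
# a triangle with one on-vertex and a straddling opposite edge contributes
# the on-vertex-to-crossing segment, and an on-edge (two on-vertices) is
# emitted once, by the triangle whose third vertex lies above the plane.
# Returns an S x 4 matrix (x1, y1, x2, y2), or NULL when nothing crosses.
#' @noRd
tri_plane_segments <- function(v, f, z, eps) {
  vz <- v[, 3]
  sgn <- integer(length(vz))
  sgn[vz > z + eps] <- 1L
  sgn[vz < z - eps] <- -1L
  s1 <- sgn[f[, 1]]; s2 <- sgn[f[, 2]]; s3 <- sgn[f[, 3]]
  n_on <- (s1 == 0L) + (s2 == 0L) + (s3 == 0L)
  cross_pt <- function(ia, ib) {
    A <- v[ia, , drop = FALSE]; B <- v[ib, , drop = FALSE]
    t <- (z - A[, 3]) / (B[, 3] - A[, 3])
    cbind(A[, 1] + t * (B[, 1] - A[, 1]), A[, 2] + t * (B[, 2] - A[, 2]))
  }
  segs <- list()
  # generic straddle: no on-vertex, both signs present
  gen <- which(n_on == 0L & pmin(s1, s2, s3) < 0L & pmax(s1, s2, s3) > 0L)
  if (length(gen)) {
    fs <- f[gen, , drop = FALSE]
    odd <- ifelse(s1[gen] == s2[gen], 3L, ifelse(s1[gen] == s3[gen], 2L, 1L))
    ia <- fs[cbind(seq_along(gen), odd)]
    ib <- fs[cbind(seq_along(gen), odd %% 3L + 1L)]
    ic <- fs[cbind(seq_along(gen), (odd + 1L) %% 3L + 1L)]
    p1 <- cross_pt(ia, ib); p2 <- cross_pt(ia, ic)
    segs[[length(segs) + 1L]] <- cbind(p1, p2)
  }
  # one vertex on the plane, opposite edge straddling
  one <- which(n_on == 1L)
  if (length(one)) {
    fs <- f[one, , drop = FALSE]
    ss <- cbind(s1[one], s2[one], s3[one])
    onpos <- apply(ss == 0L, 1, which.max)
    straddle <- rowSums(ss) == 0L            # remaining two vertices oppose
    if (any(straddle)) {
      keep <- which(straddle)
      iv <- fs[cbind(keep, onpos[keep])]
      ib <- fs[cbind(keep, onpos[keep] %% 3L + 1L)]
      ic <- fs[cbind(keep, (onpos[keep] + 1L) %% 3L + 1L)]
      pc <- cross_pt(ib, ic)
      segs[[length(segs) + 1L]] <- cbind(v[iv, 1], v[iv, 2], pc)
    }
  }
  # on-edge: two vertices on the plane; emit once (third vertex above)
  two <- which(n_on == 2L & (s1 + s2 + s3) == 1L)
  if (length(two)) {
    fs <- f[two, , drop = FALSE]
    ss <- cbind(s1[two], s2[two], s3[two])
    offpos <- apply(ss == 1L, 1, which.max)
    ia <- fs[cbind(seq_along(two), offpos %% 3L + 1L)]
    ib <- fs[cbind(seq_along(two), (offpos + 1L) %% 3L + 1L)]
    segs[[length(segs) + 1L]] <- cbind(v[ia, 1], v[ia, 2], v[ib, 1], v[ib, 2])
  }
  if (length(segs) == 0L) return(NULL)
  out <- do.call(rbind, segs)
  # drop zero-length contacts
  keep <- (out[, 1] - out[, 3])^2 + (out[, 2] - out[, 4])^2 > 0
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) NULL else out
}

# Chain unordered segments into closed loops by snapping endpoints to a
# tolerance grid; every snapped endpoint must join exactly two segments.
#' @noRd
chain_segments <- function(segs, tol) {
  n <- nrow(segs)
  ends <- rbind(segs[, 1:2, drop = FALSE], segs[, 3:4, drop = FALSE])
  key <- paste(round(ends[, 1] / tol), round(ends[, 2] / tol))
  uk <- unique(key)
  node <- match(key, uk)                     # 2n endpoint -> node id
  a <- node[seq_len(n)]; b <- node[n + seq_len(n)]
  # drop segments collapsing to a point after snapping (and exact duplicates)
  keep <- a != b & !duplicated(paste(pmin(a, b), pmax(a, b)))
  if (!all(keep)) {
    segs <- segs[keep, , drop = FALSE]
    n <- nrow(segs)
    if (n < 3L) stop_topology("slice degenerates after snapping")
    ends <- rbind(segs[, 1:2, drop = FALSE], segs[, 3:4, drop = FALSE])
    key <- paste(round(ends[, 1] / tol), round(ends[, 2] / tol))
    uk <- unique(key)
    node <- match(key, uk)
    a <- node[seq_len(n)]; b <- node[n + seq_len(n)]
  }
  deg <- tabulate(c(a, b), nbins = length(uk))
  if (any(deg != 2L))
    stop_topology("unchainable slice: %d endpoints with degree != 2 (tolerance gap)",
                  sum(deg != 2L))
  # node -> the (up to 2) segments touching it
  seg_at <- split(rep(seq_len(n), 2L), c(a, b))
  used <- rep(FALSE, n)
  loops <- list()
  for (s0 in seq_len(n)) {
    if (used[s0]) next
    loop_nodes <- integer(0)
    cur_seg <- s0; cur_node <- a[s0]
    repeat {
      used[cur_seg] <- TRUE
      loop_nodes <- c(loop_nodes, cur_node)
      nxt_node <- if (a[cur_seg] == cur_node) b[cur_seg] else a[cur_seg]
      cand <- seg_at[[as.character(nxt_node)]]
      nxt_seg <- cand[!used[cand]]
      if (length(nxt_seg) == 0L) { loop_nodes <- c(loop_nodes, nxt_node); break }
      cur_seg <- nxt_seg[[1]]; cur_node <- nxt_node
    }
    # drop closing duplicate
    if (loop_nodes[1] == loop_nodes[length(loop_nodes)])
      loop_nodes <- loop_nodes[-length(loop_nodes)]
    # actual coordinates: first occurrence of each node id
    coords <- ends[match(loop_nodes, node), , drop = FALSE]
    if (nrow(coords) >= 3L) loops[[length(loops) + 1L]] <- coords
  }
  if (length(loops) == 0L) stop_topology("no closed loop recovered from slice")
  loops
}

#' Resample a closed contour to N points at uniform arclength
#'
#' Points are placed at equal arclength spacing along the polyline,
#' starting from the vertex of smallest polar angle theta about `center`.
#' The perimeter is preserved (the samples lie on the original polyline).
#'
#' @param contour An [aaa_contour()].
#' @param N Number of output points.
#' @param center (x, y) about which theta is measured; defaults to the
#'   contour area centroid.
#' @return An [aaa_contour()] with N points.
#' @export
resample_contour <- function(contour, N, center = NULL) {
  p <- contour$points
  per <- contour_perimeter(contour)
  if (per <= 0) stop_geometry("degenerate contour with zero perimeter")
  center <- center %||% contour_centroid(contour)
  th <- atan2(p[, 2] - center[2], p[, 1] - center[1])
  i0 <- which.min(th)
  idx <- c(i0:nrow(p), seq_len(i0 - 1L))
  p <- p[idx, , drop = FALSE]
  closed <- rbind(p, p[1, ])
  seglen <- sqrt(rowSums(diff(closed[, 1:2, drop = FALSE])^2))
  s <- c(0, cumsum(seglen))                  # 0 .. perimeter
  target <- per * (seq_len(N) - 1L) / N
  xi <- stats::approx(s, closed[, 1], xout = target)$y
  yi <- stats::approx(s, closed[, 2], xout = target)$y
  aaa_contour(cbind(xi, yi, contour$z), z = contour$z)
}

#' Map a contour to polar samples about a local center
#'
#' `r = sqrt((x - c_x)^2 + (y - c_y)^2)`, `theta = atan2(y - c_y, x - c_x)`.
#' The center must lie strictly inside the contour (star-shape assumption).
#'
#' @param contour An [aaa_contour()].
#' @param center (c_x, c_y) local centerline origin.
#' @return M x 2 matrix with columns `r` (cm, > 0) and `theta`
#'   (radians in \eqn{[-\pi, \pi)}).
#' @export
to_cylindrical <- function(contour, center) {
  p <- contour$points
  if (!point_in_polygon(center, p[, 1:2, drop = FALSE]))
    stop_parameterization("center (%.4g, %.4g) not strictly inside the contour at z = %g",
                          center[1], center[2], contour$z)
  dx <- p[, 1] - center[1]; dy <- p[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  if (any(r <= 0)) stop_parameterization("contour passes through the center")
  cbind(r = r, theta = wrap_angle(atan2(dy, dx)))
}

# even-odd ray casting
#' @noRd
point_in_polygon <- function(pt, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  inside <- FALSE
  crosses <- ((y > pt[2]) != (y[j] > pt[2])) &
    (pt[1] < (x[j] - x) * (pt[2] - y) / (y[j] - y) + x)
  sum(crosses, na.rm = TRUE) %% 2L == 1L
}

#' Interpolate polar samples of one slice onto the fixed angular lattice
#'
#' Samples are sorted by theta (exact ties averaged), replicated at
#' theta +- 2*pi (periodic augmentation) and linearly interpolated at each
#' lattice angle, so the seam at theta = +-pi is continuous.
#'
#' @param samples M x 2 matrix (r, theta) from [to_cylindrical()].
#' @param theta_grid Angular lattice from [theta_axis()].
#' @return Numeric vector of N radii, finite and positive.
#' @export
grid_row_interpolate <- function(samples, theta_grid) {
  r <- samples[, 1]; th <- samples[, 2]
  if (length(r) < 3L) stop_degenerate("need >= 3 polar samples, got %d", length(r))
  o <- order(th)
  th <- th[o]; r <- r[o]
  if (anyDuplicated(th)) {
    r <- as.numeric(tapply(r, th, mean))
    th <- sort(unique(th))
  }
  if (length(unique(th)) < 2L) stop_degenerate("all polar samples share one theta")
  th_aug <- c(th - 2 * pi, th, th + 2 * pi)
  r_aug <- c(r, r, r)
  out <- stats::approx(th_aug, r_aug, xout = theta_grid)$y
  if (any(!is.finite(out)) || any(out <= 0))
    stop_degenerate("interpolated radii not finite/positive")
  out
}

# Outer envelope for non-star-shaped sample sets: per fine theta bin keep
# the sample of maximal r (conservative for an aneurysm wall).
#' @noRd
theta_envelope <- function(samples, nbins) {
  th <- samples[, 2]; r <- samples[, 1]
  bin <- floor((th + pi) / (2 * pi) * nbins)
  bin[bin >= nbins] <- nbins - 1L
  keep <- unlist(lapply(split(seq_along(r), bin), function(ii) ii[which.max(r[ii])]),
                 use.names = FALSE)
  samples[sort(keep), , drop = FALSE]
}

# count of backtracks in theta along the contour order (0 for star-shaped)
#' @noRd
theta_backtracks <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))      # unwrap single jumps
  sgn <- sign(d[d != 0])
  if (length(sgn) < 2L) return(0L)
  sum(diff(sgn) != 0)
}
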