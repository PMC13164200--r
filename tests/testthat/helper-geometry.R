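# Analytic mesh builders and independent oracles used across tests.

# Unit cube [0,1]^3: 8 vertices, 12 consistently oriented faces.
cube_vertices <- function() {
  as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
}

cube_faces <- function() {
  # outward-oriented triangulation of the 6 quads
  rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
}

cube_mesh <- function() aaa_mesh(cube_vertices(), cube_faces())

# Closed cylinder-like tube: rings of n_theta vertices between z0 and z1,
# radius r(z) (function or constant), axis (ax(z), ay(z)), capped ends.
tube_mesh <- function(r = 1, z0 = 0, z1 = 1, n_theta = 64L, n_z = 33L,
                      ax = function(z) 0 * z, ay = function(z) 0 * z,
                      theta_offset = 0, layer = "outer_wall") {
  rf <- if (is.function(r)) r else function(z) rep(r, length(z))
  zs <- seq(z0, z1, length.out = n_z)
  th <- -pi + 2 * pi * (seq_len(n_theta) - 1) / n_theta + theta_offset
  verts <- do.call(rbind, lapply(zs, function(z)
    cbind(ax(z) + rf(z) * cos(th), ay(z) + rf(z) * sin(th), z)))
  bottom <- n_z * n_theta + 1L; top <- n_z * n_theta + 2L
  verts <- rbind(verts, c(ax(z0), ay(z0), z0), c(ax(z1), ay(z1), z1))
  faces <- list()
  for (j in seq_len(n_z - 1L)) {
    a <- (j - 1L) * n_theta + seq_len(n_theta)
    b <- (j - 1L) * n_theta + c(seq_len(n_theta)[-1], 1L)
    cc <- j * n_theta + seq_len(n_theta)
    d <- j * n_theta + c(seq_len(n_theta)[-1], 1L)
    faces[[j]] <- rbind(cbind(a, b, cc), cbind(b, d, cc))
  }
  i1 <- seq_len(n_theta); i2 <- c(seq_len(n_theta)[-1], 1L)
  faces[[n_z]] <- cbind(i2, i1, bottom)
  faces[[n_z + 1L]] <- cbind((n_z - 1L) * n_theta + i1, (n_z - 1L) * n_theta + i2, top)
  aaa_mesh(verts, do.call(rbind, faces), layer = layer)
}

# Lat-long triangulated sphere.
sphere_mesh <- function(radius = 1, center = c(0, 0, 0), n_lat = 48L, n_lon = 96L) {
  phi <- seq(-pi / 2, pi / 2, length.out = n_lat + 2L)[2:(n_lat + 1L)]
  th <- -pi + 2 * pi * (seq_len(n_lon) - 1) / n_lon
  verts <- do.call(rbind, lapply(phi, function(p)
    cbind(radius * cos(p) * cos(th), radius * cos(p) * sin(th), radius * sin(p))))
  south <- n_lat * n_lon + 1L; north <- n_lat * n_lon + 2L
  verts <- rbind(verts, c(0, 0, -radius), c(0, 0, radius))
  verts <- sweep(verts, 2, center, "+")
  faces <- list()
  for (j in seq_len(n_lat - 1L)) {
    a <- (j - 1L) * n_lon + seq_len(n_lon)
    b <- (j - 1L) * n_lon + c(seq_len(n_lon)[-1], 1L)
    cc <- j * n_lon + seq_len(n_lon)
    d <- j * n_lon + c(seq_len(n_lon)[-1], 1L)
    faces[[j]] <- rbind(cbind(a, b, cc), cbind(b, d, cc))
  }
  i1 <- seq_len(n_lon); i2 <- c(seq_len(n_lon)[-1], 1L)
  faces[[n_lat]] <- cbind(i2, i1, south)
  faces[[n_lat + 1L]] <- cbind((n_lat - 1L) * n_lon + i1, (n_lat - 1L) * n_lon + i2, north)
  aaa_mesh(verts, do.call(rbind, faces))
}

# Torus-segment tube: centerline is the arc (R cos phi, 0, R sin phi),
# phi in [phi0, phi1] (z monotone for phi in (0, pi/2)); tube radius a in
# the plane spanned by the radial direction and y. Capped ends.
torus_segment_mesh <- function(R = 5, a = 0.8, phi0 = 20 * pi / 180,
                               phi1 = 70 * pi / 180, n_phi = 200L, n_psi = 96L) {
  phis <- seq(phi0, phi1, length.out = n_phi)
  psi <- -pi + 2 * pi * (seq_len(n_psi) - 1) / n_psi
  verts <- do.call(rbind, lapply(phis, function(p) {
    er <- c(cos(p), 0, sin(p))
    cen <- R * er
    t(cen + outer(er, a * cos(psi)) + outer(c(0, 1, 0), a * sin(psi)))
  }))
  b1 <- n_phi * n_psi + 1L; b2 <- n_phi * n_psi + 2L
  verts <- rbind(verts, R * c(cos(phi0), 0, sin(phi0)), R * c(cos(phi1), 0, sin(phi1)))
  faces <- list()
  for (j in seq_len(n_phi - 1L)) {
    a_ <- (j - 1L) * n_psi + seq_len(n_psi)
    b_ <- (j - 1L) * n_psi + c(seq_len(n_psi)[-1], 1L)
    cc <- j * n_psi + seq_len(n_psi)
    d <- j * n_psi + c(seq_len(n_psi)[-1], 1L)
    faces[[j]] <- rbind(cbind(a_, b_, cc), cbind(b_, d, cc))
  }
  i1 <- seq_len(n_psi); i2 <- c(seq_len(n_psi)[-1], 1L)
  faces[[n_phi]] <- cbind(i2, i1, b1)
  faces[[n_phi + 1L]] <- cbind((n_phi - 1L) * n_psi + i1, (n_phi - 1L) * n_psi + i2, b2)
  aaa_mesh(verts, do.call(rbind, faces))
}

# Oracle: area centroid x of the torus-segment section at height z0
# (centerline circle of radius R in the x-z plane, tube radius a), by
# dense strip integration of the implicit section
# (sqrt(x^2 + z0^2) - R)^2 + y^2 <= a^2 over x > 0.
torus_section_centroid_x <- function(R, a, z0, n = 20000L) {
  xlo <- sqrt((R - a)^2 - z0^2)
  xhi <- sqrt((R + a)^2 - z0^2)
  x <- seq(xlo, xhi, length.out = n)
  h2 <- a^2 - (sqrt(x^2 + z0^2) - R)^2
  h <- sqrt(pmax(h2, 0))
  sum(x * h) / sum(h)
}

# Dense polygon approximating an ellipse cross-section at height z.
ellipse_contour <- function(a = 2, b = 1, z = 0, n = 400L, center = c(0, 0)) {
  th <- -pi + 2 * pi * (seq_len(n) - 1) / n
  aaa_contour(cbind(center[1] + a * cos(th), center[2] + b * sin(th), z))
}

# Independent periodic linear interpolation oracle for one slice row.
periodic_interp_oracle <- function(r, th, theta_grid) {
  o <- order(th); th <- th[o]; r <- r[o]
  tha <- c(th - 2 * pi, th, th + 2 * pi)
  ra <- c(r, r, r)
  vapply(theta_grid, function(q) {
    j <- max(which(tha <= q))
    w <- (q - tha[j]) / (tha[j + 1] - tha[j])
    (1 - w) * ra[j] + w * ra[j + 1]
  }, numeric(1))
}

# Brute-force O(|A|*|B|) nearest-neighbour HD95 oracle: per-point loop,
# coordinate-wise squared differences added in column order (plain double
# arithmetic), quantile type 7 on the combined list.
hd95_oracle <- function(A, B, probs = 0.95) {
  one_way <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(i) {
      d2 <- (Q[, 1] - P[i, 1])^2
      for (k in seq_len(ncol(Q))[-1]) d2 <- d2 + (Q[, k] - P[i, k])^2
      sqrt(min(d2))
    }, numeric(1))
  }
  stats::quantile(c(one_way(A, B), one_way(B, A)), probs = probs, type = 7, names = FALSE)
}

# Exact-linear-growth aaa_param built directly from radius/centerline
# fields (bypasses meshes): radius field r0 + slope * t on a K x N
# lattice, centerline x = dx * t about a straight axis.
make_linear_param <- function(K = 12L, N = 16L, times = c(0, 300, 700, 1200),
                              r_int = NULL, r_slope = NULL,
                              cx_slope = 0, patient_id = "LIN") {
  z <- seq(0, 8, length.out = K)
  th <- theta_axis(N)
  if (is.null(r_int)) r_int <- matrix(2 + 0.5 * outer(exp(-(z - 4)^2 / 4), rep(1, N)), K, N)
  if (is.null(r_slope)) r_slope <- matrix(3e-4, K, N)
  out <- list(times = times, z_axis = z, theta = th, patient_id = patient_id,
              K = K, N = N)
  for (layer in c("lumen", "outer_wall")) {
    off <- if (layer == "lumen") 0.5 else 0
    grids <- lapply(times, function(t)
      aaa_grid(r_int - off + r_slope * t, z_axis = z, theta_grid = th, layer = layer))
    cls <- lapply(times, function(t)
      aaa_centerline(cbind(cx_slope * t * sin(pi * z / 8), 0 * z, z), layer = layer))
    out[[layer]] <- list(grids = grids, centerlines = cls)
  }
  structure(out, class = "aaa_param")
}

sort_rows <- function(m) {
  m <- unname(as.matrix(m))
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# minimal binary STL writer used only as a fixture generator
write_binary_stl <- function(mesh, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(raw(80L), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  for (i in seq_len(nf)) {
    tri <- mesh$vertices[mesh$faces[i, ], ]
    writeBin(as.numeric(c(0, 0, 0, t(tri))), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
}
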