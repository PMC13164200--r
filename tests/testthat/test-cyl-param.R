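# Slicing, contour resampling, polar mapping, lattice interpolation,
# forward parameterization and back-projection.

test_that("slicing analytic solids recovers their sections", {
  cyl <- tube_mesh(r = 1, z0 = 0, z1 = 2, n_theta = 4096L, n_z = 3L)
  ct <- slice_at_level(cyl, 0.73)
  r <- sqrt(ct$points[, 1]^2 + ct$points[, 2]^2)
  expect_lt(max(abs(r - 1)), 1e-6)
  expect_gt(contour_area(ct), 0)            # CCW orientation

  sph <- sphere_mesh(radius = 2, n_lat = 96L, n_lon = 192L)
  cts <- slice_at_level(sph, 1)
  rs <- sqrt(cts$points[, 1]^2 + cts$points[, 2]^2)
  expect_lt(max(abs(rs - sqrt(3))), 1e-3)

  expect_error(slice_at_level(cyl, 2.5), class = "aaafc_geometry_error")
})

test_that("the loop nearest the requested center is selected among several", {
  c1 <- tube_mesh(r = 0.5, z0 = 0, z1 = 2, n_theta = 48L, n_z = 5L)
  c2 <- tube_mesh(r = 0.8, z0 = 0, z1 = 2, n_theta = 48L, n_z = 5L,
                  ax = function(z) 5 + 0 * z)
  merged <- aaa_mesh(rbind(c1$vertices, c2$vertices),
                     rbind(c1$faces, c2$faces + nrow(c1$vertices)))
  # brute-force oracle: label loops by connected components of snapped
  # segment endpoints and pick the component nearest each axis
  ct1 <- slice_at_level(merged, 1, center = c(0, 0))
  ct2 <- slice_at_level(merged, 1, center = c(5, 0))
  expect_lt(max(abs(sqrt(ct1$points[, 1]^2 + ct1$points[, 2]^2) - 0.5)), 1e-6)
  expect_lt(max(abs(sqrt((ct2$points[, 1] - 5)^2 + ct2$points[, 2]^2) - 0.8)), 1e-6)
  # with no center, the larger-area loop wins
  expect_equal(abs(contour_area(slice_at_level(merged, 1))),
               abs(contour_area(ct2)), tolerance = 1e-12)
})

test_that("contour resampling is uniform in arclength from the min-angle start", {
  sq <- aaa_contour(cbind(c(1, -1, -1, 1), c(1, 1, -1, -1), 0))
  rs <- resample_contour(sq, 4L, center = c(0, 0))
  d <- sqrt(rowSums((rs$points - rs$points[c(2:4, 1), ])^2))
  expect_equal(d, rep(contour_perimeter(sq) / 4, 4L), tolerance = 1e-12)

  circ <- ellipse_contour(a = 1, b = 1, n = 400L)
  rc <- resample_contour(circ, 100L, center = c(0, 0))
  dc <- sqrt(rowSums((rc$points - rc$points[c(2:100, 1), ])^2))
  expect_lt(diff(range(dc)), 1e-9)

  # irregular hexagon: positions must match a direct polyline walk
  hexa <- aaa_contour(cbind(c(2, 1, -1, -2, -1, 1), c(0, 1.5, 1.5, 0, -1.5, -1.5), 0))
  rh <- resample_contour(hexa, 6L, center = c(0, 0))
  P <- contour_perimeter(hexa)
  walk <- function(poly, s) {               # brute-force arclength walk
    closed <- rbind(poly, poly[1, ])
    seg <- sqrt(rowSums(diff(closed)^2))
    cum <- c(0, cumsum(seg))
    j <- max(which(cum <= s + 1e-12))
    if (j > length(seg)) return(closed[j, ])
    w <- (s - cum[j]) / seg[j]
    (1 - w) * closed[j, ] + w * closed[j + 1, ]
  }
  th0 <- atan2(hexa$points[, 2], hexa$points[, 1])
  start <- which.min(th0)
  poly <- hexa$points[c(start:6, seq_len(start - 1L)), 1:2]
  for (j in 1:6)
    expect_equal(rh$points[j, 1:2], unname(walk(poly, (j - 1) * P / 6)),
                 tolerance = 1e-12)

  expect_error(resample_contour(aaa_contour(matrix(c(1, 1, 0, 1, 1, 0, 1, 1, 0), 3,
                                                   byrow = TRUE)), 10L),
               class = "aaafc_geometry_error")
})

test_that("polar mapping matches axis points and the ellipse closed form", {
  # square about (2, -1) whose vertices include the two axis points
  sq <- aaa_contour(cbind(c(3, 2, 1, 2), c(-1, 1, -1, -3), 0))
  s <- to_cylindrical(sq, center = c(2, -1))
  expect_equal(unname(s[1, ]), c(1, 0), tolerance = 1e-12)
  expect_equal(unname(s[4, ]), c(2, -pi / 2), tolerance = 1e-12)

  # ellipse about its center: r(phi) = a b / sqrt(b^2 cos^2 + a^2 sin^2)
  a <- 2; b <- 1
  ell <- ellipse_contour(a = a, b = b, n = 5000L)
  se <- to_cylindrical(ell, center = c(0, 0))
  i45 <- which.min(abs(se[, 2] - pi / 4))
  r_form <- a * b / sqrt(b^2 * cos(se[i45, 2])^2 + a^2 * sin(se[i45, 2])^2)
  expect_equal(unname(se[i45, 1]), unname(r_form), tolerance = 1e-4)

  expect_error(to_cylindrical(ell, center = c(5, 0)),
               class = "aaafc_parameterization_error")
})

test_that("lattice interpolation is periodic, seam-free and matches the oracle", {
  N <- 64L
  th_grid <- theta_axis(N)
  const <- cbind(r = rep(1.5, 10), theta = seq(-3, 3, length.out = 10))
  expect_equal(grid_row_interpolate(const, th_grid), rep(1.5, N))

  th <- -pi + 2 * pi * (0:199) / 200
  smooth <- cbind(2 + cos(th), th)
  got <- grid_row_interpolate(smooth, th_grid)
  expect_lt(max(abs(got - (2 + cos(th_grid)))), 1e-3)
  expect_lt(abs(got[1] - (2 + cos(-pi))), 1e-3)   # seam node

  sparse <- cbind(c(1, 2, 3), c(-3, 0, 3))
  expect_equal(grid_row_interpolate(sparse, th_grid),
               periodic_interp_oracle(c(1, 2, 3), c(-3, 0, 3), th_grid),
               tolerance = 1e-12)

  expect_error(grid_row_interpolate(cbind(1:4, rep(0.3, 4)), th_grid),
               class = "aaafc_degenerate_error")
})

test_that("forward parameterization reproduces analytic surfaces on the lattice", {
  K <- 20L; N <- 24L
  z_axis <- seq(0.2, 3.8, length.out = K)
  cl <- aaa_centerline(cbind(0 * z_axis, 0 * z_axis, z_axis))
  cyl <- tube_mesh(r = 2, z0 = 0, z1 = 4, n_theta = 720L, n_z = 9L)
  pr <- parameterize_surface(cyl, cl, N = N)
  expect_equal(dim(pr$grid$radii), c(K, N))
  expect_lt(max(abs(pr$grid$radii - 2)), 1e-3)
  expect_length(pr$slices, K)

  cone <- tube_mesh(r = function(z) 1 + z, z0 = 0, z1 = 3, n_theta = 720L, n_z = 61L)
  zc <- seq(0.2, 2.8, length.out = K)
  clc <- aaa_centerline(cbind(0 * zc, 0 * zc, zc))
  prc <- parameterize_surface(cone, clc, N = N)
  expect_equal(rowMeans(prc$grid$radii), 1 + zc, tolerance = 1e-3)
})

test_that("the default lattice is 100 x 100 (10,000 nodes)", {
  z_axis <- seq(0.3, 1.7, length.out = 100L)
  cl <- aaa_centerline(cbind(0 * z_axis, 0 * z_axis, z_axis))
  cyl <- tube_mesh(r = 1, z0 = 0, z1 = 2, n_theta = 128L, n_z = 7L)
  pr <- parameterize_surface(cyl, cl)       # default N
  expect_equal(dim(pr$grid$radii), c(100L, 100L))
  expect_equal(length(pr$grid$radii), 10000L)
  expect_equal(pr$grid$theta, -pi + 2 * pi * (0:99) / 100)
})

test_that("back-projection inverts the parameterization", {
  K <- 16L; N <- 32L
  z_axis <- seq(0, 5, length.out = K)
  cl <- aaa_centerline(cbind(0.3 * sin(z_axis), 0.1 * z_axis, z_axis))
  radii <- matrix(2, K, N)
  grid <- aaa_grid(radii, z_axis, layer = "outer_wall")
  pts <- inverse_map(grid, cl)
  expect_equal(nrow(pts), K * N)
  # constant radii about the axis: exact closed form
  th <- theta_axis(N)
  want <- do.call(rbind, lapply(seq_len(K), function(k)
    cbind(0.3 * sin(z_axis[k]) + 2 * cos(th), 0.1 * z_axis[k] + 2 * sin(th), z_axis[k])))
  expect_equal(pts, unname(want), tolerance = 1e-12)

  cl_bad <- aaa_centerline(cbind(0 * z_axis, 0 * z_axis, z_axis + 1)[1:8, ])
  expect_error(inverse_map(grid, cl_bad), class = "aaafc_lattice_error")
})

test_that("double round trip recovers a smooth radius field within tolerance", {
  K <- 24L; N <- 48L
  z_axis <- seq(0, 8, length.out = K)
  th <- theta_axis(N)
  field <- 1.5 + 0.6 * outer(exp(-(z_axis - 4)^2 / 3), rep(1, N)) *
    outer(rep(1, K), 1 + 0.12 * cos(th - 0.8))
  mesh <- aaafc:::sweep_mesh(field, z_axis, th)
  cl <- aaa_centerline(cbind(0 * z_axis, 0 * z_axis, z_axis))
  pr <- parameterize_surface(mesh, cl, N = N)
  expect_lt(max(abs(pr$grid$radii - field)), 2e-3)
  # seam continuity for the C^1 field: first and last angular columns agree
  # with the field's own periodic continuation
  expect_lt(max(abs(pr$grid$radii[, 1] - field[, 1])), 2e-3)
})
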