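# Synthetic longitudinal aneurysm generator.
#
# Emulates co-registered fusiform tubular surfaces with node-wise linear
# radial growth, a slowly drifting centerline and Gaussian observation
# noise, so every pipeline stage can be validated against known ground
# truth. The wall radius field is
#
#   r(z, theta, t) = r0 + (A0 + g t) * exp(-(z - z0)^2 / (2 w^2))
#                       * (1 + e cos(theta - theta0))
#                  + eta_n + b_n t + eps_{n t}
#
# a Gaussian axial bulge with a cosine azimuthal asymmetry: node random
# intercepts eta_n ~ N(0, sigma_node^2), node random slopes
# b_n ~ N(0, sigma_slope^2), per-observation noise eps ~ N(0, sigma_obs^2).
# Growth is concentrated near the maximum diameter and fades toward the
# proximal and distal ends, matching the observed phenomenology. The
# lumen is the wall field minus a constant offset, floored at 0.3 r0.

#' Configuration of the synthetic aneurysm generator
#'
#' Defaults emulate a surveillance-scale fusiform AAA: baseline trunk
#' radius 1.5 cm with a 0.8 cm bulge (hydraulic Dmax around 4.5 cm),
#' growth 5.5e-4 cm/day (about 2 mm/year at the bulge apex), four scans
#' over 1540 days (mean interval about 1 year), modest azimuthal asymmetry
#' and centerline drift, and observation noise of 0.02 cm.
#'
#' @param K,N Lattice sizes (stations x angles).
#' @param times Acquisition days, first must be 0.
#' @param length_cm Axial extent of the lattice (cm).
#' @param r0 Base (trunk) radius (cm).
#' @param A0 Baseline bulge amplitude (cm).
#' @param g Bulge growth rate (cm/day).
#' @param z0,w Bulge center and Gaussian width (cm); `z0 = length_cm / 2`
#'   by default.
#' @param e,theta0 Azimuthal asymmetry amplitude (relative) and phase.
#' @param delta Centerline drift amplitude (cm) reached at the last scan.
#' @param sigma_node Node random-intercept SD (cm).
#' @param sigma_slope Node random-slope SD (cm/day).
#' @param sigma_obs Per-observation noise SD (cm).
#' @param lumen_offset Wall-to-lumen radial offset (cm), floored at
#'   `0.3 * r0`.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Validated list of class `synth_config`.
#' @export
synth_config <- function(K = 40L, N = 40L,
                         times = c(0, 513, 1027, 1540),
                         length_cm = 10, r0 = 1.5, A0 = 0.8,
                         g = 5.5e-4, z0 = NULL, w = 2.0,
                         e = 0.15, theta0 = pi / 4,
                         delta = 0.1,
                         sigma_node = 0.05, sigma_slope = 5e-5,
                         sigma_obs = 0.02,
                         lumen_offset = 0.4, seed = 1L) {
  z0 <- z0 %||% (length_cm / 2)
  cfg <- list(K = as.integer(K), N = as.integer(N), times = as.numeric(times),
              length_cm = length_cm, r0 = r0, A0 = A0, g = g, z0 = z0, w = w,
              e = e, theta0 = theta0, delta = delta,
              sigma_node = sigma_node, sigma_slope = sigma_slope,
              sigma_obs = sigma_obs, lumen_offset = lumen_offset,
              seed = as.integer(seed))
  if (cfg$times[1] != 0 || any(diff(cfg$times) <= 0))
    stop_validation("times must start at 0 and increase strictly")
  if (length(cfg$times) < 2L) stop_validation("need at least 2 scan times")
  if (!(cfg$r0 > cfg$A0 * cfg$e) || cfg$A0 * cfg$e < 0)
    stop_validation("require r0 > A0*e >= 0 (star-shaped sections)")
  if (any(c(cfg$sigma_node, cfg$sigma_slope, cfg$sigma_obs) < 0))
    stop_validation("noise SDs must be >= 0")
  if (cfg$K < 4L || cfg$N < 4L) stop_validation("lattice sizes must be >= 4")
  class(cfg) <- "synth_config"
  cfg
}

#' @noRd
bulge_profile <- function(z, cfg) exp(-(z - cfg$z0)^2 / (2 * cfg$w^2))

#' @noRd
asym_profile <- function(theta, cfg) 1 + cfg$e * cos(theta - cfg$theta0)

#' Generate one synthetic longitudinal patient
#'
#' Draws node effects and observation noise, sweeps each scan's wall and
#' lumen radius fields into watertight triangulated meshes (vertex rings
#' offset from the analysis lattice so slicing planes never pass through
#' vertices; node-effect fields are interpolated bilinearly to ring
#' positions), and returns both the in-memory scan series and the exact
#' ground truth.
#'
#' @param cfg A [synth_config()].
#' @param patient_id Identifier stored on the series.
#' @return List with `series` (an `aaa_series`) and `truth` (class
#'   `synth_truth`: lattice axes, per-layer node intercept/slope fields,
#'   noise draws and the config).
#' @export
generate_patient <- function(cfg = synth_config(), patient_id = "SYN001") {
  stopifnot(inherits(cfg, "synth_config"))
  K <- cfg$K; N <- cfg$N; tms <- cfg$times; T_ <- length(tms)
  z_axis <- seq(0, cfg$length_cm, length.out = K)
  th <- theta_axis(N)
  with_seed(cfg$seed, {
    eta <- matrix(stats::rnorm(K * N, 0, cfg$sigma_node), K, N)
    bnode <- matrix(stats::rnorm(K * N, 0, cfg$sigma_slope), K, N)
    eps <- array(stats::rnorm(K * N * T_, 0, cfg$sigma_obs), dim = c(K, N, T_))
  })
  bulge <- bulge_profile(z_axis, cfg)
  asym <- asym_profile(th, cfg)
  shape <- outer(bulge, asym)                        # K x N
  wall_int <- cfg$r0 + cfg$A0 * shape + eta          # true node intercepts
  wall_slp <- cfg$g * shape + bnode                  # true node slopes (cm/day)
  lumen_floor <- 0.3 * cfg$r0
  drift_slope <- if (max(tms) > 0) cfg$delta * sin(pi * z_axis / cfg$length_cm) / max(tms)
                 else rep(0, K)
  scans <- vector("list", T_)
  for (j in seq_len(T_)) {
    t <- tms[j]
    wall_r <- wall_int + wall_slp * t + eps[, , j]
    lumen_r <- pmax(wall_r - cfg$lumen_offset, lumen_floor)
    cx <- drift_slope * t
    scans[[j]] <- list(
      time = t,
      wall = sweep_mesh(wall_r, z_axis, th, cx, layer = "outer_wall"),
      lumen = sweep_mesh(lumen_r, z_axis, th, cx, layer = "lumen"))
  }
  series <- structure(list(patient_id = patient_id, times = tms, scans = scans),
                      class = "aaa_series")
  truth <- structure(list(
    cfg = cfg, z_axis = z_axis, theta = th,
    wall_intercept = wall_int, wall_slope = wall_slp,
    lumen_offset = cfg$lumen_offset, lumen_floor = lumen_floor,
    drift_slope = drift_slope, eta = eta, bnode = bnode, eps = eps),
    class = "synth_truth")
  list(series = series, truth = truth)
}

# Sweep a K x N radius field (defined on lattice nodes) into a watertight
# triangulated tube with capped ends. Rings are placed on a finer axial
# grid offset from the lattice stations; the field is interpolated
# linearly in z (constant extension beyond the lattice) at the lattice
# angles, so cross-sections at lattice stations reproduce the field up to
# the axial chord error.
#' @noRd
sweep_mesh <- function(radii, z_axis, th, cx = NULL, layer = "outer_wall",
                       refine = 4L, az_refine = 3L) {
  K <- nrow(radii); N <- ncol(radii)
  cx <- cx %||% rep(0, K)
  # azimuthal refinement (midpoint insertion, periodic linear in theta)
  # keeps the facet chord sagitta below the lattice-recovery tolerance
  # while leaving the field values at the lattice angles untouched
  if (az_refine > 1L) {
    dth <- 2 * pi / N
    th_f <- as.vector(vapply(seq_len(az_refine) - 1L,
                             function(s) th + s * dth / az_refine,
                             numeric(N)))
    ord <- order(th_f)
    rad_f <- matrix(NA_real_, K, N * az_refine)
    for (s in seq_len(az_refine) - 1L) {
      w <- s / az_refine
      nxt <- c(seq_len(N)[-1], 1L)
      rad_f[, s * N + seq_len(N)] <- (1 - w) * radii + w * radii[, nxt, drop = FALSE]
    }
    th <- th_f[ord]
    radii <- rad_f[, ord, drop = FALSE]
    N <- N * az_refine
  }
  dz <- diff(range(z_axis)) / (K - 1)
  pad <- dz
  zr <- seq(min(z_axis) - pad, max(z_axis) + pad,
            by = dz / refine)
  zr <- zr + dz / (2 * refine * 7)           # offset off every lattice station
  interp_field <- function(zq) {
    zq <- pmin(pmax(zq, min(z_axis)), max(z_axis))
    t(vapply(zq, function(z) {
      k <- findInterval(z, z_axis, all.inside = TRUE)
      a <- (z - z_axis[k]) / (z_axis[k + 1] - z_axis[k])
      (1 - a) * radii[k, ] + a * radii[k + 1, ]
    }, numeric(N)))
  }
  interp_cx <- function(zq) {
    zq <- pmin(pmax(zq, min(z_axis)), max(z_axis))
    stats::approx(z_axis, cx, xout = zq, rule = 2)$y
  }
  R <- interp_field(zr)                       # n_ring x N
  cxs <- interp_cx(zr)
  n_ring <- length(zr)
  verts <- matrix(NA_real_, n_ring * N + 2L, 3L)
  for (j in seq_len(n_ring)) {
    idx <- (j - 1L) * N + seq_len(N)
    verts[idx, ] <- cbind(cxs[j] + R[j, ] * cos(th), R[j, ] * sin(th), zr[j])
  }
  bottom <- n_ring * N + 1L; top <- n_ring * N + 2L
  verts[bottom, ] <- c(cxs[1], 0, zr[1])
  verts[top, ] <- c(cxs[n_ring], 0, zr[n_ring])
  faces <- vector("list", n_ring + 1L)
  for (j in seq_len(n_ring - 1L)) {
    a <- (j - 1L) * N + seq_len(N)
    b <- (j - 1L) * N + c(seq_len(N)[-1], 1L)
    c_ <- j * N + seq_len(N)
    d <- j * N + c(seq_len(N)[-1], 1L)
    faces[[j]] <- rbind(cbind(a, b, c_), cbind(b, d, c_))
  }
  i1 <- seq_len(N); i2 <- c(seq_len(N)[-1], 1L)
  faces[[n_ring]] <- cbind(i2, i1, bottom)                       # bottom cap, outward -z
  faces[[n_ring + 1L]] <- cbind((n_ring - 1L) * N + i1, (n_ring - 1L) * N + i2, top)
  aaa_mesh(verts, do.call(rbind, faces), layer = layer, validate = TRUE)
}

#' Exact noiseless node trajectories of a synthetic patient
#'
#' Returns the generating intercept + slope * t field as a balanced
#' response matrix, for parameter-recovery assertions against fitted
#' models.
#'
#' @param truth The `synth_truth` from [generate_patient()].
#' @param response `"radius"`, `"centerline_x"` or `"centerline_y"`.
#' @param layer `"lumen"` or `"outer_wall"`. Lumen radii apply the offset
#'   and floor to the noiseless wall field.
#' @return An [response_matrix()].
#' @export
ground_truth_response <- function(truth,
                                  response = c("radius", "centerline_x", "centerline_y"),
                                  layer = "outer_wall") {
  response <- match.arg(response)
  layer <- match.arg(layer, LAYERS)
  tms <- truth$cfg$times
  K <- truth$cfg$K; N <- truth$cfg$N
  if (response == "radius") {
    vals <- sapply(tms, function(t) {
      r <- truth$wall_intercept + truth$wall_slope * t
      if (layer == "lumen") r <- pmax(r - truth$lumen_offset, truth$lumen_floor)
      as.vector(t(r))
    })
  } else if (response == "centerline_x") {
    vals <- sapply(tms, function(t) truth$drift_slope * t)
  } else {
    vals <- matrix(0, K, length(tms))
  }
  response_matrix(vals, tms, response = response, layer = layer)
}

#' Write a synthetic patient to disk in the manifest layout
#'
#' Emits ASCII STL meshes plus the JSON manifest consumed by
#' [load_patient_series()], and the ground truth as JSON.
#'
#' @param patient Output of [generate_patient()].
#' @param dir Output directory (created).
#' @return The manifest path, invisibly.
#' @export
write_synth_patient <- function(patient, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series <- patient$series
  scans <- lapply(seq_along(series$scans), function(j) {
    s <- series$scans[[j]]
    wf <- sprintf("scan%02d_wall.stl", j)
    lf <- sprintf("scan%02d_lumen.stl", j)
    write_mesh(s$wall, file.path(dir, wf))
    write_mesh(s$lumen, file.path(dir, lf))
    list(day = s$time, wall_mesh = wf, lumen_mesh = lf)
  })
  man <- list(patient_id = series$patient_id, scans = scans)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, manifest, auto_unbox = TRUE, digits = NA)
  tr <- patient$truth
  jsonlite::write_json(
    list(cfg = unclass(tr$cfg), z_axis = tr$z_axis, theta = tr$theta,
         wall_intercept = tr$wall_intercept, wall_slope = tr$wall_slope,
         drift_slope = tr$drift_slope),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(manifest)
}
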