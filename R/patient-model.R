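# Per-patient pipeline: shared lattice construction, six-model fitting,
# and geometry forecasting.

#' Parameterize every scan of a patient onto one common lattice
#'
#' Builds the patient-common station lattice z_k from the z-range shared by
#' all scans (a small interior margin avoids tangential end slices), then,
#' per scan and layer: extracts the slice-centroid centerline, smooths it
#' with a truncated Fourier series, resamples it at the common z_k, and
#' unwraps the surface about it. All grids of a patient share the same
#' (z_k, theta_i) axes, giving one-to-one node correspondence over time.
#'
#' @param series An `aaa_series` from [load_patient_series()] or
#'   [generate_patient()].
#' @param K Stations (default 100). @param N Angular nodes (default 100).
#' @param n_harmonics Fourier harmonics for centerline smoothing
#'   (default 5).
#' @param margin Interior margin as a fraction of the common z-range kept
#'   away from the mesh ends (default 0.02).
#' @return Object of class `aaa_param`: per-layer lists of per-scan grids,
#'   centerlines and raw slices, plus `times`, `z_axis`, `theta`,
#'   `patient_id`.
#' @export
parameterize_series <- function(series, K = 100L, N = 100L, n_harmonics = 5L,
                                margin = 0.02) {
  if (!is_count(K, 4L) || !is_count(N, 4L))
    stop_config("lattice sizes K and N must be integers >= 4 (got K=%s, N=%s)", K, N)
  scans <- series$scans
  zlo <- max(vapply(scans, function(s) max(mesh_z_range(s$wall)[1], mesh_z_range(s$lumen)[1]), numeric(1)))
  zhi <- min(vapply(scans, function(s) min(mesh_z_range(s$wall)[2], mesh_z_range(s$lumen)[2]), numeric(1)))
  if (zhi <= zlo) stop_validation("scans share no overlapping z-range")
  pad <- margin * (zhi - zlo)
  z_axis <- seq(zlo + pad, zhi - pad, length.out = K)
  out <- list(times = series$times, z_axis = z_axis, theta = theta_axis(N),
              patient_id = series$patient_id, K = K, N = N)
  for (layer in LAYERS) {
    key <- if (layer == "lumen") "lumen" else "wall"
    grids <- vector("list", length(scans))
    cls <- vector("list", length(scans))
    slices <- vector("list", length(scans))
    for (j in seq_along(scans)) {
      mesh <- scans[[j]][[key]]
      raw <- extract_raw_centerline(mesh, z_axis[1], z_axis[K],
                                    n_levels = max(2L * K, 2L * n_harmonics + 8L))
      sm <- fourier_smooth(raw, n_harmonics = n_harmonics)
      cl <- resample_stations(sm, z_grid = z_axis)
      pr <- parameterize_surface(mesh, cl, N = N)
      grids[[j]] <- pr$grid; cls[[j]] <- cl; slices[[j]] <- pr$slices
    }
    out[[layer]] <- list(grids = grids, centerlines = cls, slices = slices)
  }
  structure(out, class = "aaa_param")
}

#' @export
print.aaa_param <- function(x, ...) {
  cat(sprintf("<aaa_param> patient %s: %d scans, K=%d x N=%d lattice, z in [%.2f, %.2f] cm\n",
              x$patient_id, length(x$times), x$K, x$N, x$z_axis[1], x$z_axis[x$K]))
  invisible(x)
}

#' @noRd
response_matrices_from_param <- function(param, layer, keep) {
  tms <- param$times[keep]
  tms <- tms - tms[1]
  lay <- param[[layer]]
  K <- param$K; N <- param$N
  r <- sapply(lay$grids[keep], function(g) as.vector(t(g$radii)))   # (K*N) x T, node-major
  x <- sapply(lay$centerlines[keep], function(cl) cl$stations[, 1])
  y <- sapply(lay$centerlines[keep], function(cl) cl$stations[, 2])
  list(radius = response_matrix(r, tms, response = "radius", layer = layer),
       centerline_x = response_matrix(x, tms, response = "centerline_x", layer = layer),
       centerline_y = response_matrix(y, tms, response = "centerline_y", layer = layer))
}

#' Fit the six per-patient growth models
#'
#' Fits, per layer (lumen, outer wall), node-wise LME models for
#' centerline x, centerline y (G = K nodes) and the unwrapped radii
#' (G = K*N nodes). Under `regime = "exclude_last"` the final scan is held
#' out of the fit (requires at least 3 imaging sessions) and its time is
#' recorded for honest forecast evaluation.
#'
#' @param param An `aaa_param` from [parameterize_series()].
#' @param regime `"all_fu"` or `"exclude_last"`.
#' @param ... Passed to [fit_growth_lme()].
#' @return Object of class `aaa_patient_model`.
#' @export
fit_aaa_patient <- function(param, regime = c("all_fu", "exclude_last"), ...) {
  regime <- match.arg(regime)
  T_all <- length(param$times)
  if (regime == "exclude_last" && T_all < 3L)
    stop_regime("exclude_last requires at least 3 imaging sessions, patient has %d", T_all)
  keep <- if (regime == "exclude_last") seq_len(T_all - 1L) else seq_len(T_all)
  fits <- list()
  t0 <- proc.time()[["elapsed"]]
  for (layer in LAYERS) {
    rm_ <- response_matrices_from_param(param, layer, keep)
    fits[[layer]] <- lapply(rm_, fit_growth_lme, ...)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!all(vapply(fits, function(l) all(vapply(l, `[[`, logical(1), "converged")), logical(1))))
    warning("not all six growth fits reported convergence", call. = FALSE)
  structure(list(fits = fits, regime = regime,
                 train_times = param$times[keep],
                 held_out_times = setdiff(param$times, param$times[keep]),
                 z_axis = param$z_axis, theta = param$theta,
                 K = param$K, N = param$N,
                 patient_id = param$patient_id,
                 fit_seconds = elapsed),
            class = "aaa_patient_model")
}

#' @export
print.aaa_patient_model <- function(x, ...) {
  cat(sprintf("<aaa_patient_model> patient %s (%s): K=%d x N=%d, trained on days {%s}\n",
              x$patient_id, x$regime, x$K, x$N, paste(x$train_times, collapse = ", ")))
  if (length(x$held_out_times))
    cat(sprintf("  held-out follow-up(s): day %s\n", paste(x$held_out_times, collapse = ", ")))
  for (layer in LAYERS) {
    f <- x$fits[[layer]]
    cat(sprintf("  %s: radius beta = %.4g cm/year; centerline drift (%.3g, %.3g) cm/year\n",
                layer, f$radius$beta * 365.25,
                f$centerline_x$beta * 365.25, f$centerline_y$beta * 365.25))
  }
  cat(sprintf("  six-model fit time: %.2f s\n", x$fit_seconds))
  invisible(x)
}

#' Forecast the 3D geometry at an arbitrary target time
#'
#' Predicts the centerline (x_hat, y_hat at each station; z fixed at the
#' lattice levels), reshapes the predicted radii to the K x N lattice and
#' back-projects them about the predicted centerline, yielding a Cartesian
#' forecast surface directly comparable with an observed scan.
#'
#' @param object An `aaa_patient_model`.
#' @param t_star Target time in days since baseline (forward or backward
#'   extrapolation allowed).
#' @param ... Unused.
#' @return List per layer with `centerline` ([aaa_centerline()]), `grid`
#'   ([aaa_grid()]) and `cloud` ((K*N) x 3 Cartesian matrix); class
#'   `aaa_forecast`, with attributes `t_star` and `patient_id`.
#' @export
predict.aaa_patient_model <- function(object, t_star, ...) {
  out <- list()
  for (layer in LAYERS) {
    f <- object$fits[[layer]]
    x <- predict(f$centerline_x, t_star)
    y <- predict(f$centerline_y, t_star)
    cl <- aaa_centerline(cbind(x, y, object$z_axis), layer = layer)
    r <- predict(f$radius, t_star)
    radii <- matrix(r, nrow = object$K, ncol = object$N, byrow = TRUE)
    grid <- aaa_grid(radii, z_axis = object$z_axis, theta_grid = object$theta, layer = layer)
    out[[layer]] <- list(centerline = cl, grid = grid, cloud = inverse_map(grid, cl))
  }
  structure(out, class = "aaa_forecast", t_star = t_star,
            patient_id = object$patient_id)
}

#' @rdname predict.aaa_patient_model
#' @param model An `aaa_patient_model`.
#' @export
forecast_geometry <- function(model, t_star) predict(model, t_star)

#' @export
print.aaa_forecast <- function(x, ...) {
  cat(sprintf("<aaa_forecast> patient %s at t* = %g days (%.2f years)\n",
              attr(x, "patient_id"), attr(x, "t_star"), days_to_years(attr(x, "t_star"))))
  for (layer in LAYERS)
    cat(sprintf("  %s: max radius %.3f cm\n", layer, max(x[[layer]]$grid$radii)))
  invisible(x)
}

#' Save / load a fitted patient model
#'
#' JSON carries the fixed effects, variance components, regime and lattice
#' axes; a CSV sidecar holds the per-node BLUP vectors.
#'
#' @param model An `aaa_patient_model`.
#' @param path JSON path; the sidecar is written next to it with suffix
#'   `_blups.csv`.
#' @return `path` (write) or an `aaa_patient_model` (read).
#' @export
write_patient_model <- function(model, path) {
  meta <- list(patient_id = model$patient_id, regime = model$regime,
               train_times = model$train_times, held_out_times = model$held_out_times,
               K = model$K, N = model$N, z_axis = model$z_axis, theta = model$theta,
               fit_seconds = model$fit_seconds, fits = list())
  blups <- list()
  for (layer in LAYERS) for (resp in names(model$fits[[layer]])) {
    f <- model$fits[[layer]][[resp]]
    key <- paste(layer, resp, sep = ".")
    meta$fits[[key]] <- list(alpha = f$alpha, beta = f$beta,
                             sigma0_sq = f$sigma0_sq, sigma1_sq = f$sigma1_sq,
                             sigma_eps_sq = f$sigma_eps_sq, loglik = f$loglik,
                             converged = f$converged, G = f$G, times = f$times)
    blups[[key]] <- data.frame(series = key, node = seq_len(f$G), b0 = f$b0, b1 = f$b1)
  }
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(do.call(rbind, blups), sidecar_path(path), row.names = FALSE)
  invisible(path)
}

#' @noRd
sidecar_path <- function(path) sub("\\.json$", "_blups.csv", path)

#' @rdname write_patient_model
#' @export
read_patient_model <- function(path) {
  if (!file.exists(path)) stop_upstream("model file not found: %s", path)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  bl <- utils::read.csv(sidecar_path(path))
  fits <- list()
  for (key in names(meta$fits)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    fm <- meta$fits[[key]]
    sub <- bl[bl$series == key, ]
    fit <- structure(list(alpha = fm$alpha, beta = fm$beta,
                          sigma0_sq = fm$sigma0_sq, sigma1_sq = fm$sigma1_sq,
                          sigma_eps_sq = fm$sigma_eps_sq,
                          b0 = sub$b0, b1 = sub$b1,
                          loglik = fm$loglik, converged = fm$converged,
                          times = fm$times, G = fm$G,
                          response = parts[2], layer = parts[1]),
                     class = "growth_lme")
    fits[[parts[1]]][[parts[2]]] <- fit
  }
  structure(list(fits = fits, regime = meta$regime,
                 train_times = meta$train_times,
                 held_out_times = as.numeric(meta$held_out_times),
                 z_axis = meta$z_axis, theta = meta$theta,
                 K = meta$K, N = meta$N, patient_id = meta$patient_id,
                 fit_seconds = meta$fit_seconds),
            class = "aaa_patient_model")
}
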