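# Forecast evaluation: HD95 spatial similarity in three spaces, hydraulic
# maximum diameter and slice-integrated volume, per-patient and
# macro-averaged cohort summaries.

#' 95th-percentile Hausdorff distance between two point sets
#'
#' For every point of A the nearest distance to B is computed and vice
#' versa; the two lists are concatenated and the 95th percentile of the
#' combined distribution (linear interpolation between order statistics)
#' is returned. A robust near-worst-case bound on spatial disagreement.
#'
#' @param A,B Numeric matrices with matching column count (any
#'   dimensionality).
#' @param probs Percentile level (default 0.95).
#' @return Non-negative scalar distance in the units of the inputs.
#' @export
hd95 <- function(A, B, probs = 0.95) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0L || nrow(B) == 0L) stop_validation("hd95: empty point set")
  if (ncol(A) != ncol(B)) stop_validation("hd95: dimensionality mismatch (%d vs %d)", ncol(A), ncol(B))
  d <- c(nn_dist(A, B), nn_dist(B, A))
  as.numeric(stats::quantile(d, probs = probs, type = 7, names = FALSE))
}

# Nearest-neighbour distances from each row of A to B. The candidate set
# is pruned by a window on the last coordinate (for slice-structured
# clouds this is the axial direction): any point whose last-coordinate
# offset exceeds the current upper bound cannot be the nearest neighbour,
# so the minimum — and hence the returned distance — is exactly the
# brute-force double-loop value (identical per-pair arithmetic:
# coordinate-wise squared differences summed in column order).
#' @noRd
nn_dist <- function(A, B) {
  n <- nrow(A); d <- ncol(A)
  ord <- order(B[, d])
  Bs <- B[ord, , drop = FALSE]
  bz <- Bs[, d]
  nb <- nrow(Bs)
  # seed candidate: the B point nearest in the last coordinate
  pos <- pmin(pmax(findInterval(A[, d], bz), 1L), nb)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- A[i, ]
    j0 <- pos[i]
    j1 <- min(j0 + 1L, nb)
    # plain double adds in column order, matching the brute-force loop
    s0 <- (Bs[j0, 1] - a[1])^2; s1 <- (Bs[j1, 1] - a[1])^2
    for (k in seq_len(d)[-1]) {
      s0 <- s0 + (Bs[j0, k] - a[k])^2
      s1 <- s1 + (Bs[j1, k] - a[k])^2
    }
    seed <- min(s0, s1)
    ub <- sqrt(seed)
    lo <- findInterval(a[d] - ub, bz) + 1L
    hi <- findInterval(a[d] + ub, bz)
    if (hi < lo) { out[i] <- ub; next }
    w <- lo:hi
    acc <- (Bs[w, 1] - a[1])^2
    for (k in seq_len(d)[-1]) acc <- acc + (Bs[w, k] - a[k])^2
    out[i] <- sqrt(min(acc, seed))
  }
  out
}

#' Hydraulic maximum diameter over a stack of cross-sections
#'
#' Per slice the hydraulic diameter `D_h = 4 A / P` (shoelace polygon area
#' A, perimeter P) is computed; the maximum over slices is returned. The
#' hydraulic form quantifies asymmetric sections consistently, unlike a
#' single caliper distance.
#'
#' @param slices List of [aaa_contour()] objects.
#' @return Maximum hydraulic diameter (cm).
#' @export
hydraulic_dmax <- function(slices) {
  max(vapply(slices, hydraulic_diameter, numeric(1)))
}

#' @rdname hydraulic_dmax
#' @param contour A single [aaa_contour()].
#' @export
hydraulic_diameter <- function(contour) {
  P <- contour_perimeter(contour)
  A <- abs(contour_area(contour))
  if (P <= 0 || A <= 0) stop_geometry("degenerate contour at z = %g", contour$z)
  4 * A / P
}

#' Volume enclosed by a stack of cross-sections
#'
#' Trapezoidal integration of the per-slice polygon area over z.
#'
#' @param slices List of [aaa_contour()] objects (>= 2).
#' @param z_axis Optional explicit slice levels; defaults to each
#'   contour's own z. Must be strictly monotone.
#' @return Volume in cm^3.
#' @export
volume_from_slices <- function(slices, z_axis = NULL) {
  if (length(slices) < 2L) stop_validation("volume needs >= 2 slices")
  z <- z_axis %||% vapply(slices, `[[`, numeric(1), "z")
  dz <- diff(z)
  if (!(all(dz > 0) || all(dz < 0)))
    stop_validation("slice levels must be strictly monotone")
  a <- vapply(slices, function(ct) abs(contour_area(ct)), numeric(1))
  abs(sum(dz * (a[-1] + a[-length(a)]) / 2))
}

#' Evaluate forecasts of a fitted patient model against observed geometry
#'
#' For each evaluated follow-up and layer the model is forecast at the
#' observed acquisition time and compared with the observed scan in three
#' spaces: (a) the 3D centerline stations, (b) the unwrapped (r, theta, z)
#' node cloud, and (c) the reconstructed Cartesian cloud — each via HD95.
#' The geometric scalars (hydraulic maximum diameter and slice-integrated
#' volume) are computed from constant-z grid contours on both sides, so
#' the comparison isolates the growth model rather than the
#' parameterization.
#'
#' @param model An `aaa_patient_model` (regimes `all_fu` or
#'   `exclude_last`).
#' @param param The `aaa_param` of the same patient (ground truth).
#' @param followups Which follow-up indices to evaluate; defaults to every
#'   scan after baseline.
#' @return Data frame of class `aaa_eval_report`: one row per follow-up x
#'   layer with hd95_centerline, hd95_unwrapped, hd95_reconstruction (cm;
#'   unwrapped mixes cm and radians as stored), dmax/volume predictions,
#'   truths and percentage errors, regime and `held_out` flag.
#' @export
evaluate_forecast <- function(model, param, followups = NULL) {
  if (model$K != param$K || model$N != param$N ||
      max(abs(model$z_axis - param$z_axis)) > 1e-9)
    stop_lattice("model and ground-truth lattices differ")
  followups <- followups %||% seq_along(param$times)[-1]
  rows <- list()
  for (j in followups) {
    t_eval <- param$times[j]
    fc <- predict(model, t_eval)
    for (layer in LAYERS) {
      truth_cl <- param[[layer]]$centerlines[[j]]
      truth_grid <- param[[layer]]$grids[[j]]
      pred <- fc[[layer]]
      truth_cloud <- inverse_map(truth_grid, truth_cl)
      dmax_p <- hydraulic_dmax(grid_contours(pred$grid, pred$centerline))
      dmax_t <- hydraulic_dmax(grid_contours(truth_grid, truth_cl))
      vol_p <- volume_from_slices(grid_contours(pred$grid, pred$centerline))
      vol_t <- volume_from_slices(grid_contours(truth_grid, truth_cl))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = model$patient_id, followup = j, time_days = t_eval,
        layer = layer, regime = model$regime,
        held_out = t_eval %in% model$held_out_times,
        hd95_centerline = hd95(pred$centerline$stations, truth_cl$stations),
        hd95_unwrapped = hd95(unwrapped_cloud(pred$grid), unwrapped_cloud(truth_grid)),
        hd95_reconstruction = hd95(pred$cloud, truth_cloud),
        dmax_pred = dmax_p, dmax_true = dmax_t,
        volume_pred = vol_p, volume_true = vol_t,
        dmax_err_pct = 100 * abs(dmax_p - dmax_t) / dmax_t,
        volume_err_pct = 100 * abs(vol_p - vol_t) / vol_t)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("aaa_eval_report", class(out))
  out
}

#' Macro-averaged cohort summary of evaluation reports
#'
#' Per-patient means over follow-ups are taken first, then averaged across
#' patients (macro-averaging), per layer, so patients with many follow-ups
#' do not dominate. R-squared (1 - SS_res/SS_tot about the ground-truth
#' mean) and MAE for the geometric scalars are computed across all
#' patient-follow-up pairs.
#'
#' @param reports An `aaa_eval_report` (rows from one or more patients),
#'   or a list of them.
#' @return Object of class `aaa_cohort_summary` with `macro` (per layer x
#'   regime macro-means of each metric) and `scalars` (R2 and MAE per
#'   layer for dmax and volume).
#' @export
summarize_cohort <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) reports <- do.call(rbind, reports)
  if (nrow(reports) < 1L) stop_validation("no evaluation rows to summarize")
  metrics <- c("hd95_centerline", "hd95_unwrapped", "hd95_reconstruction",
               "dmax_err_pct", "volume_err_pct", "dmax_pred", "volume_pred")
  grp <- interaction(reports$layer, reports$regime, drop = TRUE)
  macro <- do.call(rbind, lapply(split(reports, grp), function(d) {
    per_pat <- stats::aggregate(d[metrics], by = list(patient_id = d$patient_id), FUN = mean)
    cbind(data.frame(layer = d$layer[1], regime = d$regime[1],
                     n_patients = nrow(per_pat)),
          as.data.frame(t(colMeans(per_pat[metrics]))))
  }))
  rownames(macro) <- NULL
  r2 <- function(pred, truth) 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
  scalars <- do.call(rbind, lapply(split(reports, grp), function(d) {
    data.frame(layer = d$layer[1], regime = d$regime[1],
               r2_dmax = r2(d$dmax_pred, d$dmax_true),
               mae_dmax = mean(abs(d$dmax_pred - d$dmax_true)),
               r2_volume = r2(d$volume_pred, d$volume_true),
               mae_volume = mean(abs(d$volume_pred - d$volume_true)))
  }))
  rownames(scalars) <- NULL
  structure(list(macro = macro, scalars = scalars), class = "aaa_cohort_summary")
}

#' @export
print.aaa_cohort_summary <- function(x, ...) {
  cat("Cohort macro-averages (per-patient means first):\n")
  print(x$macro, digits = 4)
  cat("\nGeometric scalar agreement (per follow-up):\n")
  print(x$scalars, digits = 4)
  invisible(x)
}
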