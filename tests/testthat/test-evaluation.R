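# HD95, geometric scalars, forecast evaluation, cohort summaries.

test_that("hd95 handles identity, two-point, and matches the brute-force oracle", {
  set.seed(5)
  A <- matrix(rnorm(300), ncol = 3)
  expect_equal(hd95(A, A), 0)
  expect_equal(hd95(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 1), 1)), 1.0)
  for (i in 1:3) {
    P <- matrix(rnorm(300 * 3), ncol = 3)
    Q <- matrix(rnorm(280 * 3, mean = 0.3), ncol = 3)
    expect_identical(hd95(P, Q), hd95_oracle(P, Q))
    expect_identical(hd95(P, Q), hd95(Q, P))                  # symmetry
  }
  expect_error(hd95(A[0, ], A), class = "aaafc_validation_error")
  expect_error(hd95(A, A[, 1:2]), class = "aaafc_validation_error")
})

test_that("hd95 is rigid-motion invariant and bounded by the exact Hausdorff distance", {
  set.seed(8)
  A <- matrix(rnorm(240), ncol = 3)
  B <- matrix(rnorm(300), ncol = 3)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(1, -2, 3)
  At <- sweep(A %*% t(Rz), 2, shift, "+")
  Bt <- sweep(B %*% t(Rz), 2, shift, "+")
  expect_equal(hd95(At, Bt), hd95(A, B), tolerance = 1e-12)
  # exact Hausdorff = max of the combined nearest-neighbour distances
  d_all <- c(aaafc:::nn_dist(A, B), aaafc:::nn_dist(B, A))
  expect_lte(hd95(A, B), max(d_all))
})

test_that("hydraulic diameter matches closed forms and the elliptic-perimeter oracle", {
  circ <- ellipse_contour(a = 1.3, b = 1.3, n = 100L)
  expect_equal(hydraulic_diameter(circ), 2 * 1.3, tolerance = 1e-3)

  square <- aaa_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0))
  expect_equal(hydraulic_diameter(square), 1.0, tolerance = 1e-12)

  a <- 2; b <- 1
  ell <- ellipse_contour(a = a, b = b, n = 4000L)
  # perimeter by dense numeric integration of ds = sqrt(a^2 sin^2 + b^2 cos^2)
  tt <- seq(0, 2 * pi, length.out = 200001L)
  P_or <- sum(sqrt(a^2 * sin(tt)^2 + b^2 * cos(tt)^2)) * diff(tt[1:2]) -
    0.5 * diff(tt[1:2]) * (sqrt(b^2) + sqrt(b^2))
  expect_equal(hydraulic_diameter(ell), 4 * pi * a * b / P_or, tolerance = 1e-4)

  expect_equal(hydraulic_dmax(list(circ, square)), 2 * 1.3, tolerance = 1e-3)
})

test_that("slice-integrated volume matches cylinder, cone, and the mesh oracle", {
  K <- 100L
  zs <- seq(0, 2, length.out = K)
  cyl <- lapply(zs, function(z) ellipse_contour(a = 1, b = 1, z = z, n = 100L))
  expect_equal(volume_from_slices(cyl), 2 * pi, tolerance = 0.5 * pi * 2 / 100)

  zc <- seq(0, 1, length.out = K)
  cone <- lapply(zc[-K], function(z) ellipse_contour(a = 1 - z, b = 1 - z, z = z, n = 100L))
  expect_equal(volume_from_slices(cone), pi / 3, tolerance = 0.01 * pi / 3)

  # random star-shaped radii field vs the swept mesh divergence-theorem volume
  set.seed(12)
  Kf <- 30L; Nf <- 64L
  z_axis <- seq(0, 5, length.out = Kf)
  th <- theta_axis(Nf)
  field <- 1.2 + 0.3 * outer(sin(z_axis), cos(2 * th)) + 0.1 * outer(exp(-z_axis), rep(1, Nf))
  mesh <- aaafc:::sweep_mesh(field, z_axis, th, refine = 8L, az_refine = 4L)
  slices <- lapply(seq_len(Kf), function(k)
    aaa_contour(cbind(field[k, ] * cos(th), field[k, ] * sin(th), z_axis[k])))
  v_slices <- volume_from_slices(slices)
  v_mesh <- mesh_volume(mesh)                 # includes the end padding
  # subtract the two padded end slabs (estimated by their end-slice areas)
  dz <- diff(range(z_axis)) / (Kf - 1)
  pad_vol <- (abs(contour_area(slices[[1]])) + abs(contour_area(slices[[Kf]]))) * dz
  expect_equal(v_slices, v_mesh - pad_vol, tolerance = 0.01 * v_slices)

  expect_error(volume_from_slices(cyl[1]), class = "aaafc_validation_error")
  expect_error(volume_from_slices(cyl, z_axis = rep(1, K)),
               class = "aaafc_validation_error")
})

test_that("noise-free linear growth is forecast with vanishing error", {
  param <- make_linear_param()
  m <- fit_aaa_patient(param, regime = "all_fu")
  rep <- evaluate_forecast(m, param)
  expect_s3_class(rep, "aaa_eval_report")
  expect_equal(nrow(rep), 3L * 2L)            # 3 follow-ups x 2 layers
  expect_lt(max(rep$hd95_centerline), 1e-6)
  expect_lt(max(rep$hd95_unwrapped), 1e-6)
  expect_lt(max(rep$hd95_reconstruction), 1e-6)
  expect_lt(max(rep$dmax_err_pct), 1e-4)
  expect_lt(max(rep$volume_err_pct), 1e-4)
  expect_false(any(rep$held_out))
})

test_that("cohort summaries macro-average patient-first", {
  base <- data.frame(patient_id = "A", followup = 2, time_days = 300,
                     layer = "outer_wall", regime = "all_fu", held_out = FALSE,
                     hd95_centerline = 0.1, hd95_unwrapped = 0.1,
                     hd95_reconstruction = 0.1,
                     dmax_pred = 4.5, dmax_true = 4.5,
                     volume_pred = 120, volume_true = 120,
                     dmax_err_pct = 0, volume_err_pct = 0)
  one <- summarize_cohort(base)
  expect_equal(one$macro$hd95_centerline, 0.1)

  # patient A: one follow-up at 0.1; patient B: three follow-ups at 0.3
  rows <- rbind(base,
                transform(base[rep(1, 3), ], patient_id = "B",
                          hd95_centerline = 0.3, hd95_unwrapped = 0.3,
                          hd95_reconstruction = 0.3))
  two <- summarize_cohort(rows)
  expect_equal(two$macro$hd95_centerline, 0.2)   # not the pooled 0.25
  expect_equal(two$macro$n_patients, 2L)

  # duplicating one patient's follow-ups leaves the macro-mean unchanged
  dup <- rbind(rows, rows[rows$patient_id == "B", ])
  expect_equal(summarize_cohort(dup)$macro$hd95_centerline, 0.2)

  # perfect scalar predictions
  set.seed(3)
  rows2 <- base[rep(1, 6), ]
  rows2$patient_id <- rep(c("A", "B", "C"), each = 2)
  rows2$dmax_true <- rows2$dmax_pred <- runif(6, 4, 5)
  rows2$volume_true <- rows2$volume_pred <- runif(6, 100, 140)
  s <- summarize_cohort(rows2)
  expect_equal(s$scalars$r2_dmax, 1)
  expect_equal(s$scalars$mae_dmax, 0)
  expect_equal(s$scalars$r2_volume, 1)
})
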