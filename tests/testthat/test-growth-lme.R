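# Node-wise linear mixed-effects growth model: likelihood, fitting,
# BLUPs, prediction, and the per-patient six-model wrapper.

sim_balanced <- function(G, times, alpha = 2, beta = 5.5e-4,
                         s0 = 0.3, s1 = 1e-4, se = 0.02, seed = 1) {
  set.seed(seed)
  a <- alpha + rnorm(G, 0, s0)
  b <- beta + rnorm(G, 0, s1)
  outer(a, rep(1, length(times))) + outer(b, times) +
    matrix(rnorm(G * length(times), 0, se), G)
}

test_that("exact common-line data gives the line, floored variances, null BLUPs", {
  tms <- c(0, 200, 600, 1100)
  y <- matrix(rep(2 + 0.001 * tms, each = 50), 50)
  fit <- fit_growth_lme(y, tms)
  expect_equal(fit$alpha, 2, tolerance = 1e-8)
  expect_equal(fit$beta, 0.001, tolerance = 1e-8)
  expect_lt(fit$sigma0_sq, 1e-10)
  expect_lt(fit$sigma1_sq, 1e-10)
  expect_lt(fit$sigma_eps_sq, 1e-10)
  expect_lt(max(abs(fit$b0)), 1e-6)
  expect_lt(max(abs(fit$b1)), 1e-6)
  expect_true(fit$converged)
})

test_that("node-intercept-only data recovers alpha and the intercept variance", {
  tms <- c(0, 385, 770, 1540)
  G <- 1000L
  set.seed(11)
  delta <- rnorm(G, 0, 0.3)
  y <- outer(2 + delta, rep(1, 4)) + outer(rep(0.001, G), tms)
  fit <- fit_growth_lme(y, tms)
  se_alpha <- sd(delta) / sqrt(G)
  expect_lt(abs(fit$alpha - 2), 2 * se_alpha + 2 * abs(mean(delta)))
  expect_lt(abs(fit$sigma0_sq - var(delta)) / var(delta), 0.25)
  expect_lt(fit$sigma1_sq, 1e-10)
  expect_lt(fit$sigma_eps_sq, 1e-10)
})

test_that("profiled deviance equals the dense block-covariance Gaussian density", {
  for (case in list(list(G = 2L, times = c(0, 400)),
                    list(G = 3L, times = c(0, 300, 900)))) {
    y <- sim_balanced(case$G, case$times, seed = 5 + case$G)
    theta <- log(c(0.05, 2e-9, 4e-4))
    got <- profile_deviance(theta, y, case$times)
    # oracle: stacked (G*T)-vector, kronecker block covariance, GLS mean
    T_ <- length(case$times); G <- case$G
    X1 <- cbind(1, case$times)
    V <- exp(theta[1]) + exp(theta[2]) * tcrossprod(case$times) + diag(exp(theta[3]), T_)
    Sig <- kronecker(diag(G), V)
    Xs <- do.call(rbind, replicate(G, X1, simplify = FALSE))
    yv <- as.vector(t(y))
    gam <- solve(t(Xs) %*% solve(Sig, Xs), t(Xs) %*% solve(Sig, yv))
    r <- yv - Xs %*% gam
    dev <- G * T_ * log(2 * pi) + determinant(Sig)$modulus[1] +
      as.numeric(t(r) %*% solve(Sig, r))
    expect_equal(got, dev, tolerance = 1e-8)
  }
})

test_that("deviance respects location invariance and Gaussian scale equivariance", {
  tms <- c(0, 250, 800)
  y <- sim_balanced(30L, tms, seed = 3)
  theta <- log(c(0.09, 1e-8, 4e-4))
  base <- profile_deviance(theta, y, tms)
  expect_equal(profile_deviance(theta, y + 5, tms), base, tolerance = 1e-9)
  s <- 3
  scaled <- profile_deviance(theta + 2 * log(s), y * s, tms)
  expect_equal(scaled - base, 2 * length(y) * log(s), tolerance = 1e-8)
  expect_error(profile_deviance(c(NA, 0, 0), y, tms), class = "aaafc_validation_error")
})

test_that("two-scan fits near-interpolate the observations", {
  tms <- c(0, 365)
  y <- sim_balanced(200L, tms, seed = 9)
  fit <- fit_growth_lme(y, tms)
  rmse <- sqrt(mean(residuals(fit)^2))
  expect_lt(rmse, 1e-3 * mean(abs(y)))
})

test_that("ML estimates are invariant to node permutation", {
  tms <- c(0, 300, 700, 1200)
  y <- sim_balanced(120L, tms, seed = 21)
  f1 <- fit_growth_lme(y, tms)
  set.seed(1); perm <- sample(nrow(y))
  f2 <- fit_growth_lme(y[perm, ], tms)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$sigma0_sq, f2$sigma0_sq, tolerance = 1e-5)
  expect_equal(f1$b0[perm], f2$b0, tolerance = 1e-6)
})

test_that("with variances pinned at the floor the fixed effects are pooled OLS", {
  tms <- c(0, 300, 700, 1200)
  y <- sim_balanced(80L, tms, seed = 13)
  gl <- aaafc:::gls_fixed_effects(log(c(1e-12, 1e-12, var(as.vector(y)))), y, tms)
  dat <- data.frame(yy = as.vector(t(y)), tt = rep(tms, times = nrow(y)))
  ols <- coef(lm(yy ~ tt, dat))
  expect_equal(unname(gl$gamma), unname(ols), tolerance = 1e-8)
})

test_that("BLUPs shrink node intercepts toward the population line", {
  tms <- c(0, 300, 700, 1200)
  y <- sim_balanced(150L, tms, s0 = 0.2, s1 = 1e-12, se = 0.05, seed = 31)
  fit <- fit_growth_lme(y, tms)
  # unshrunk per-node intercept deviations about the fitted fixed line
  # (common slope); the BLUP must shrink each toward zero
  dev_raw <- rowMeans(y - outer(rep(1, nrow(y)), fit$alpha + fit$beta * tms))
  expect_true(all(abs(fit$b0) <= abs(dev_raw) + 1e-10))
  expect_true(all(sign(fit$b0) == sign(dev_raw)))
  expect_lt(abs(mean(fit$b0)), 1e-8)
  expect_lt(abs(mean(fit$b1)), 1e-12)
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  tms <- c(0, 385, 770, 1540)
  G <- 200L
  y <- sim_balanced(G, tms, seed = 77)
  fit <- fit_growth_lme(y, tms)
  dat <- data.frame(yy = as.vector(t(y)),
                    tt = rep(tms, times = G),
                    node = factor(rep(seq_len(G), each = length(tms))))
  # lme4 needs a well-scaled covariate: fit on years and convert back
  dat$ty <- dat$tt / 365.25
  lf <- lme4::lmer(yy ~ ty + ((1 | node) + (0 + ty | node)), data = dat, REML = FALSE)
  fe <- unname(lme4::fixef(lf))
  expect_equal(fe[1], fit$alpha, tolerance = 1e-5)
  expect_equal(fe[2] / 365.25, fit$beta, tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))
  s0_l <- vc$vcov[vc$var1 == "(Intercept)" & !is.na(vc$var1)]
  s1_l <- vc$vcov[vc$var1 == "ty" & !is.na(vc$var1)]
  se_l <- vc$vcov[vc$grp == "Residual"]
  expect_equal(s0_l, fit$sigma0_sq, tolerance = 1e-2)
  expect_equal(s1_l / 365.25^2, fit$sigma1_sq, tolerance = 5e-2)
  expect_equal(se_l, fit$sigma_eps_sq, tolerance = 1e-2)
  expect_equal(as.numeric(stats::logLik(lf)), fit$loglik, tolerance = 1e-6)
})

test_that("predictions are exactly affine in the target time", {
  tms <- c(0, 300, 700, 1200)
  y <- sim_balanced(60L, tms, seed = 41)
  fit <- fit_growth_lme(y, tms)
  expect_equal(predict(fit, 0), fit$alpha + fit$b0)
  expect_equal(predict(fit, 365) - predict(fit, 0), 365 * (fit$beta + fit$b1))
  mid <- (tms[2] + tms[3]) / 2
  expect_equal(predict(fit, mid),
               (predict(fit, tms[2]) + predict(fit, tms[3])) / 2, tolerance = 1e-12)
  # three-point colinearity per node
  p <- predict(fit, c(0, 1000, 2000))
  expect_lt(max(abs(p[, 2] - (p[, 1] + p[, 3]) / 2)), 1e-9)
  expect_warning(predict(fit, tms[4] + 6 * 365.25), "5 years")
})

test_that("simulate() reproduces the generating variance structure", {
  tms <- c(0, 385, 770, 1540)
  y <- sim_balanced(800L, tms, seed = 55)
  fit <- fit_growth_lme(y, tms)
  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), dim(y))
  refit <- fit_growth_lme(sims[[1]], tms)
  expect_equal(refit$sigma0_sq, fit$sigma0_sq, tolerance = 0.3)
})

test_that("the per-patient wrapper fits six models and honors regimes", {
  param <- make_linear_param()
  m <- fit_aaa_patient(param, regime = "all_fu")
  expect_s3_class(m, "aaa_patient_model")
  for (layer in c("lumen", "outer_wall")) {
    expect_named(m$fits[[layer]], c("radius", "centerline_x", "centerline_y"))
    expect_true(all(vapply(m$fits[[layer]], `[[`, logical(1), "converged")))
    expect_length(m$fits[[layer]]$radius$times, 4L)
  }
  mel <- fit_aaa_patient(param, regime = "exclude_last")
  expect_length(mel$fits$lumen$radius$times, 3L)
  expect_equal(mel$held_out_times, 1200)

  p2 <- make_linear_param(times = c(0, 500))
  expect_error(fit_aaa_patient(p2, regime = "exclude_last"),
               class = "aaafc_regime_error")
})

test_that("forecasts reproduce exact linear growth and its arithmetic", {
  slope <- matrix(0.001, 12L, 16L)
  param <- make_linear_param(r_slope = slope, cx_slope = 1e-5)
  m <- fit_aaa_patient(param, regime = "all_fu")
  # at a training time the forecast matches that scan's reconstruction
  for (j in c(1L, 3L)) {
    fc <- predict(m, param$times[j])
    for (layer in c("lumen", "outer_wall")) {
      truth <- inverse_map(param[[layer]]$grids[[j]], param[[layer]]$centerlines[[j]])
      expect_lt(max(abs(fc[[layer]]$cloud - truth)), 1e-6)
    }
  }
  # one year past the last scan the radii exceed the last scan by 365 * slope
  fc2 <- predict(m, 1200 + 365)
  expect_equal(fc2$outer_wall$grid$radii - param$outer_wall$grids[[4]]$radii,
               matrix(0.365, 12L, 16L), tolerance = 1e-6)
})

test_that("model serialization round-trips fits and forecasts", {
  param <- make_linear_param()
  m <- fit_aaa_patient(param, regime = "exclude_last")
  p <- withr::local_tempfile(fileext = ".json")
  write_patient_model(m, p)
  back <- read_patient_model(p)
  expect_equal(coef(back$fits$lumen$radius), coef(m$fits$lumen$radius))
  expect_equal(predict(back, 900)$outer_wall$cloud, predict(m, 900)$outer_wall$cloud)
  expect_equal(back$held_out_times, m$held_out_times)
})
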