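# Node-wise linear mixed-effects growth model.
#
# For one response (a centerline coordinate or the unwrapped radii) of one
# layer of one patient, observations on the lattice follow
#
#   y_{t n} = (alpha + b0_n) + (beta + b1_n) * t + eps_{t n},
#   b0_n ~ N(0, sigma0^2), b1_n ~ N(0, sigma1^2), eps ~ N(0, sigma_eps^2),
#
# with uncorrelated random effects (diagonal 2 x 2 covariance). alpha and
# beta are the patient-level fixed intercept and slope (cm, cm/day); the
# node-level random intercepts and slopes carry the regional heterogeneity.
#
# The design is balanced: every node is observed at the same T times, so
# the marginal covariance V = sigma0^2 J + sigma1^2 t t' + sigma_eps^2 I
# (T x T) is shared by all G nodes. Maximum likelihood profiles the fixed
# effects in closed form given V and searches only over the three
# log-variances; node effects are recovered as BLUPs.

#' Balanced response matrix for one geometric response
#'
#' @param values G x T numeric matrix: G lattice nodes observed at T times
#'   (cm). No missing cells.
#' @param times T acquisition times in days since baseline; strictly
#'   increasing with `times[1] == 0`.
#' @param response `"radius"`, `"centerline_x"` or `"centerline_y"`.
#' @param layer `"lumen"` or `"outer_wall"`.
#' @return Object of class `aaa_response`.
#' @export
response_matrix <- function(values, times,
                            response = c("radius", "centerline_x", "centerline_y"),
                            layer = "outer_wall") {
  response <- match.arg(response)
  layer <- match.arg(layer, LAYERS)
  values <- as.matrix(values)
  times <- as.numeric(times)
  if (ncol(values) != length(times))
    stop_validation("values has %d columns but %d times given", ncol(values), length(times))
  if (length(times) < 2L) stop_insufficient("need T >= 2 times, got %d", length(times))
  if (times[1] != 0) stop_validation("times must start at 0 (days since baseline)")
  if (any(diff(times) <= 0)) stop_validation("times must be strictly increasing")
  if (anyNA(values)) stop_validation("response matrix has missing cells; the design must be balanced")
  structure(list(values = values, times = times, response = response, layer = layer),
            class = "aaa_response")
}

# V(theta) for log-variances theta; t is the raw time vector in days
#' @noRd
marginal_cov <- function(theta, times) {
  s0 <- exp(theta[1]); s1 <- exp(theta[2]); se <- exp(theta[3])
  s0 + s1 * tcrossprod(times) + diag(se, length(times))
}

#' Profiled deviance of the growth model
#'
#' Minus twice the marginal log-likelihood at the generalized-least-squares
#' fixed effects implied by the variance components. Exposed for testing:
#' it must agree with a dense evaluation of the (G*T)-dimensional Gaussian
#' density with block-diagonal covariance.
#'
#' @param log_var Numeric length-3: log(sigma0^2), log(sigma1^2),
#'   log(sigma_eps^2).
#' @param y An [response_matrix()] (or bare G x T matrix).
#' @param times Times in days (taken from `y` when it is a response
#'   matrix).
#' @return -2 * profile log-likelihood (scalar).
#' @export
profile_deviance <- function(log_var, y, times = NULL) {
  if (inherits(y, "aaa_response")) { times <- y$times; y <- y$values }
  if (any(!is.finite(log_var))) stop_validation("non-finite variance parameters")
  T_ <- length(times); G <- nrow(y)
  V <- marginal_cov(log_var, times)
  big <- .Machine$double.xmax / 2             # finite penalty for optim
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(big)
  Vi <- chol2inv(ch)
  X <- cbind(1, times)
  A <- crossprod(X, Vi %*% X)                 # 2 x 2
  ybar <- colMeans(y)
  gam <- tryCatch(solve(A, crossprod(X, Vi %*% ybar)), error = function(e) NULL)
  if (is.null(gam)) return(big)
  R <- t(y) - as.vector(X %*% gam)            # T x G residuals
  quad <- sum(R * (Vi %*% R))
  logdet <- 2 * sum(log(diag(ch)))
  dev <- G * T_ * log(2 * pi) + G * logdet + quad
  if (!is.finite(dev)) return(big)
  dev
}

# Final-estimate path: eigendecomposition whitening + QR least squares,
# backward-stable even at boundary optima where V is nearly singular
# (e.g. exact linear data with variance components at the floor).
#' @noRd
gls_fixed_effects <- function(log_var, y, times) {
  V <- marginal_cov(log_var, times)
  E <- eigen(V, symmetric = TRUE)
  vals <- pmax(E$values, .Machine$double.xmin)
  W <- t(E$vectors) / sqrt(vals)              # whitener: W V W' = I
  X <- cbind(1, times)
  Xw <- W %*% X
  gam <- qr.solve(Xw, W %*% colMeans(y))
  list(gamma = as.numeric(gam), W = W, X = X, Xw = Xw)
}

#' Fit the node-wise linear mixed-effects growth model
#'
#' Maximum-likelihood estimation over the three log-variances (bounded
#' L-BFGS-B with three starts: method-of-moments, all-equal and
#' residual-dominated), fixed effects profiled in closed form, node
#' effects recovered as BLUPs `b_n = D Z' V^{-1} (y_n - X gamma)` with
#' `D = diag(sigma0^2, sigma1^2)`, `Z = X = [1, t]`.
#'
#' @param y An [response_matrix()], or a bare G x T matrix.
#' @param times Times in days (ignored when `y` is a response matrix).
#' @param var_floor Lower bound on each variance component (cm^2 or
#'   (cm/day)^2); keeps V invertible at boundary solutions such as the
#'   two-scan case. Default `1e-12`.
#' @param response,layer Labels stored on the fit when `y` is a bare
#'   matrix.
#' @return Object of class `growth_lme` with components `alpha`, `beta`
#'   (fixed effects, cm and cm/day), `sigma0_sq`, `sigma1_sq`,
#'   `sigma_eps_sq`, `b0`, `b1` (G-vector BLUPs), `loglik`, `converged`,
#'   plus the data and times.
#' @export
fit_growth_lme <- function(y, times = NULL, var_floor = 1e-12,
                           response = "radius", layer = "outer_wall") {
  if (inherits(y, "aaa_response")) {
    times <- y$times; response <- y$response; layer <- y$layer; y <- y$values
  }
  y <- as.matrix(y)
  G <- nrow(y); T_ <- length(times)
  if (T_ < 2L) stop_insufficient("need T >= 2 observation times")
  # optimize on span-normalized time: identical V, far better conditioning
  # at boundary optima; the slope and its variance transform back by the
  # span at the end. The floor then applies per component on the unit
  # scale, so a floored slope variance contributes at most var_floor to V.
  span <- max(times)
  ts <- times / span
  lb <- rep(log(var_floor), 3L)
  starts <- lme_starts(y, ts, var_floor)
  best <- NULL
  best_clean <- Inf                           # best value over starts with a clean exit code
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(pmax(s, lb), profile_deviance, y = y, times = ts,
                   method = "L-BFGS-B",
                   lower = lb, upper = rep(log(1e6), 3L),
                   control = list(factr = 1e3, maxit = 1000L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0L) best_clean <- min(best_clean, opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    aaafc_stop("aaafc_convergence_error", "growth model optimizer failed on all starts")
  # a line-search abort at the optimum is still convergence when a clean
  # start reached (numerically) the same objective; otherwise confirm the
  # point with a derivative-free polish — if Nelder-Mead cannot improve
  # it, it is a (possibly bound-constrained) optimum
  tol <- 1e-6 * (1 + abs(best$value))
  if (best$convergence != 0L && best_clean > best$value + tol) {
    clamped <- function(th) profile_deviance(pmin(pmax(th, lb), log(1e6)), y, ts)
    polish <- tryCatch(
      stats::optim(best$par, clamped, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 2000L)),
      error = function(e) NULL)
    if (!is.null(polish)) {
      if (polish$value < best$value - tol) {
        best <- polish
        best$par <- pmin(pmax(best$par, lb), log(1e6))
      } else if (polish$convergence == 0L || any(best$par - lb < 1e-6)) {
        # confirmed interior optimum, or an unimprovable point on the
        # variance floor (the flat clamped region stalls Nelder-Mead
        # without representing a genuine failure)
        best$convergence <- 0L
      }
    }
  }
  converged <- best$convergence == 0L || best_clean <= best$value + tol
  theta <- best$par
  gl <- gls_fixed_effects(theta, y, ts)
  D <- diag(exp(theta[1:2]), 2L)
  R <- t(y) - as.vector(gl$X %*% gl$gamma)    # T x G
  B <- D %*% crossprod(gl$Xw, gl$W %*% R)     # 2 x G BLUPs (whitened form)
  fit <- structure(list(
    alpha = gl$gamma[1], beta = gl$gamma[2] / span,
    sigma0_sq = exp(theta[1]), sigma1_sq = exp(theta[2]) / span^2,
    sigma_eps_sq = exp(theta[3]),
    b0 = B[1, ], b1 = B[2, ] / span,
    loglik = -best$value / 2, deviance = best$value,
    converged = converged,
    times = times, G = G, response = response, layer = layer,
    var_floor = var_floor, y = y,
    call = match.call()),
    class = "growth_lme")
  if (!fit$converged)
    warning("growth model optimizer did not report convergence; returning best fit found",
            call. = FALSE)
  fit
}

# moment-based, all-equal and residual-dominated log-variance starts
#' @noRd
lme_starts <- function(y, times, var_floor) {
  T_ <- length(times)
  tc <- times - mean(times)
  denom <- sum(tc^2)
  slopes <- as.vector(y %*% tc) / denom
  ints <- rowMeans(y) - slopes * mean(times)
  fitted <- outer(ints, rep(1, T_)) + outer(slopes, times)
  rvar <- if (T_ > 2L) sum((y - fitted)^2) / (nrow(y) * (T_ - 2L)) else stats::var(as.vector(y - fitted))
  s0 <- max(stats::var(ints), var_floor)
  s1 <- max(stats::var(slopes), var_floor)
  se <- max(rvar, var_floor, na.rm = TRUE)
  tot <- max(stats::var(as.vector(y)), var_floor)
  list(log(c(s0, s1, se)),
       log(rep(tot / 3, 3L)),
       log(c(var_floor * 10, var_floor * 10, tot)))
}

#' @export
print.growth_lme <- function(x, ...) {
  cat(sprintf("Node-wise LME growth fit (%s, %s): G = %d nodes, T = %d times\n",
              x$layer, x$response, x$G, length(x$times)))
  cat(sprintf("  fixed: alpha = %.5g cm, beta = %.5g cm/day (%.4g cm/year)\n",
              x$alpha, x$beta, x$beta * 365.25))
  cat(sprintf("  variances: sigma0^2 = %.4g, sigma1^2 = %.4g, sigma_eps^2 = %.4g\n",
              x$sigma0_sq, x$sigma1_sq, x$sigma_eps_sq))
  cat(sprintf("  logLik = %.4g, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @export
coef.growth_lme <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
summary.growth_lme <- function(object, ...) {
  s <- list(
    fixed = c(alpha = object$alpha, beta = object$beta,
              beta_per_year = object$beta * 365.25),
    variances = c(sigma0_sq = object$sigma0_sq, sigma1_sq = object$sigma1_sq,
                  sigma_eps_sq = object$sigma_eps_sq),
    blup_sd = c(b0 = stats::sd(object$b0), b1 = stats::sd(object$b1)),
    loglik = object$loglik, G = object$G, times = object$times,
    converged = object$converged)
  class(s) <- "summary.growth_lme"
  s
}

#' @export
print.summary.growth_lme <- function(x, ...) {
  cat("Node-wise linear mixed-effects growth model\n")
  cat(sprintf("  G = %d nodes, T = %d times (days %s)\n", x$G, length(x$times),
              paste(x$times, collapse = ", ")))
  cat(sprintf("  alpha = %.6g cm, beta = %.6g cm/day = %.4g cm/year\n",
              x$fixed["alpha"], x$fixed["beta"], x$fixed["beta_per_year"]))
  cat(sprintf("  sigma0^2 = %.4g cm^2, sigma1^2 = %.4g (cm/day)^2, sigma_eps^2 = %.4g cm^2\n",
              x$variances[1], x$variances[2], x$variances[3]))
  cat(sprintf("  BLUP spread: sd(b0) = %.4g cm, sd(b1) = %.4g cm/day\n",
              x$blup_sd[1], x$blup_sd[2]))
  cat(sprintf("  logLik = %.6g (converged: %s)\n", x$loglik, x$converged))
  invisible(x)
}

#' Node-level predictions at an arbitrary target time
#'
#' `y_hat_n(t*) = (alpha + b0_n) + (beta + b1_n) * t*` — exactly linear in
#' `t*` per node. Extrapolation is allowed by design; a warning is issued
#' when `t*` exceeds the training span by more than 5 years (the
#' interactive forecast range).
#'
#' @param object A `growth_lme` fit.
#' @param t_star Target time(s) in days since baseline.
#' @param level `"node"` (default) for per-node forecasts, `"population"`
#'   for the fixed-effects line only.
#' @param ... Unused.
#' @return G-vector (single `t_star`) or G x length(t_star) matrix.
#' @export
predict.growth_lme <- function(object, t_star = 0, level = c("node", "population"), ...) {
  level <- match.arg(level)
  span <- range(object$times)
  horizon <- 5 * 365.25
  if (any(t_star > span[2] + horizon) || any(t_star < span[1] - horizon))
    warning(sprintf("forecast time beyond 5 years outside the training span [%g, %g] days",
                    span[1], span[2]), call. = FALSE)
  if (level == "population") {
    out <- object$alpha + object$beta * t_star
    return(if (length(t_star) == 1L) out else out)
  }
  a <- object$alpha + object$b0
  b <- object$beta + object$b1
  out <- outer(a, rep(1, length(t_star))) + outer(b, t_star)
  if (length(t_star) == 1L) as.vector(out) else out
}

#' @export
fitted.growth_lme <- function(object, ...) {
  predict(object, t_star = object$times)
}

#' @export
residuals.growth_lme <- function(object, ...) {
  object$y - fitted(object)
}

#' Simulate balanced responses from a fitted growth model
#'
#' Draws new node intercepts/slopes from the fitted variance components
#' around the fixed-effects line plus observation noise, on the training
#' time lattice.
#'
#' @param object A `growth_lme` fit.
#' @param nsim Number of simulated G x T response matrices.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of `nsim` G x T matrices.
#' @export
simulate.growth_lme <- function(object, nsim = 1, seed = NULL, ...) {
  sim1 <- function() {
    G <- object$G; tms <- object$times
    a <- object$alpha + stats::rnorm(G, 0, sqrt(object$sigma0_sq))
    b <- object$beta + stats::rnorm(G, 0, sqrt(object$sigma1_sq))
    outer(a, rep(1, length(tms))) + outer(b, tms) +
      matrix(stats::rnorm(G * length(tms), 0, sqrt(object$sigma_eps_sq)), G)
  }
  runner <- function() replicate(nsim, sim1(), simplify = FALSE)
  if (is.null(seed)) runner() else with_seed(seed, runner())
}

#' Spaghetti plot of node trajectories and the fixed-effects line
#'
#' @param x A `growth_lme` fit.
#' @param max_nodes Number of node trajectories drawn (sampled evenly).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.growth_lme <- function(x, max_nodes = 50L, ...) {
  idx <- unique(round(seq(1, x$G, length.out = min(max_nodes, x$G))))
  ty <- days_to_years(x$times)
  graphics::matplot(ty, t(x$y[idx, , drop = FALSE]), type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", 0.4),
                    xlab = "time since baseline (years)",
                    ylab = sprintf("%s (cm)", x$response),
                    main = sprintf("%s %s: node trajectories", x$layer, x$response), ...)
  graphics::abline(a = x$alpha, b = x$beta * 365.25, col = "firebrick", lwd = 2)
  invisible(x)
}
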