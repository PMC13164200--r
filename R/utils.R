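# Internal helpers: classed conditions and small numeric utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
aaafc_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "aaafc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_format        <- function(msg, ...) aaafc_stop("aaafc_format_error", msg, ...)
stop_validation    <- function(msg, ...) aaafc_stop("aaafc_validation_error", msg, ...)
stop_insufficient  <- function(msg, ...) aaafc_stop("aaafc_insufficient_data_error", msg, ...)
stop_io            <- function(msg, ...) aaafc_stop("aaafc_io_error", msg, ...)
stop_coverage      <- function(msg, ...) aaafc_stop("aaafc_coverage_error", msg, ...)
stop_identifiability <- function(msg, ...) aaafc_stop("aaafc_identifiability_error", msg, ...)
stop_extrapolation <- function(msg, ...) aaafc_stop("aaafc_extrapolation_error", msg, ...)
stop_geometry      <- function(msg, ...) aaafc_stop("aaafc_geometry_error", msg, ...)
stop_topology      <- function(msg, ...) aaafc_stop("aaafc_topology_error", msg, ...)
stop_parameterization <- function(msg, ...) aaafc_stop("aaafc_parameterization_error", msg, ...)
stop_degenerate    <- function(msg, ...) aaafc_stop("aaafc_degenerate_error", msg, ...)
stop_lattice       <- function(msg, ...) aaafc_stop("aaafc_lattice_error", msg, ...)
stop_regime        <- function(msg, ...) aaafc_stop("aaafc_regime_error", msg, ...)
stop_config        <- function(msg, ...) aaafc_stop("aaafc_config_error", msg, ...)
stop_upstream      <- function(msg, ...) aaafc_stop("aaafc_missing_upstream_error", msg, ...)

#' Angular lattice used throughout the package
#'
#' Returns the fixed azimuthal axis \eqn{\theta_i = -\pi + 2\pi i / N},
#' \eqn{i = 0, \dots, N-1}, shared by every scan of a patient.
#'
#' @param n_theta Number of angular nodes.
#' @return Numeric vector of length `n_theta` in \eqn{[-\pi, \pi)}.
#' @export
theta_axis <- function(n_theta) {
  if (n_theta < 3) stop_validation("angular lattice needs at least 3 nodes, got %d", n_theta)
  -pi + 2 * pi * (seq_len(n_theta) - 1) / n_theta
}

#' @noRd
wrap_angle <- function(a) {
  # map to [-pi, pi)
  a <- (a + pi) %% (2 * pi) - pi
  a[a >= pi] <- -pi
  a
}

# run expr with a private RNG stream seeded by `seed`, restoring global state
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
days_to_years <- function(d) d / 365.25

#' @noRd
is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
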