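#' Rate parameters of the fate-adoption model
#'
#' Bundles the kinetic constants of the four-compartment model of ES-cell
#' differentiation: pluripotent cells (P) exit pluripotency at rate
#' `lambda_D`; differentiating cells (D) then commit irreversibly to
#' neuroectoderm (N) at rate `lambda_N` or to Primitive Streak (M) at a
#' piecewise-constant rate that switches from `lambda_M_low` to
#' `lambda_M_high` once a population-level signal crosses the threshold
#' `theta`. In non-PS-permissive media the PS channel is closed entirely
#' (effective rate 0) regardless of the signal.
#'
#' @param lambda_D Exit rate from pluripotency, per day.
#' @param lambda_N D -> NECT commitment rate, per day.
#' @param lambda_M_low D -> PS commitment rate below the signal threshold,
#'   per day. Defaults to 0: PS conversion is negligible before the signal
#'   has built up.
#' @param lambda_M_high D -> PS commitment rate at or above the threshold,
#'   per day. Must be `>= lambda_M_low`.
#' @param theta Dimensionless signal threshold in `[0, 1]`.
#' @param signal_law Functional form of the population signal:
#'   `"instantaneous"` (default) sets s(t) to the non-pluripotent fraction
#'   1 - P(t); `"cumulative"` integrates it over time,
#'   s(t) = integral of (1 - P(u)) du.
#'
#' @return An object of class `rate_params` (a validated named list).
#' @examples
#' rate_params(lambda_D = 0.8, lambda_N = 0.55, lambda_M_high = 8, theta = 0.85)
#' @export
rate_params <- function(lambda_D, lambda_N, lambda_M_low = 0,
                        lambda_M_high = lambda_M_low, theta = 1,
                        signal_law = c("instantaneous", "cumulative")) {
  signal_law <- match.arg(signal_law)
  rates <- c(lambda_D = lambda_D, lambda_N = lambda_N,
             lambda_M_low = lambda_M_low, lambda_M_high = lambda_M_high)
  if (!is.numeric(rates) || anyNA(rates) || any(!is.finite(rates))) {
    stop("all rates must be finite numbers", call. = FALSE)
  }
  if (any(rates < 0)) {
    stop("all rates must be >= 0 (per day)", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta < 0 || theta > 1) {
    stop("`theta` must be a single number in [0, 1]", call. = FALSE)
  }
  if (lambda_M_low > lambda_M_high) {
    stop("`lambda_M_low` must not exceed `lambda_M_high` ",
         "(PS conversion switches from negligible to dominant)", call. = FALSE)
  }
  structure(
    list(lambda_D = lambda_D, lambda_N = lambda_N,
         lambda_M_low = lambda_M_low, lambda_M_high = lambda_M_high,
         theta = theta, signal_law = signal_law),
    class = "rate_params"
  )
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params>\n")
  cat(sprintf("  lambda_D      %-8.4g /day  (exit from pluripotency)\n", x$lambda_D))
  cat(sprintf("  lambda_N      %-8.4g /day  (D -> NECT)\n", x$lambda_N))
  cat(sprintf("  lambda_M_low  %-8.4g /day  (D -> PS, below threshold)\n", x$lambda_M_low))
  cat(sprintf("  lambda_M_high %-8.4g /day  (D -> PS, above threshold)\n", x$lambda_M_high))
  cat(sprintf("  theta         %-8.4g       (signal threshold)\n", x$theta))
  cat(sprintf("  signal_law    %s\n", x$signal_law))
  invisible(x)
}

is_rate_params <- function(x) inherits(x, "rate_params")

assert_rate_params <- function(params) {
  if (!is_rate_params(params)) {
    stop("`params` must be created with `rate_params()`", call. = FALSE)
  }
  invisible(params)
}

#' Population state of the fate-adoption model
#'
#' A point in the model's state space: fractions of pluripotent (p),
#' differentiating (d), NECT-committed (n) and PS-committed (m) cells.
#' Death and division are disregarded, so the fractions are conserved and
#' must sum to 1.
#'
#' @param p,d,n,m Fractions in `[0, 1]` summing to 1 (within 1e-9).
#' @return A named numeric vector `c(p, d, n, m)` of class `population_state`.
#' @examples
#' population_state()            # all cells pluripotent
#' population_state(0.5, 0.3, 0.15, 0.05)
#' @export
population_state <- function(p = 1, d = 0, n = 0, m = 0) {
  s <- c(p = p, d = d, n = n, m = m)
  validate_state(s)
  structure(s, class = "population_state")
}

validate_state <- function(s, tol = 1e-9) {
  if (!is.numeric(s) || length(s) != 4L || anyNA(s) || any(!is.finite(s))) {
    stop("state must be four finite fractions (p, d, n, m)", call. = FALSE)
  }
  if (any(s < -tol) || any(s > 1 + tol)) {
    stop("state fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(s) - 1) > 1e-9) {
    stop("state fractions must sum to 1 (no death or division)", call. = FALSE)
  }
  invisible(s)
}

as_state <- function(x) {
  if (inherits(x, "population_state")) return(unclass(x))
  if (is.numeric(x) && length(x) == 4L) {
    nm <- names(x)
    if (is.null(nm)) names(x) <- c("p", "d", "n", "m")
    x <- x[c("p", "d", "n", "m")]
    validate_state(x)
    return(x)
  }
  stop("cannot interpret `state`: supply `population_state()` or a named ",
       "numeric vector c(p, d, n, m)", call. = FALSE)
}
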