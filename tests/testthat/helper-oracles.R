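# Independent oracles and random-case generators shared across tests.

# Brute-force reference for a constant-rate step: adaptive numerical
# integration of the right-hand side, independent of the closed-form path.
ode_segment_oracle <- function(state, regime, dt, rtol = 1e-11, atol = 1e-13) {
  if (dt == 0) return(unclass(fatekinetics::population_state(
    state[["p"]], state[["d"]], state[["n"]], state[["m"]])))
  deriv <- function(t, y, parms) {
    list(unname(fatekinetics::fate_rhs(y, regime)))
  }
  sol <- deSolve::lsoda(y = unclass(state), times = c(0, dt), func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  sol[2, c("p", "d", "n", "m")]
}

# Bisection oracle for the signal threshold crossing, independent of the
# closed-form crossing_time().
bisect_crossing <- function(params, p0 = 1, upper = 1e3, tol = 1e-10) {
  f <- function(t) fatekinetics::signal_level(params, t, p0)$s - params$theta
  if (f(0) >= 0) return(0)
  if (f(upper) < 0) return(Inf)
  lo <- 0; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

random_params <- function() {
  fatekinetics::rate_params(
    lambda_D = stats::runif(1, 0.05, 3),
    lambda_N = stats::runif(1, 0.05, 3),
    lambda_M_low = stats::runif(1, 0, 0.2),
    lambda_M_high = stats::runif(1, 0.5, 9),
    theta = stats::runif(1, 0.05, 0.95)
  )
}

random_protocol <- function(max_segments = 3) {
  k <- sample(max_segments, 1)
  fatekinetics::protocol(
    conditions = sample(c("N2B27", "AC"), k, replace = TRUE),
    durations = stats::runif(k, 0.5, 3)
  )
}

state_matrix <- function(traj) as.matrix(traj[, c("p", "d", "n", "m")])

protocol_span_of <- function(pr) max(pr$end)
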