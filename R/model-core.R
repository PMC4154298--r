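#' Right-hand side of the fate-adoption ODE system
#'
#' The linear compartmental system
#' \deqn{\dot p = -\lambda_D p,\quad
#'       \dot d = \lambda_D p - (\lambda_N + \lambda_M) d,\quad
#'       \dot n = \lambda_N d,\quad
#'       \dot m = \lambda_M d,}
#' with piecewise-constant effective rates set by the active culture
#' condition and signal regime. Fluxes conserve total cell fraction.
#'
#' @param state A [population_state()] or named numeric `c(p, d, n, m)`.
#' @param regime Named list or vector with effective rates `lambda_D`,
#'   `lambda_N`, `lambda_M` (per day), all `>= 0`.
#' @return Named numeric derivative vector `(dp, dd, dn, dm)`, per day.
#' @examples
#' fate_rhs(population_state(), list(lambda_D = 1, lambda_N = 0.5, lambda_M = 0))
#' @export
fate_rhs <- function(state, regime) {
  s <- as_state(state)
  r <- as_regime(regime)
  d <- c(
    p = -r[["lambda_D"]] * s[["p"]],
    d = r[["lambda_D"]] * s[["p"]] -
      (r[["lambda_N"]] + r[["lambda_M"]]) * s[["d"]],
    n = r[["lambda_N"]] * s[["d"]],
    m = r[["lambda_M"]] * s[["d"]]
  )
  d
}

as_regime <- function(regime) {
  r <- unlist(regime[c("lambda_D", "lambda_N", "lambda_M")])
  if (length(r) != 3L || anyNA(r) || any(!is.finite(r))) {
    stop("`regime` must supply finite lambda_D, lambda_N, lambda_M", call. = FALSE)
  }
  if (any(r < 0)) stop("effective rates must be >= 0", call. = FALSE)
  r
}

# Relative tolerance below which Lambda = lambda_N + lambda_M and lambda_D are
# treated as equal and the confluent (degenerate) closed-form branch is used.
DEGENERATE_TOL <- 1e-9

# Exact solution of the constant-rate linear system over a step of length dt.
# Core primitive behind every deterministic solver in the package.
advance_state <- function(state, lambda_D, lambda_N, lambda_M, dt) {
  p0 <- state[["p"]]; d0 <- state[["d"]]
  n0 <- state[["n"]]; m0 <- state[["m"]]
  L <- lambda_N + lambda_M
  a <- exp(-lambda_D * dt)
  p1 <- p0 * a
  if (L == 0) {
    # no commitment channels open: D only accumulates
    return(c(p = p1, d = d0 + p0 * (1 - a), n = n0, m = m0))
  }
  b <- exp(-L * dt)
  if (abs(L - lambda_D) < DEGENERATE_TOL * max(L, lambda_D, 1)) {
    # confluent branch Lambda == lambda_D
    d1 <- (d0 + lambda_D * p0 * dt) * b
    int_d <- d0 * (1 - b) / L + lambda_D * p0 * (1 - (1 + L * dt) * b) / L^2
  } else {
    d1 <- d0 * b + lambda_D * p0 / (L - lambda_D) * (a - b)
    # E(r) = integral of exp(-r u) over [0, dt]
    E <- function(r) if (r == 0) dt else (1 - exp(-r * dt)) / r
    int_d <- d0 * (1 - b) / L +
      lambda_D * p0 / (L - lambda_D) * (E(lambda_D) - E(L))
  }
  c(p = p1, d = d1, n = n0 + lambda_N * int_d, m = m0 + lambda_M * int_d)
}

#' Exact constant-rate segment solution
#'
#' Advances a population state over a time interval during which all
#' effective rates are constant, using the closed-form solution of the
#' linear system (with a dedicated confluent branch when
#' `lambda_N + lambda_M` coincides with `lambda_D`). This is the building
#' block that piecewise protocol solutions are glued from.
#'
#' @inheritParams fate_rhs
#' @param dt Interval length in days, `>= 0`.
#' @return A [population_state()] at time `dt`.
#' @examples
#' solve_segment(population_state(),
#'               list(lambda_D = 1, lambda_N = 0.5, lambda_M = 0), dt = 1)
#' @export
solve_segment <- function(state, regime, dt) {
  s <- as_state(state)
  r <- as_regime(regime)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0) {
    stop("`dt` must be a single finite number >= 0 (days)", call. = FALSE)
  }
  out <- advance_state(s, r[["lambda_D"]], r[["lambda_N"]], r[["lambda_M"]], dt)
  structure(out, class = "population_state")
}

#' Population signal level
#'
#' The model couples fate bias to a dimensionless signal that builds up as
#' cells lose pluripotency. Under the default (`"instantaneous"`) law the
#' signal is the non-pluripotent fraction, s(t) = 1 - P(t) with
#' P(t) = p0 exp(-lambda_D t); under the `"cumulative"` law it is the time
#' integral of that fraction. Both are monotone nondecreasing, and the
#' threshold crossing is irreversible.
#'
#' @param params A [rate_params()] object (supplies `lambda_D`, `theta` and
#'   the signal law).
#' @param t Time(s) in days, `>= 0`.
#' @param p0 Initial pluripotent fraction (default 1: all cells pluripotent).
#' @return A tibble with columns `time`, `s`, `crossed`.
#' @examples
#' signal_level(rate_params(log(2), 0.5, theta = 0.5), t = 0:3)
#' @export
signal_level <- function(params, t, p0 = 1) {
  assert_rate_params(params)
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) {
    stop("`t` must be non-negative (days)", call. = FALSE)
  }
  s <- signal_value(params, t, p0)
  tibble::tibble(time = as.numeric(t), s = s, crossed = s >= params$theta)
}

signal_value <- function(params, t, p0 = 1) {
  lD <- params$lambda_D
  if (params$signal_law == "instantaneous") {
    1 - p0 * exp(-lD * t)
  } else {
    if (lD == 0) t * (1 - p0) else t - p0 * (1 - exp(-lD * t)) / lD
  }
}

#' Signal threshold-crossing time
#'
#' Smallest time at which the signal reaches the threshold `theta`. Under
#' the instantaneous law this has the closed form
#' t* = log(p0 / (1 - theta)) / lambda_D (so log(1/(1-theta))/lambda_D from
#' a fully pluripotent start); the cumulative law is solved numerically.
#' Returns 0 when the threshold is already met at t = 0 and `Inf` when it is
#' never reached (`theta = 1`, or `lambda_D = 0` from a fully pluripotent
#' start).
#'
#' @inheritParams signal_level
#' @return Crossing time in days, possibly `Inf`.
#' @examples
#' crossing_time(rate_params(log(2), 0.5, theta = 0.5))  # 1 day
#' @export
crossing_time <- function(params, p0 = 1) {
  assert_rate_params(params)
  theta <- params$theta
  if (signal_value(params, 0, p0) >= theta) return(0)
  lD <- params$lambda_D
  if (params$signal_law == "instantaneous") {
    if (theta >= 1 || lD == 0) return(Inf)
    # 1 - p0 exp(-lD t) = theta
    return(log(p0 / (1 - theta)) / lD)
  }
  # cumulative law: s is monotone and unbounded unless lD == 0 and p0 == 1
  if (lD == 0 && p0 >= 1) return(Inf)
  upper <- 1
  while (signal_value(params, upper, p0) < theta) {
    upper <- upper * 2
    if (upper > 1e12) return(Inf)
  }
  stats::uniroot(function(t) signal_value(params, t, p0) - theta,
                 lower = 0, upper = upper, tol = 1e-12)$root
}

# Effective lambda_M for a protocol segment, given signal state.
# Off PS-permissive media the PS channel is closed outright.
lambda_M_eff <- function(params, ps_permissive, post_threshold) {
  if (!ps_permissive) return(0)
  if (post_threshold) params$lambda_M_high else params$lambda_M_low
}

regime_label <- function(condition, post_threshold) {
  paste0(condition, "/", ifelse(post_threshold, "post-threshold", "pre-threshold"))
}

# Breakpoints of the piecewise-constant-rate problem: protocol segment
# boundaries plus the signal crossing time (if it falls inside the span).
piece_table <- function(protocol, params, p0) {
  span <- protocol_span(protocol)
  t_cross <- crossing_time(params, p0)
  bp <- sort(unique(c(protocol$start, span,
                      if (is.finite(t_cross) && t_cross > 0 && t_cross < span) t_cross)))
  t0 <- bp[-length(bp)]
  t1 <- bp[-1]
  seg <- vapply(t0, function(t) segment_at(protocol, t), integer(1))
  post <- t0 >= t_cross
  lM <- mapply(function(s, po) lambda_M_eff(params, protocol$ps_permissive[s], po),
               seg, post)
  list(
    t0 = t0, t1 = t1,
    condition = protocol$condition[seg],
    lambda_M = as.numeric(lM),
    label = regime_label(protocol$condition[seg], post),
    n_pieces = length(t0)
  )
}

#' Simulate the model along a culture protocol (exact piecewise solution)
#'
#' Solves the model exactly by gluing the closed-form constant-rate segment
#' solutions at every breakpoint: protocol segment boundaries plus the
#' signal threshold-crossing time. Within each piece the effective PS rate
#' is constant: 0 in non-PS-permissive media, `lambda_M_low` before the
#' crossing and `lambda_M_high` after it in PS-permissive media. The state
#' is continuous at all breakpoints and total fraction is conserved.
#'
#' @param protocol A [protocol()] object.
#' @param params A [rate_params()] object.
#' @param init Initial [population_state()]; default: all cells pluripotent.
#' @param times Output time grid (days) within the protocol span; default a
#'   0.05-day grid over the full span.
#' @return A tibble of class `fate_trajectory` with columns `time`, `p`,
#'   `d`, `n`, `m`, `signal`, `condition`, `regime_label`. The generating
#'   `params` and `protocol` are stored as attributes.
#' @examples
#' prm <- rate_params(0.8, 0.55, 0, 8, 0.85)
#' traj <- simulate_fates(protocol(c("N2B27", "AC", "N2B27"), c(2, 1, 3)), prm)
#' tail(traj, 1)
#' @export
simulate_fates <- function(protocol, params, init = population_state(),
                           times = NULL) {
  assert_rate_params(params)
  span <- protocol_span(protocol)
  state <- as_state(init)
  if (is.null(times)) times <- seq(0, span, by = 0.05)
  times <- as.numeric(times)
  if (length(times) == 0L || anyNA(times)) stop("empty output grid", call. = FALSE)
  if (any(times < -1e-12) || any(times > span + 1e-12)) {
    stop("output grid times must lie within the protocol span [0, ",
         span, "]", call. = FALSE)
  }
  ord <- order(times)
  pieces <- piece_table(protocol, params, state[["p"]])

  out <- matrix(NA_real_, nrow = length(times), ncol = 4,
                dimnames = list(NULL, c("p", "d", "n", "m")))
  lab <- character(length(times))
  cond <- character(length(times))
  for (k in seq_len(pieces$n_pieces)) {
    t0 <- pieces$t0[k]; t1 <- pieces$t1[k]
    last <- k == pieces$n_pieces
    sel <- ord[times[ord] >= t0 - 1e-12 &
                 (times[ord] < t1 - 1e-12 | (last & times[ord] <= t1 + 1e-12))]
    for (i in sel) {
      out[i, ] <- advance_state(state, params$lambda_D, params$lambda_N,
                                pieces$lambda_M[k], max(times[i] - t0, 0))
      lab[i] <- pieces$label[k]
      cond[i] <- pieces$condition[k]
    }
    state <- advance_state(state, params$lambda_D, params$lambda_N,
                           pieces$lambda_M[k], t1 - t0)
  }
  o <- order(times)
  res <- tibble::new_tibble(list(
    time = times[o], p = as.vector(out[o, "p"]), d = as.vector(out[o, "d"]),
    n = as.vector(out[o, "n"]), m = as.vector(out[o, "m"]),
    signal = signal_value(params, times[o], as_state(init)[["p"]]),
    condition = cond[o], regime_label = lab[o]
  ), nrow = length(times))
  attr(res, "params") <- params
  attr(res, "protocol") <- protocol
  class(res) <- c("fate_trajectory", class(res))
  res
}

#' Numerical reference solver (adaptive ODE integration)
#'
#' Independent check on [simulate_fates()]: integrates the same right-hand
#' side with `deSolve`'s adaptive `lsodar`, locating the signal
#' threshold-crossing by root-finding on s(t) - theta instead of using the
#' analytic crossing time, and restarting at every protocol boundary.
#' Intended for validation; the analytic solver is the one to use.
#'
#' @inheritParams simulate_fates
#' @param rtol,atol Relative and absolute integration tolerances.
#' @return A tibble of class `fate_trajectory` (columns as in
#'   [simulate_fates()]).
#' @export
simulate_fates_ode <- function(protocol, params, init = population_state(),
                               times = NULL, rtol = 1e-9, atol = 1e-12) {
  assert_rate_params(params)
  span <- protocol_span(protocol)
  state <- as_state(init)
  p0 <- state[["p"]]
  if (is.null(times)) times <- seq(0, span, by = 0.05)
  times <- sort(unique(as.numeric(times)))
  if (any(times < -1e-12) || any(times > span + 1e-12)) {
    stop("output grid times must lie within the protocol span", call. = FALSE)
  }

  deriv <- function(t, y, parms) {
    lam <- c(lambda_D = params$lambda_D, lambda_N = params$lambda_N,
             lambda_M = parms$lambda_M)
    list(unname(fate_rhs(y[1:4], lam)))
  }
  # root: signal crossing; signal depends on the integrated p (instantaneous)
  # or on an auxiliary integral state (cumulative)
  crossed <- params$theta <= signal_value(params, 0, p0)
  y <- c(state, scum = 0)
  deriv_full <- function(t, y, parms) {
    base <- deriv(t, y, parms)[[1]]
    list(c(base, 1 - y[["p"]]))
  }
  sig_of <- function(y) {
    if (params$signal_law == "instantaneous") 1 - y[["p"]] else y[["scum"]]
  }
  rootfun <- function(t, y, parms) sig_of(y) - params$theta

  rows <- list()
  record <- function(sol, cond_name, post) {
    tt <- sol[, "time"]
    keep <- tt %in% times | abs(tt - span) < 1e-12
    if (!any(keep)) return()
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      time = tt[keep], p = sol[keep, "p"], d = sol[keep, "d"],
      n = sol[keep, "n"], m = sol[keep, "m"],
      condition = cond_name, regime_label = regime_label(cond_name, post)
    )
  }

  t_now <- 0
  for (k in seq_len(nrow(protocol))) {
    t_end <- protocol$end[k]
    cond_name <- protocol$condition[k]
    perm <- protocol$ps_permissive[k]
    while (t_now < t_end - 1e-14) {
      lM <- lambda_M_eff(params, perm, crossed)
      tt <- sort(unique(c(t_now, t_end, times[times > t_now + 1e-14 & times < t_end - 1e-14])))
      sol <- deSolve::lsodar(y = y, times = tt, func = deriv_full,
                             parms = list(lambda_M = lM),
                             rootfunc = if (!crossed) rootfun else NULL,
                             rtol = rtol, atol = atol)
      if (inherits(sol, "try-error") || anyNA(sol[nrow(sol), ])) {
        stop("numerical integration failed between t = ", t_now, " and ", t_end,
             call. = FALSE)
      }
      t_reached <- sol[nrow(sol), "time"]
      # drop a root-stop row from output unless it is a requested time
      record(sol[sol[, "time"] > t_now - 1e-14 | t_now == 0, , drop = FALSE],
             cond_name, crossed)
      y <- sol[nrow(sol), c("p", "d", "n", "m", "scum")]
      if (t_reached < t_end - 1e-12) {
        crossed <- TRUE      # terminated at the signal root: switch regime
        t_now <- t_reached
      } else {
        t_now <- t_end
      }
      # a crossing landing exactly on a boundary leaves no interior root
      if (!crossed && sig_of(y) >= params$theta - 1e-13) crossed <- TRUE
    }
  }

  res <- dplyr::bind_rows(rows)
  res <- res[!duplicated(res$time, fromLast = TRUE), ]
  res <- res[res$time %in% times, ]
  res <- res[order(res$time), ]
  res$signal <- signal_value(params, res$time, p0)
  res <- res[, c("time", "p", "d", "n", "m", "signal", "condition", "regime_label")]
  attr(res, "params") <- params
  attr(res, "protocol") <- protocol
  class(res) <- c("fate_trajectory", class(res))
  res
}
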