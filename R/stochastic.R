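#' Stochastic per-cell simulation of fate adoption
#'
#' Discrete-time Markov-chain counterpart of the mean-field model. Each
#' cell starts pluripotent and, per step of length `dt`, exits pluripotency
#' with probability `1 - exp(-lambda_D dt)`; differentiating cells then
#' face a single categorical draw between NECT and PS with competing
#' probabilities `lambda_N / Lambda (1 - exp(-Lambda dt))` and
#' `lambda_M / Lambda (1 - exp(-Lambda dt))`, `Lambda = lambda_N +
#' lambda_M`. The effective PS rate follows the active condition and the
#' signal regime; by default the signal is computed self-consistently from
#' the realized pluripotent fraction of the simulated population
#' (`signal_coupling = "realized"`), with a `"deterministic"` variant using
#' the mean-field signal. Exit and commitment times are refined within
#' their step by truncated-exponential draws, so marginal exit times are
#' exactly exponential with rate `lambda_D`.
#'
#' @inheritParams simulate_fates
#' @param n_cells Number of cells, `>= 1`.
#' @param dt Step size in days, in `(0, 0.05]`; the cap keeps per-step
#'   transition probabilities small enough for the competing-risks
#'   approximation.
#' @param seed Mandatory integer seed; runs are fully reproducible.
#' @param signal_coupling `"realized"` (default) or `"deterministic"`.
#' @return A list of class `cell_simulation` with elements `counts` (tibble
#'   `time`, `P`, `D`, `N`, `M`; integer counts summing to `n_cells`) and
#'   `cells` (tibble `cell_id`, `t_exit`, `t_commit`, `final_fate` in
#'   `{"NECT", "PS", "uncommitted"}`).
#' @examples
#' sim <- simulate_cells(protocol("N2B27", 6), paper_like_params(),
#'                       n_cells = 500, seed = 1)
#' tail(sim$counts, 1)
#' @export
simulate_cells <- function(protocol, params, n_cells, dt = 0.05, seed,
                           init = population_state(),
                           signal_coupling = c("realized", "deterministic")) {
  signal_coupling <- match.arg(signal_coupling)
  assert_rate_params(params)
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory for stochastic simulations", call. = FALSE)
  }
  if (!is.numeric(n_cells) || n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0 || dt > 0.05) {
    stop("`dt` must be in (0, 0.05] days (transition-probability accuracy)",
         call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  span <- protocol_span(protocol)
  init <- as_state(init)
  steps <- ceiling(span / dt - 1e-9)
  times <- pmin(seq(0, by = dt, length.out = steps + 1L), span)

  # initial states drawn to match the initial fractions exactly (rounded)
  n_init <- round(init * n_cells)
  n_init[1] <- n_cells - sum(n_init[-1])
  state <- rep.int(1:4, n_init)  # 1=P 2=D 3=N 4=M

  t_exit <- rep(NA_real_, n_cells)
  t_commit <- rep(NA_real_, n_cells)
  counts <- matrix(0L, nrow = steps + 1L, ncol = 4L,
                   dimnames = list(NULL, c("P", "D", "N", "M")))
  crossed <- FALSE
  lD <- params$lambda_D
  lN <- params$lambda_N

  withr::with_seed(as.integer(seed), {
    counts[1L, ] <- tabulate(state, nbins = 4L)
    for (k in seq_len(steps)) {
      t0 <- times[k]
      h <- times[k + 1L] - t0
      seg <- segment_at(protocol, t0)
      s_now <- if (signal_coupling == "realized") {
        1 - sum(state == 1L) / n_cells
      } else {
        signal_value(params, t0, init[["p"]])
      }
      if (!crossed && s_now >= params$theta) crossed <- TRUE
      lM <- lambda_M_eff(params, protocol$ps_permissive[seg], crossed)

      # D -> N / M competing draw for cells differentiating at step start
      d_idx <- which(state == 2L)
      if (length(d_idx) > 0L) {
        Lam <- lN + lM
        if (Lam > 0) {
          p_any <- -expm1(-Lam * h)
          pN <- lN / Lam * p_any
          pM <- lM / Lam * p_any
          u <- stats::runif(length(d_idx))
          to_N <- d_idx[u < pN]
          to_M <- d_idx[u >= pN & u < pN + pM]
          moved <- c(to_N, to_M)
          if (length(moved) > 0L) {
            # refine commitment times within the step (truncated exponential)
            v <- stats::runif(length(moved))
            t_commit[moved] <- t0 - log1p(v * expm1(-Lam * h)) / Lam
          }
          state[to_N] <- 3L
          state[to_M] <- 4L
        }
      }

      # P -> D exits
      p_idx <- which(state == 1L)
      if (length(p_idx) > 0L && lD > 0) {
        pe <- -expm1(-lD * h)
        u <- stats::runif(length(p_idx))
        exits <- p_idx[u < pe]
        if (length(exits) > 0L) {
          v <- stats::runif(length(exits))
          t_exit[exits] <- t0 - log1p(v * expm1(-lD * h)) / lD
          state[exits] <- 2L
        }
      }
      counts[k + 1L, ] <- tabulate(state, nbins = 4L)
    }
  })

  fate <- c("uncommitted", "uncommitted", "NECT", "PS")[state]
  out <- list(
    counts = tibble::tibble(time = times,
                            P = counts[, "P"], D = counts[, "D"],
                            N = counts[, "N"], M = counts[, "M"]),
    cells = tibble::tibble(cell_id = seq_len(n_cells),
                           t_exit = t_exit, t_commit = t_commit,
                           final_fate = fate),
    n_cells = n_cells, dt = dt, seed = as.integer(seed),
    params = params, protocol = protocol, signal_coupling = signal_coupling
  )
  class(out) <- "cell_simulation"
  out
}

#' @export
print.cell_simulation <- function(x, ...) {
  endpoint <- x$counts[nrow(x$counts), ]
  cat(sprintf("<cell_simulation: %d cells, dt = %g d, seed = %d, signal = %s>\n",
              x$n_cells, x$dt, x$seed, x$signal_coupling))
  cat(sprintf("  endpoint (t = %g d): P %d  D %d  N %d  M %d\n",
              endpoint$time, endpoint$P, endpoint$D, endpoint$N, endpoint$M))
  invisible(x)
}
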