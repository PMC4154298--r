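#' Endpoint fate response across pulse days
#'
#' Simulates every protocol of a pulse-chase design with the exact
#' piecewise solver and tabulates the endpoint fate fractions: NECT
#' (`n_final`, the Sox1::GFP+ analogue), PS (`m_final`, the T::GFP+
#' analogue) and the reporter-negative remainder (`uncommitted_final`,
#' p + d). Rows are ordered by pulse start day.
#'
#' @param design A [pulse_chase_design()].
#' @param params A [rate_params()] object.
#' @param init Initial [population_state()].
#' @return A tibble of class `pulse_response` with columns
#'   `pulse_start_day`, `n_final`, `m_final`, `uncommitted_final`.
#' @examples
#' pulse_response(pulse_chase_design(), paper_like_params())
#' @export
pulse_response <- function(design, params, init = population_state()) {
  stopifnot(inherits(design, "pulse_chase_design"))
  assert_rate_params(params)
  protos <- pulse_chase_protocols(design)
  rows <- purrr::map2_dfr(protos, design$pulse_start_days, function(pr, day) {
    end <- simulate_fates(pr, params, init = init, times = design$total_duration)
    tibble::tibble(
      pulse_start_day = day,
      n_final = end$n,
      m_final = end$m,
      uncommitted_final = end$p + end$d
    )
  })
  attr(rows, "params") <- params
  attr(rows, "design") <- design
  class(rows) <- c("pulse_response", class(rows))
  rows
}

#' Correlation between NECT and PS endpoint responses
#'
#' Pearson correlation between the NECT and PS endpoint fractions across
#' pulse days. In the race-for-fates picture a strongly negative value is
#' expected: days on which the pulse captures many cells for PS are days on
#' which NECT loses them.
#'
#' @param table A [pulse_response()] tibble (or any data frame with
#'   `n_final` and `m_final` columns and at least 3 rows).
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @examples
#' fate_correlation(pulse_response(pulse_chase_design(), paper_like_params()))
#' @export
fate_correlation <- function(table) {
  if (!all(c("n_final", "m_final") %in% names(table))) {
    stop("`table` must have columns `n_final` and `m_final`", call. = FALSE)
  }
  if (nrow(table) < 3L) {
    stop("need at least 3 pulse days to compute a correlation", call. = FALSE)
  }
  if (stats::sd(table$n_final) == 0 || stats::sd(table$m_final) == 0) {
    stop("correlation undefined: zero variance in an endpoint response",
         call. = FALSE)
  }
  stats::cor(table$n_final, table$m_final)
}
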