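#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated fate trajectory
#'
#' Fraction of each compartment over time, with the population signal as a
#' dashed curve and a vertical line at the threshold-crossing time.
#'
#' @param object A `fate_trajectory` from [simulate_fates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fate_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("p", "d", "n", "m"),
                              names_to = "compartment", values_to = "fraction")
  long$compartment <- factor(long$compartment, levels = c("p", "d", "n", "m"),
                             labels = c("pluripotent (P)", "differentiating (D)",
                                        "NECT (N)", "PS (M)"))
  params <- attr(object, "params")
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$fraction,
                                           colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_line(
      data = tibble::as_tibble(object),
      ggplot2::aes(y = pmin(.data$signal, 1)), inherit.aes = FALSE,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(x = "time (days)", y = "fraction of cells",
                  colour = NULL,
                  caption = "dashed: population signal s(t)") +
    ggplot2::theme_minimal()
  if (!is.null(params)) {
    tc <- crossing_time(params, p0 = object$p[which.min(object$time)])
    if (is.finite(tc) && tc <= max(object$time)) {
      gg <- gg + ggplot2::geom_vline(xintercept = tc, linetype = "dotted")
    }
  }
  gg
}

#' Plot a pulse-chase endpoint response
#'
#' Endpoint NECT and PS fractions against the pulse start day: the
#' competence-window readout.
#'
#' @param object A `pulse_response` from [pulse_response()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pulse_response <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("n_final", "m_final", "uncommitted_final"),
                              names_to = "fate", values_to = "fraction")
  long$fate <- factor(long$fate,
                      levels = c("n_final", "m_final", "uncommitted_final"),
                      labels = c("NECT", "PS", "uncommitted"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pulse_start_day,
                                     y = .data$fraction, colour = .data$fate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pulse start day", y = "endpoint fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a stochastic simulation against its mean-field prediction
#'
#' Per-compartment cell fractions from the stochastic run (points) overlaid
#' on the deterministic solution (lines).
#'
#' @param object A `cell_simulation` from [simulate_cells()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cell_simulation <- function(object, ...) {
  frac <- dplyr::mutate(object$counts,
                        dplyr::across(c("P", "D", "N", "M"), ~ .x / object$n_cells))
  long <- tidyr::pivot_longer(frac, cols = c("P", "D", "N", "M"),
                              names_to = "compartment", values_to = "fraction")
  det <- simulate_fates(object$protocol, object$params,
                        times = object$counts$time)
  det_long <- tidyr::pivot_longer(
    dplyr::rename(tibble::as_tibble(det), P = "p", D = "d", N = "n", M = "m"),
    cols = c("P", "D", "N", "M"),
    names_to = "compartment", values_to = "fraction"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$fraction,
                                     colour = .data$compartment)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::geom_line(data = det_long) +
    ggplot2::labs(x = "time (days)", y = "fraction of cells", colour = NULL,
                  caption = "points: stochastic run; lines: mean-field solution") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
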