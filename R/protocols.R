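#' Built-in culture-condition registry
#'
#' The model distinguishes culture conditions only by whether they permit
#' Primitive Streak conversion. The registry ships the two conditions used
#' throughout: `N2B27` (neutral serum-free differentiation medium, PS channel
#' closed) and `AC` (Activin 100 ng/ml + CHIR99021 3 uM, PS-permissive).
#' Additional conditions can be registered by appending rows of the same
#' shape; the model claims no kinetics for them beyond the user-set gating.
#'
#' @return A tibble with columns `name`, `ps_permissive` and a list-column
#'   `media_meta` of free-form annotations.
#' @examples
#' default_conditions()
#' @export
default_conditions <- function() {
  tibble::tibble(
    name = c("N2B27", "AC"),
    ps_permissive = c(FALSE, TRUE),
    media_meta = list(
      list(base = "N2B27"),
      list(base = "N2B27", Activin = "100 ng/ml", CHIR99021 = "3 uM")
    )
  )
}

#' Look up a culture condition by name
#'
#' @param name Condition label, e.g. `"AC"` or `"N2B27"`.
#' @param registry A condition registry tibble; defaults to
#'   [default_conditions()]. Extend it with `dplyr::bind_rows()` to register
#'   new media.
#' @return A one-row tibble (`name`, `ps_permissive`, `media_meta`).
#' @examples
#' condition_from_name("AC")$ps_permissive  # TRUE
#' @export
condition_from_name <- function(name, registry = default_conditions()) {
  stopifnot(is.character(name), length(name) == 1L)
  hit <- registry[registry$name == name, ]
  if (nrow(hit) != 1L) {
    stop(sprintf("unknown condition '%s'; known conditions: %s",
                 name, paste(registry$name, collapse = ", ")), call. = FALSE)
  }
  if (is.na(hit$ps_permissive)) {
    stop(sprintf("condition '%s' has no ps_permissive flag", name), call. = FALSE)
  }
  hit
}

#' Build a culture protocol from condition segments
#'
#' A protocol is an ordered, contiguous sequence of half-open time segments
#' `[start, end)`, each spent in one culture condition, with the population
#' state continuous at every boundary (media changes swap the environment,
#' not the cells).
#'
#' @param conditions Character vector of condition names (looked up in
#'   `registry`).
#' @param durations Numeric vector of segment durations in days, all `> 0`,
#'   recycled against `conditions` only if length 1.
#' @param registry Condition registry, see [condition_from_name()].
#' @return A tibble of class `fate_protocol` with columns `segment`,
#'   `condition`, `ps_permissive`, `duration`, `start`, `end`.
#' @examples
#' protocol("N2B27", 6)
#' protocol(c("N2B27", "AC", "N2B27"), c(2, 1, 3))   # 1-day AC pulse on day 2
#' @export
protocol <- function(conditions, durations, registry = default_conditions()) {
  if (length(durations) == 1L) durations <- rep(durations, length(conditions))
  if (length(conditions) == 0L) stop("protocol must have >= 1 segment", call. = FALSE)
  if (length(conditions) != length(durations)) {
    stop("`conditions` and `durations` lengths differ", call. = FALSE)
  }
  if (!is.numeric(durations) || anyNA(durations) || any(!is.finite(durations)) ||
      any(durations <= 0)) {
    stop("segment durations must be finite and strictly positive (days)",
         call. = FALSE)
  }
  perm <- vapply(conditions, function(nm) condition_from_name(nm, registry)$ps_permissive,
                 logical(1))
  end <- cumsum(durations)
  out <- tibble::tibble(
    segment = seq_along(conditions),
    condition = as.character(conditions),
    ps_permissive = unname(perm),
    duration = as.numeric(durations),
    start = c(0, end[-length(end)]),
    end = end
  )
  class(out) <- c("fate_protocol", class(out))
  out
}

is_protocol <- function(x) inherits(x, "fate_protocol")

protocol_span <- function(protocol) {
  if (!is_protocol(protocol) || nrow(protocol) == 0L) {
    stop("`protocol` must be a non-empty `protocol()` object", call. = FALSE)
  }
  protocol$end[nrow(protocol)]
}

# condition row index active at time t under half-open [start, end) segments;
# the protocol endpoint belongs to the last segment.
segment_at <- function(protocol, t) {
  span <- protocol_span(protocol)
  if (t < 0 || t > span) stop("time outside protocol span", call. = FALSE)
  if (t >= span) return(nrow(protocol))
  findInterval(t, protocol$start)
}

#' Pulse-chase experimental design
#'
#' Describes a family of protocols in which a single pulse of one condition
#' (default 1 day of AC) is applied at each of several start days within an
#' otherwise constant background (default 6 days of N2B27), mirroring the
#' classic competence-window experiment: the endpoint fate distribution is
#' read once, at the end of the full time course.
#'
#' @param total_duration Total protocol length, days.
#' @param pulse_duration Pulse length, days.
#' @param pulse_start_days Sorted unique start days; each pulse must fit:
#'   `start + pulse_duration <= total_duration`.
#' @param pulse_condition,base_condition Condition names.
#' @param registry Condition registry.
#' @return A list of class `pulse_chase_design`.
#' @examples
#' pulse_chase_design()   # the default: 1-day AC pulses on days 0..5 of 6 d N2B27
#' @export
pulse_chase_design <- function(total_duration = 6, pulse_duration = 1,
                               pulse_start_days = 0:5,
                               pulse_condition = "AC", base_condition = "N2B27",
                               registry = default_conditions()) {
  stopifnot(is.numeric(total_duration), total_duration > 0,
            is.numeric(pulse_duration), pulse_duration > 0)
  pulse_start_days <- as.numeric(pulse_start_days)
  if (anyNA(pulse_start_days) || any(pulse_start_days < 0)) {
    stop("pulse start days must be non-negative", call. = FALSE)
  }
  if (is.unsorted(pulse_start_days, strictly = TRUE)) {
    stop("`pulse_start_days` must be sorted and unique", call. = FALSE)
  }
  if (any(pulse_start_days + pulse_duration > total_duration + 1e-12)) {
    stop("each pulse must fit inside the total duration ",
         "(start + pulse_duration <= total_duration)", call. = FALSE)
  }
  condition_from_name(pulse_condition, registry)
  condition_from_name(base_condition, registry)
  structure(
    list(total_duration = total_duration, pulse_duration = pulse_duration,
         pulse_start_days = pulse_start_days,
         pulse_condition = pulse_condition, base_condition = base_condition,
         registry = registry),
    class = "pulse_chase_design"
  )
}

#' Expand a pulse-chase design into one protocol per pulse day
#'
#' @param design A [pulse_chase_design()].
#' @return A named list of [protocol()] objects (`"pulse_day_<d>"`), each
#'   spanning exactly `total_duration` days; zero-length leading or trailing
#'   background segments are omitted.
#' @examples
#' pulse_chase_protocols(pulse_chase_design(pulse_start_days = c(0, 2)))
#' @export
pulse_chase_protocols <- function(design) {
  stopifnot(inherits(design, "pulse_chase_design"))
  out <- lapply(design$pulse_start_days, function(start) {
    conds <- c(design$base_condition, design$pulse_condition, design$base_condition)
    durs <- c(start, design$pulse_duration,
              design$total_duration - start - design$pulse_duration)
    keep <- durs > 1e-12
    protocol(conds[keep], durs[keep], registry = design$registry)
  })
  names(out) <- paste0("pulse_day_", format_day(design$pulse_start_days))
  out
}

format_day <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, format(round(x)), format(x))
}
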