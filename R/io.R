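#' Read a reporter time-course dataset from CSV
#'
#' Expects columns `time_day`, `protocol_id`, `reporter`,
#' `positive_count`, `total_count` (and optionally `fraction`,
#' `pulse_start_day`). Fractions are filled in from counts when absent.
#'
#' @param path CSV file path.
#' @return A `timecourse_dataset` tibble. Protocols are not stored in the
#'   CSV; pass them to the fitting functions via `protocols =`.
#' @export
read_timecourse <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time" %in% names(x) && "time_day" %in% names(x)) {
    x <- dplyr::rename(x, time = "time_day")
  }
  if (!"fraction" %in% names(x)) {
    x$fraction <- x$positive_count / x$total_count
  }
  assert_timecourse(x)
  class(x) <- c("timecourse_dataset", class(x))
  x
}

#' Write a reporter time-course dataset to CSV
#'
#' @param dataset A `timecourse_dataset` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(dataset, path) {
  assert_timecourse(dataset)
  out <- dplyr::rename(tibble::as_tibble(dataset), time_day = "time")
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a simulated trajectory to CSV
#'
#' Columns: `time_day`, `p`, `d`, `n`, `m`, `signal`, `regime_label`.
#'
#' @param trajectory A `fate_trajectory` from [simulate_fates()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "fate_trajectory"))
  out <- tibble::as_tibble(trajectory)[, c("time", "p", "d", "n", "m",
                                           "signal", "regime_label")]
  out <- dplyr::rename(out, time_day = "time")
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a pulse-response table to CSV
#'
#' Columns: `pulse_start_day`, `n_final`, `m_final`, `uncommitted_final`.
#'
#' @param table A `pulse_response` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pulse_response <- function(table, path) {
  stopifnot(inherits(table, "pulse_response"))
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Read rate parameters from a YAML or JSON config
#'
#' Recognised keys: `lambda_D`, `lambda_N`, `lambda_M_low`,
#' `lambda_M_high`, `theta`, `signal_law`.
#'
#' @param path A `.yml`/`.yaml` or `.json` file.
#' @return A [rate_params()] object.
#' @export
read_params <- function(path) {
  x <- read_structured(path)
  known <- c("lambda_D", "lambda_N", "lambda_M_low", "lambda_M_high",
             "theta", "signal_law")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(rate_params, x)
}

#' Write rate parameters to a YAML or JSON config
#'
#' @param params A [rate_params()] object.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  assert_rate_params(params)
  write_structured(unclass(params), path)
  invisible(path)
}

read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

write_structured <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
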