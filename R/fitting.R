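REPORTER_COLUMN <- c(NECT = "n", PS = "m", pluripotency = "p")

dataset_fraction <- function(dataset) {
  if ("fraction" %in% names(dataset) && !anyNA(dataset$fraction)) {
    return(dataset$fraction)
  }
  dataset$positive_count / dataset$total_count
}

assert_timecourse <- function(dataset) {
  needed <- c("time", "protocol_id", "reporter")
  if (!all(needed %in% names(dataset))) {
    stop("dataset must have columns time, protocol_id, reporter and either ",
         "fraction or positive_count/total_count", call. = FALSE)
  }
  if (!("fraction" %in% names(dataset)) &&
      !all(c("positive_count", "total_count") %in% names(dataset))) {
    stop("dataset must carry `fraction` or `positive_count`/`total_count`",
         call. = FALSE)
  }
  if (any(!dataset$reporter %in% names(REPORTER_COLUMN))) {
    stop("unknown reporter; expected one of: ",
         paste(names(REPORTER_COLUMN), collapse = ", "), call. = FALSE)
  }
  if (all(c("positive_count", "total_count") %in% names(dataset))) {
    cnt <- stats::complete.cases(dataset[, c("positive_count", "total_count")])
    if (any(dataset$positive_count[cnt] > dataset$total_count[cnt]) ||
        any(dataset$positive_count[cnt] < 0) || any(dataset$total_count[cnt] <= 0)) {
      stop("counts must satisfy 0 <= positive_count <= total_count, total > 0",
           call. = FALSE)
    }
  }
  if (any(dataset$time < 0)) stop("observation times must be >= 0", call. = FALSE)
  invisible(dataset)
}

resolve_protocols <- function(dataset, protocols) {
  if (is.null(protocols)) protocols <- attr(dataset, "protocols")
  if (is.null(protocols)) {
    stop("no protocols available: pass `protocols =` (a named list of ",
         "protocol() objects keyed by protocol_id)", call. = FALSE)
  }
  missing <- setdiff(unique(dataset$protocol_id), names(protocols))
  if (length(missing) > 0L) {
    stop("dataset references unknown protocol id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  protocols
}

# Model-predicted fraction for every dataset record, one simulation per
# protocol at its distinct observation times.
predict_fractions <- function(params, dataset, protocols) {
  pred <- numeric(nrow(dataset))
  for (id in unique(dataset$protocol_id)) {
    idx <- which(dataset$protocol_id == id)
    tt <- sort(unique(dataset$time[idx]))
    traj <- simulate_fates(protocols[[id]], params, times = tt)
    for (i in idx) {
      row <- traj[match_time(traj$time, dataset$time[i]), ]
      pred[i] <- row[[REPORTER_COLUMN[[dataset$reporter[i]]]]]
    }
  }
  pred
}

match_time <- function(grid, t) which.min(abs(grid - t))

build_params <- function(candidate, fixed) {
  all <- utils::modifyList(as.list(fixed), as.list(candidate))
  needed <- c("lambda_D", "lambda_N", "lambda_M_low", "lambda_M_high", "theta")
  missing <- setdiff(needed, names(all))
  if (length(missing) > 0L) {
    stop("candidate + fixed must fully specify the rate parameters; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rate_params(lambda_D = all$lambda_D, lambda_N = all$lambda_N,
              lambda_M_low = all$lambda_M_low, lambda_M_high = all$lambda_M_high,
              theta = all$theta,
              signal_law = all$signal_law %||% "instantaneous")
}

#' Sum-of-squares loss of a parameter candidate on a time-course dataset
#'
#' Sum over records of the squared difference between the observed
#' reporter-positive fraction and the model-predicted fraction for that
#' reporter, at that time, under that protocol. Optionally weighted by the
#' inverse binomial variance of each observation.
#'
#' @param dataset A time-course dataset tibble (columns `time`,
#'   `protocol_id`, `reporter`, and `fraction` or
#'   `positive_count`/`total_count`), e.g. from [generate_neutral_dataset()]
#'   or [read_timecourse()].
#' @param candidate Named list/vector of the parameters being evaluated.
#' @param fixed Named list of the remaining parameters held fixed;
#'   `candidate` and `fixed` together must fully specify [rate_params()].
#' @param protocols Named list of [protocol()] objects keyed by
#'   `protocol_id`; defaults to the `protocols` attribute generated datasets
#'   carry.
#' @param weights `"none"` (default) for unweighted SSE on the fraction
#'   scale, `"binomial"` to weight each record by
#'   `total_count / (f (1 - f))`.
#' @return A single non-negative loss value.
#' @export
sse_loss <- function(dataset, candidate, fixed = list(), protocols = NULL,
                     weights = c("none", "binomial")) {
  weights <- match.arg(weights)
  assert_timecourse(dataset)
  protocols <- resolve_protocols(dataset, protocols)
  params <- build_params(candidate, fixed)
  obs <- dataset_fraction(dataset)
  pred <- predict_fractions(params, dataset, protocols)
  w <- rep(1, nrow(dataset))
  if (weights == "binomial" && "total_count" %in% names(dataset) &&
      !anyNA(dataset$total_count)) {
    f <- pmin(pmax(obs, 1e-6), 1 - 1e-6)
    w <- dataset$total_count / (f * (1 - f))
  }
  sum(w * (obs - pred)^2)
}

new_fate_fit <- function(estimates, loss, n_starts, converged, bounds, seed,
                         fixed, method, starts, extra = list()) {
  structure(
    c(list(estimates = estimates, loss = loss, n_starts = n_starts,
           converged = converged, bounds = bounds, seed = seed,
           fixed = fixed, method = method, starts = starts), extra),
    class = "fate_fit"
  )
}

#' @export
print.fate_fit <- function(x, ...) {
  cat(sprintf("<fate_fit: %s>  loss = %.6g  (%d starts, converged: %s)\n",
              x$method, x$loss, x$n_starts, x$converged))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-14s %.6g   [bounds %g, %g]\n", nm, x$estimates[[nm]],
                x$bounds[[nm]][1], x$bounds[[nm]][2]))
  }
  if (!is.null(x$regime_consistent)) {
    cat(sprintf("  lambda_M_high >> lambda_N regime consistent: %s\n",
                x$regime_consistent))
  }
  invisible(x)
}

multistart_fit <- function(objective, bounds, n_starts, seed) {
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  withr::with_seed(seed, {
    starts <- replicate(n_starts,
                        exp(stats::runif(length(bounds), log(lower), log(upper))),
                        simplify = FALSE)
    fits <- lapply(starts, function(x0) {
      names(x0) <- names(bounds)
      tryCatch(
        stats::nlminb(x0, objective, lower = lower, upper = upper,
                      control = list(iter.max = 500, eval.max = 2000,
                                     rel.tol = 1e-12, x.tol = 1e-10)),
        error = function(e) NULL
      )
    })
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("all optimization starts failed; check the dataset and bounds",
         call. = FALSE)
  }
  fits <- fits[ok]
  losses <- vapply(fits, `[[`, numeric(1), "objective")
  best <- fits[[which.min(losses)]]
  starts_tbl <- tibble::tibble(
    start = seq_along(fits),
    loss = losses,
    converged = vapply(fits, function(f) f$convergence == 0, logical(1))
  )
  list(best = best, starts = starts_tbl)
}

#' Fit exit and NECT rates from a neutral (N2B27) time course
#'
#' Estimates `lambda_D` and `lambda_N` by bounded multi-start nonlinear
#' least squares on reporter-positive fractions from differentiation in a
#' non-PS-permissive medium, with the PS channel fixed closed
#' (`lambda_M = 0`), mirroring how these two rates are identified from
#' neutral differentiation alone. Starts are drawn log-uniformly from the
#' bounds; the best-loss solution wins.
#'
#' @inheritParams sse_loss
#' @param n_starts Number of random starts (default 20).
#' @param seed Integer seed making the multi-start draw reproducible.
#' @param lower,upper Named bounds for `lambda_D` and `lambda_N`, per day.
#' @return A `fate_fit` object; see [tidy.fate_fit()] and
#'   [glance.fate_fit()].
#' @examples
#' prm <- paper_like_params()
#' ds <- generate_neutral_dataset(prm, days = 0:5, noise = NULL)
#' fit <- fit_neutral(ds, seed = 1)
#' tidy(fit)
#' @export
fit_neutral <- function(dataset, protocols = NULL, n_starts = 20, seed = 1L,
                        lower = c(lambda_D = 1e-4, lambda_N = 1e-4),
                        upper = c(lambda_D = 10, lambda_N = 10),
                        weights = c("none", "binomial")) {
  weights <- match.arg(weights)
  assert_timecourse(dataset)
  protocols <- resolve_protocols(dataset, protocols)
  keep <- dataset$reporter %in% c("NECT", "pluripotency")
  if (!any(keep)) {
    stop("neutral fit needs NECT and/or pluripotency reporter records",
         call. = FALSE)
  }
  dataset <- dataset[keep, ]
  if (length(unique(dataset$time)) < 2L) {
    stop("unidentifiable design: need at least 2 distinct time points",
         call. = FALSE)
  }
  fixed <- list(lambda_M_low = 0, lambda_M_high = 0, theta = 1)
  bounds <- list(lambda_D = c(lower[["lambda_D"]], upper[["lambda_D"]]),
                 lambda_N = c(lower[["lambda_N"]], upper[["lambda_N"]]))
  objective <- function(x) {
    sse_loss(dataset, candidate = as.list(x), fixed = fixed,
             protocols = protocols, weights = weights)
  }
  res <- multistart_fit(objective, bounds, n_starts, seed)
  new_fate_fit(
    estimates = as.list(res$best$par),
    loss = res$best$objective, n_starts = n_starts,
    converged = any(res$starts$converged), bounds = bounds, seed = seed,
    fixed = fixed, method = "neutral", starts = res$starts
  )
}

#' Fit the PS switch parameters from pulse-chase endpoint data
#'
#' With `lambda_D` and `lambda_N` fixed (typically from [fit_neutral()]),
#' estimates the post-threshold PS conversion rate `lambda_M_high` and the
#' signal threshold `theta` from endpoint fate fractions across pulse days,
#' with `lambda_M_low` held at 0. The result is flagged
#' `regime_consistent` only when the recovered `lambda_M_high` exceeds the
#' fixed `lambda_N`, i.e. when the fit supports a switch to a
#' PS-dominated regime.
#'
#' @inheritParams fit_neutral
#' @param fixed Named list with `lambda_D` and `lambda_N` (and optionally
#'   `lambda_M_low`, default 0).
#' @param lower,upper Named bounds for `lambda_M_high` (per day) and
#'   `theta`.
#' @return A `fate_fit` object with an extra `regime_consistent` flag.
#' @examples
#' prm <- paper_like_params()
#' ds <- generate_pulse_chase_dataset(prm, pulse_chase_design(), noise = NULL)
#' fit <- fit_switch(ds, fixed = list(lambda_D = prm$lambda_D,
#'                                    lambda_N = prm$lambda_N), seed = 1)
#' glance(fit)
#' @export
fit_switch <- function(dataset, fixed, protocols = NULL, n_starts = 20,
                       seed = 1L,
                       lower = c(lambda_M_high = 1e-4, theta = 0.01),
                       upper = c(lambda_M_high = 10, theta = 0.99),
                       weights = c("none", "binomial")) {
  weights <- match.arg(weights)
  assert_timecourse(dataset)
  protocols <- resolve_protocols(dataset, protocols)
  if (!all(c("lambda_D", "lambda_N") %in% names(fixed))) {
    stop("`fixed` must supply lambda_D and lambda_N (from the neutral fit)",
         call. = FALSE)
  }
  ps <- dataset$reporter == "PS"
  if (any(ps) && all(dataset_fraction(dataset)[ps] == 0)) {
    stop("theta unidentifiable: every PS endpoint fraction is zero",
         call. = FALSE)
  }
  fixed <- utils::modifyList(list(lambda_M_low = 0), as.list(fixed))
  bounds <- list(
    lambda_M_high = c(lower[["lambda_M_high"]], upper[["lambda_M_high"]]),
    theta = c(lower[["theta"]], upper[["theta"]])
  )
  objective <- function(x) {
    sse_loss(dataset, candidate = as.list(x), fixed = fixed,
             protocols = protocols, weights = weights)
  }
  res <- multistart_fit(objective, bounds, n_starts, seed)
  est <- as.list(res$best$par)
  new_fate_fit(
    estimates = est, loss = res$best$objective, n_starts = n_starts,
    converged = any(res$starts$converged), bounds = bounds, seed = seed,
    fixed = fixed, method = "switch", starts = res$starts,
    extra = list(regime_consistent = est$lambda_M_high > fixed$lambda_N)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fate-model fit into one row per parameter
#'
#' @param x A `fate_fit` from [fit_neutral()] or [fit_switch()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `lower`, `upper`,
#'   `fixed`.
#' @export
tidy.fate_fit <- function(x, ...) {
  free <- tibble::tibble(
    term = names(x$estimates),
    estimate = unlist(x$estimates),
    lower = vapply(x$bounds, `[`, numeric(1), 1),
    upper = vapply(x$bounds, `[`, numeric(1), 2),
    fixed = FALSE
  )
  fx <- x$fixed[vapply(x$fixed, is.numeric, logical(1))]
  held <- tibble::tibble(
    term = names(fx), estimate = unlist(fx),
    lower = NA_real_, upper = NA_real_, fixed = TRUE
  )
  dplyr::bind_rows(free, held)
}

#' One-row summary of a fate-model fit
#'
#' @inheritParams tidy.fate_fit
#' @return A tibble with `method`, `loss`, `n_starts`, `n_starts_converged`,
#'   `converged`, `seed` and, for switch fits, `regime_consistent`.
#' @export
glance.fate_fit <- function(x, ...) {
  out <- tibble::tibble(
    method = x$method, loss = x$loss, n_starts = x$n_starts,
    n_starts_converged = sum(x$starts$converged),
    converged = x$converged, seed = x$seed
  )
  if (!is.null(x$regime_consistent)) out$regime_consistent <- x$regime_consistent
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
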