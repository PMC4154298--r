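test_that("condition registry resolves names and gating flags", {
  ac <- condition_from_name("AC")
  expect_true(ac$ps_permissive)
  expect_equal(ac$media_meta[[1]]$Activin, "100 ng/ml")
  expect_equal(ac$media_meta[[1]]$CHIR99021, "3 uM")
  expect_false(condition_from_name("N2B27")$ps_permissive)
  expect_error(condition_from_name("XYZ"), "known conditions.*N2B27.*AC")
  # user-extended registry
  reg <- dplyr::bind_rows(default_conditions(),
                          tibble::tibble(name = "AC+SB43", ps_permissive = TRUE,
                                         media_meta = list(list())))
  expect_true(condition_from_name("AC+SB43", reg)$ps_permissive)
})

test_that("pulse-chase designs expand into contiguous full-length protocols", {
  # pulse at day 0: leading background segment omitted
  p0 <- pulse_chase_protocols(pulse_chase_design(pulse_start_days = 0))[[1]]
  expect_equal(nrow(p0), 2L)
  expect_equal(p0$condition, c("AC", "N2B27"))
  expect_equal(p0$duration, c(1, 5))

  p2 <- pulse_chase_protocols(pulse_chase_design(pulse_start_days = 2))[[1]]
  expect_equal(p2$condition, c("N2B27", "AC", "N2B27"))
  expect_equal(p2$duration, c(2, 1, 3))

  protos <- pulse_chase_protocols(pulse_chase_design())
  expect_length(protos, 6L)
  expect_equal(names(protos), paste0("pulse_day_", 0:5))
  for (pr in protos) {
    expect_equal(sum(pr$duration), 6)
    expect_equal(pr$start, c(0, cumsum(pr$duration))[seq_len(nrow(pr))])
  }
  expect_error(pulse_chase_design(pulse_start_days = c(0, 6)), "fit inside")
  expect_error(pulse_chase_design(pulse_start_days = c(2, 1)), "sorted")
})

test_that("pulse-response tables conserve mass and follow the competence window", {
  prm <- rate_params(0.8, 0.55, 0, 8, 0.85)
  resp <- pulse_response(pulse_chase_design(), prm)
  expect_equal(resp$pulse_start_day, 0:5)
  expect_lt(max(abs(resp$n_final + resp$m_final + resp$uncommitted_final - 1)),
            1e-9)
  expect_true(all(unlist(resp[, -1]) >= 0 & unlist(resp[, -1]) <= 1))

  # PS channel closed: no PS anywhere
  resp0 <- pulse_response(pulse_chase_design(),
                          rate_params(0.8, 0.55, 0, 0, 0.5))
  expect_true(all(resp0$m_final == 0))

  # the PS peak sits at the first pulse day at/after the crossing time
  tc <- crossing_time(prm)
  first_day <- min(resp$pulse_start_day[resp$pulse_start_day >= floor(tc)])
  expect_equal(resp$pulse_start_day[which.max(resp$m_final)], first_day)

  # with an always-open threshold the PS response peaks as soon as the
  # differentiating pool has built up (day 0 or 1) and then declines as
  # NECT absorbs the remaining cells
  resp_open <- pulse_response(pulse_chase_design(),
                              rate_params(0.8, 0.55, 0, 8, theta = 0))
  peak_open <- which.max(resp_open$m_final)
  expect_lte(resp_open$pulse_start_day[peak_open], 1)
  expect_true(all(diff(resp_open$m_final[peak_open:6]) < 0))
  # each pulse's PS yield is bounded by the pool available when it starts
  avail <- vapply(0:5, function(day) {
    st <- simulate_fates(protocol("N2B27", 6), rate_params(0.8, 0.55),
                         times = max(day, 1e-9))
    st$p + st$d
  }, numeric(1))
  expect_true(all(resp_open$m_final <= avail + 1e-9))
})

test_that("fate correlation behaves as the Pearson statistic with guards", {
  tb <- tibble::tibble(n_final = c(1, 2, 3, 4) / 10,
                       m_final = c(4, 3, 2, 1) / 10)
  expect_equal(fate_correlation(tb), -1)
  tb2 <- tibble::tibble(n_final = 1:3 / 10, m_final = 1:3 / 10)
  expect_equal(fate_correlation(tb2), 1)
  expect_error(fate_correlation(tibble::tibble(n_final = 1:2, m_final = 2:1)),
               "at least 3")
  expect_error(
    fate_correlation(tibble::tibble(n_final = 1:3 / 10, m_final = c(0, 0, 0))),
    "zero variance")
})
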