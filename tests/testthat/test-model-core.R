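test_that("right-hand side computes the linear fluxes and conserves total mass", {
  r <- list(lambda_D = 1, lambda_N = 0.5, lambda_M = 0)
  expect_equal(unname(fate_rhs(population_state(), r)), c(-1, 1, 0, 0))
  r2 <- list(lambda_D = 1, lambda_N = 0.5, lambda_M = 2)
  expect_equal(unname(fate_rhs(population_state(0, 1, 0, 0), r2)),
               c(0, -2.5, 0.5, 2))
  expect_equal(unname(fate_rhs(population_state(0.3, 0.3, 0.2, 0.2),
                               list(lambda_D = 0, lambda_N = 0, lambda_M = 0))),
               c(0, 0, 0, 0))
  withr::with_seed(11, {
    for (i in 1:25) {
      s <- stats::runif(4); s <- s / sum(s)
      st <- population_state(s[1], s[2], s[3], s[4])
      reg <- list(lambda_D = stats::runif(1, 0, 5), lambda_N = stats::runif(1, 0, 5),
                  lambda_M = stats::runif(1, 0, 5))
      expect_lt(abs(sum(fate_rhs(st, reg))), 1e-12)
    }
  })
  expect_error(fate_rhs(population_state(), list(lambda_D = -1, lambda_N = 0,
                                                 lambda_M = 0)),
               "rates")
  expect_error(fate_rhs(c(0.5, 0.5, 0.5, 0.5), r), "sum to 1")
})

test_that("constant-rate segment solution matches adaptive numerical integration", {
  # frozen values verified against the lsoda oracle
  s1 <- solve_segment(population_state(),
                      list(lambda_D = 1, lambda_N = 0.5, lambda_M = 0), dt = 1)
  expect_equal(unname(unclass(s1)), c(0.367879, 0.477303, 0.154818, 0),
               tolerance = 1e-5)
  # degenerate branch Lambda == lambda_D
  s2 <- solve_segment(population_state(),
                      list(lambda_D = 1, lambda_N = 1, lambda_M = 0), dt = 1)
  expect_equal(unname(unclass(s2)), c(0.367879, 0.367879, 0.264241, 0),
               tolerance = 1e-5)
  # identity at dt = 0
  st <- population_state(0.4, 0.3, 0.2, 0.1)
  expect_equal(unclass(solve_segment(st, list(lambda_D = 2, lambda_N = 1,
                                              lambda_M = 3), 0)),
               unclass(st))
  expect_error(solve_segment(st, list(lambda_D = 1, lambda_N = 1, lambda_M = 1),
                             -0.1), "dt")
  # randomized closed-form vs numerical-oracle agreement
  withr::with_seed(21, {
    for (i in 1:30) {
      s <- stats::runif(4); s <- s / sum(s)
      st <- population_state(s[1], s[2], s[3], s[4])
      reg <- list(lambda_D = stats::runif(1, 0, 4), lambda_N = stats::runif(1, 0, 4),
                  lambda_M = stats::runif(1, 0, 4))
      dt <- stats::runif(1, 0, 3)
      got <- unclass(solve_segment(st, reg, dt))
      want <- ode_segment_oracle(unclass(st), reg, dt)
      expect_lt(max(abs(got - want)), 1e-8)
      expect_lt(abs(sum(got) - 1), 1e-9)
    }
  })
})

test_that("degenerate-rate branch is continuous across the confluence", {
  st <- population_state()
  lD <- 1.3
  exact_deg <- solve_segment(st, list(lambda_D = lD, lambda_N = lD, lambda_M = 0), 2)
  near <- solve_segment(st, list(lambda_D = lD, lambda_N = lD + 1e-10,
                                 lambda_M = 0), 2)
  expect_lt(max(abs(unclass(exact_deg) - unclass(near))), 1e-6)
})

test_that("signal law and threshold-crossing time match their closed forms", {
  prm <- rate_params(log(2), 0.5, theta = 0.5)
  s0 <- signal_level(prm, 0)
  expect_equal(s0$s, 0)
  expect_false(s0$crossed)
  expect_equal(signal_level(prm, 1)$s, 0.5, tolerance = 1e-9)
  expect_error(signal_level(prm, -1), "non-negative")

  # lambda_D = 0: no differentiation, no signal, no crossing
  prm0 <- rate_params(0, 0.5, theta = 0.5)
  expect_equal(signal_level(prm0, c(0, 5, 50))$s, c(0, 0, 0))
  expect_equal(crossing_time(prm0), Inf)

  # closed form vs bisection oracle
  expect_equal(crossing_time(prm), 1, tolerance = 1e-8)
  prm75 <- rate_params(log(2), 0.5, theta = 0.75)
  expect_equal(crossing_time(prm75), 2, tolerance = 1e-8)
  withr::with_seed(31, {
    for (i in 1:10) {
      p <- random_params()
      tc <- crossing_time(p)
      expect_equal(tc, bisect_crossing(p), tolerance = 1e-8)
    }
  })
  # boundary thresholds
  expect_equal(crossing_time(rate_params(1, 1, theta = 0)), 0)
  expect_equal(crossing_time(rate_params(1, 1, theta = 1)), Inf)

  # signal monotone nondecreasing, cumulative law included
  for (law in c("instantaneous", "cumulative")) {
    p <- rate_params(0.7, 0.5, theta = 0.6, signal_law = law)
    s <- signal_level(p, seq(0, 8, by = 0.1))$s
    expect_true(all(diff(s) >= -1e-12))
    expect_equal(crossing_time(p), bisect_crossing(p), tolerance = 1e-8)
  }
})

test_that("piecewise protocol solution agrees with the adaptive ODE oracle", {
  tt <- seq(0, 6, by = 0.25)
  prm <- rate_params(1, 0.5, 0, 5, 0.8)
  for (pr in list(protocol("AC", 6),
                  protocol(c("N2B27", "AC", "N2B27"), c(2, 1, 3)),
                  protocol(c("AC", "N2B27"), c(3, 3)))) {
    a <- simulate_fates(pr, prm, times = tt)
    b <- simulate_fates_ode(pr, prm, times = tt)
    expect_lt(max(abs(state_matrix(a) - state_matrix(b))), 1e-6)
    expect_lt(max(abs(rowSums(state_matrix(a)) - 1)), 1e-9)
  }
  # single constant-rate protocol endpoint matches solve_segment
  end <- simulate_fates(protocol("AC", 2),
                        rate_params(1, 0.5, 0.3, 5, 0), times = 2)
  seg <- solve_segment(population_state(),
                       list(lambda_D = 1, lambda_N = 0.5, lambda_M = 5), 2)
  expect_lt(max(abs(unlist(end[, c("p", "d", "n", "m")]) - unclass(seg))), 1e-8)
})

test_that("PS conversion is disabled off-permissive media and during pre-crossing pulses", {
  prm <- rate_params(1, 0.5, lambda_M_low = 2, lambda_M_high = 2, theta = 0.5)
  traj <- simulate_fates(protocol("N2B27", 6), prm)
  expect_true(all(traj$m == 0))
  expect_true(all(grepl("N2B27", traj$regime_label)))

  # a pulse confined to the pre-crossing window only opens lambda_M_low
  prm2 <- rate_params(0.8, 0.55, 0, 8, 0.85)   # crossing ~2.37 d
  pulse2 <- simulate_fates(protocol(c("N2B27", "AC", "N2B27"), c(2, 1, 3)), prm2)
  gains <- diff(pulse2$m)
  in_pulse <- pulse2$time[-1] > 2 & pulse2$time[-1] <= 3
  expect_true(all(gains[!in_pulse] < 1e-12))
  expect_gt(max(gains[in_pulse]), 0)
})

test_that("simulation rejects malformed grids and protocols", {
  prm <- rate_params(1, 0.5, 0, 5, 0.8)
  pr <- protocol("N2B27", 6)
  expect_error(simulate_fates(pr, prm, times = c(0, 7)), "span")
  expect_error(simulate_fates(pr, prm, times = numeric(0)), "grid")
  expect_error(protocol(character(0), numeric(0)), "segment")
  expect_error(protocol("N2B27", 0), "positive")
})

test_that("conservation and monotonicity hold over random parameters and protocols", {
  withr::with_seed(41, {
    for (i in 1:20) {
      prm <- random_params()
      pr <- random_protocol()
      tt <- seq(0, protocol_span_of(pr), length.out = 40)
      traj <- simulate_fates(pr, prm, times = tt)
      expect_lt(max(abs(rowSums(state_matrix(traj)) - 1)), 1e-9)
      expect_true(all(diff(traj$p) <= 1e-12))
      expect_true(all(diff(traj$n) >= -1e-12))
      expect_true(all(diff(traj$m) >= -1e-12))
      expect_true(all(diff(traj$signal) >= -1e-12))
    }
  })
})

test_that("with the PS channel closed everywhere, all cells end up NECT", {
  prm <- rate_params(1.5, 2, 0, 0, 1)
  traj <- simulate_fates(protocol("N2B27", 40), prm, times = c(0, 20, 40))
  expect_true(all(traj$m == 0))
  expect_gt(traj$n[3], 1 - 1e-9)
})

test_that("an overwhelming PS pulse converts the whole uncommitted pool", {
  # for a post-crossing pulse [t0, t0+w] with lambda_M_high -> Inf, the PS
  # gain tends to d(t0) + p(t0) (1 - exp(-lambda_D w))
  lD <- 0.8; w <- 1; t0 <- 3
  prm <- rate_params(lD, 0.55, 0, 1e4, 0.85)    # crossing ~2.37 < t0
  pre <- simulate_fates(protocol("N2B27", t0), prm, times = t0)
  pulse <- simulate_fates(protocol(c("N2B27", "AC", "N2B27"), c(t0, w, 2)), prm,
                          times = c(t0, t0 + w))
  gain <- pulse$m[2] - pulse$m[1]
  limit <- pre$d + pre$p * (1 - exp(-lD * w))
  expect_equal(gain, limit, tolerance = 1e-3)
})
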