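prm <- paper_like_params()

test_that("flow-readout sampling follows the misclassification-binomial law", {
  pure <- noise_model(n_sampled = 100, eps_fp = 0, eps_fn = 0)
  withr::with_seed(1, {
    expect_equal(sample_flow_readout(0, pure), 0L)
    expect_equal(sample_flow_readout(1, pure), 100L)
  })
  expect_error(sample_flow_readout(1.2, pure), "\\[0, 1\\]")
  # binomial moments at f = 0.5, n = 10000 over many draws
  nm <- noise_model(n_sampled = 10000, eps_fp = 0, eps_fn = 0)
  draws <- withr::with_seed(2, sample_flow_readout(rep(0.5, 1000), nm))
  expect_lt(abs(mean(draws) - 5000), 3 * sqrt(10000 * 0.25) / sqrt(1000) * 3 + 3)
  expect_lt(abs(stats::sd(draws) - sqrt(10000 * 0.25)) / sqrt(10000 * 0.25), 0.15)
  # misclassification shifts the observed probability: q = f(1-fn) + (1-f)fp
  nm2 <- noise_model(n_sampled = 50000, eps_fp = 0.02, eps_fn = 0.1)
  d2 <- withr::with_seed(3, sample_flow_readout(rep(0.4, 400), nm2))
  q <- 0.4 * 0.9 + 0.6 * 0.02
  expect_lt(abs(mean(d2) / 50000 - q), 3 * sqrt(q * (1 - q) / 50000 / 400))
})

test_that("noiseless datasets reproduce the deterministic fractions exactly", {
  ds <- generate_neutral_dataset(prm, days = 0:5, noise = NULL)
  det <- simulate_fates(protocol("N2B27", 5), prm, times = 0:5)
  expect_equal(ds$fraction[ds$reporter == "NECT"], det$n)
  expect_equal(ds$fraction[ds$reporter == "pluripotency"], det$p)
  expect_true(all(is.na(ds$positive_count)))

  dsp <- generate_pulse_chase_dataset(prm, pulse_chase_design(), noise = NULL)
  resp <- pulse_response(pulse_chase_design(), prm)
  expect_equal(dsp$fraction[dsp$reporter == "PS"], resp$m_final)
  # PS endpoint response is unimodal in pulse day: one sign change in the
  # first difference
  ps <- dsp$fraction[dsp$reporter == "PS"]
  signs <- sign(diff(ps))
  expect_lte(sum(diff(signs[signs != 0]) != 0), 1)
})

test_that("generated datasets validate, are seed-deterministic, and honour the noise law", {
  noise <- noise_model(n_sampled = 5000, seed = 9L)
  ds <- generate_neutral_dataset(prm, days = 0:5, noise = noise)
  expect_s3_class(ds, "timecourse_dataset")
  expect_true(all(ds$positive_count <= ds$total_count))
  expect_true(all(ds$positive_count >= 0))

  # same seed: byte-identical CSV; different seed: different draws
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_timecourse(ds, p1)
  write_timecourse(generate_neutral_dataset(prm, days = 0:5, noise = noise), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  ds3 <- generate_neutral_dataset(prm, days = 0:5,
                                  noise = noise_model(n_sampled = 5000), seed = 10)
  expect_false(identical(ds$positive_count, ds3$positive_count))

  # PS channel closed + no false positives -> all PS counts are zero
  clean <- noise_model(n_sampled = 2000, eps_fp = 0, eps_fn = 0, seed = 4L)
  flat <- generate_pulse_chase_dataset(rate_params(0.8, 0.55, 0, 0, 0.85),
                                       pulse_chase_design(), noise = clean)
  expect_true(all(flat$positive_count[flat$reporter == "PS"] == 0L))
})

test_that("synthetic data round-trips through both fitters", {
  ds <- generate_neutral_dataset(prm, days = 0:5, noise = NULL)
  fit <- fit_neutral(ds, seed = 1)
  expect_lt(abs(fit$estimates$lambda_D - prm$lambda_D) / prm$lambda_D, 1e-3)
  expect_lt(abs(fit$estimates$lambda_N - prm$lambda_N) / prm$lambda_N, 1e-3)

  # moderate binomial noise: single-seed recovery within 10%
  ds2 <- generate_neutral_dataset(prm, days = 0:5,
                                  noise = noise_model(n_sampled = 10000,
                                                      eps_fp = 0, eps_fn = 0,
                                                      seed = 21L))
  fit2 <- fit_neutral(ds2, seed = 1)
  expect_lt(abs(fit2$estimates$lambda_D - prm$lambda_D) / prm$lambda_D, 0.1)
  expect_lt(abs(fit2$estimates$lambda_N - prm$lambda_N) / prm$lambda_N, 0.1)
})

test_that("the calibrated defaults satisfy their documented constraints", {
  p <- paper_like_params()
  expect_gte(simulate_fates(protocol("N2B27", 5), p, times = 5)$n, 0.70)
  expect_lte(simulate_fates(protocol("N2B27", 5), p, times = 5)$n, 0.90)
  tc <- crossing_time(p)
  expect_gte(tc, 2); expect_lte(tc, 3)
  expect_gte(p$lambda_M_high, 10 * p$lambda_N)
  resp <- pulse_response(pulse_chase_design(), p)
  expect_true(resp$pulse_start_day[which.max(resp$m_final)] %in% c(2, 3))
  expect_lt(fate_correlation(resp), -0.9)
})
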