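# Latency, response frequency, kinetics.

test_that("noiseless latency is recovered within one sample period", {
  dt <- 1000 / 40000
  for (lat in c(0.5, 0.8, 1.3, 2.0)) {
    tr <- make_trace(trace_params(true_latency_ms = lat,
                                  baseline_noise_sd_mv = 0))
    r <- detect_latency(tr)
    expect_lt(abs(r$mean_latency_ms - lat), dt)
  }
})

test_that("absent EPSP is a flagged failure, not an error", {
  tr <- make_trace(trace_params(epsp_amplitude_mv = 0, seed = 1))
  r <- detect_latency(tr)
  expect_false(r$per_stimulus$responded)
  expect_true(is.na(r$mean_latency_ms))
  expect_equal(r$response_probability, 0)
})

test_that("no artifact is an error; repeated stimuli give mean and sd", {
  flat <- list(time_ms = seq(0, 40, by = 0.025),
               voltage_mv = rep(-70, 1601) + rnorm(1601, 0, 0.1),
               sampling_rate_hz = 40000, stim_times_ms = 10)
  expect_error(detect_latency(flat), "no stimulation artifact")
  tr <- make_trace(trace_params(duration_ms = 320,
                                stim_times_ms = c(20, 80, 140, 200, 260),
                                true_latency_ms = 1.1,
                                epsp_decay_tau_ms = 8,
                                baseline_noise_sd_mv = 0))
  r <- detect_latency(tr)
  expect_equal(r$n_responses, 5L)
  expect_equal(r$mean_latency_ms, 1.1, tolerance = 0.025)
  expect_lt(r$sd_latency_ms, 0.025)
})

test_that("latency is invariant to a constant voltage offset", {
  tr <- make_trace(trace_params(true_latency_ms = 1.4, seed = 5))
  r1 <- detect_latency(tr)
  tr$voltage_mv <- tr$voltage_mv + 37.5
  r2 <- detect_latency(tr)
  # invariant up to optimizer tolerance (well below a tenth of a sample)
  expect_equal(r1$mean_latency_ms, r2$mean_latency_ms, tolerance = 1e-3)
})

test_that("latency estimator is unbiased across SNR >= 5", {
  # mean signed error < 1 sample over 100 seeds per SNR level
  dt <- 1000 / 40000
  for (noise in c(3, 1)) {              # SNR 5 and 15 at 15 mV EPSPs
    errs <- vapply(1:100, function(i) {
      lat <- 0.5 + 1.5 * (i - 1) / 99
      tr <- make_trace(trace_params(true_latency_ms = lat,
                                    baseline_noise_sd_mv = noise,
                                    seed = 7000 + i + 1000 * noise))
      detect_latency(tr)$mean_latency_ms - lat
    }, numeric(1))
    expect_lt(abs(mean(errs)), dt)
  }
})

test_that("response frequency counts events and validates the window", {
  quiet <- make_event_trace(numeric(0), duration_ms = 5200, seed = 1)
  expect_equal(as.numeric(response_frequency(quiet, window_s = 5)), 0)
  # 79 events in 5 s -> 15.8 Hz (count / window arithmetic)
  set.seed(9)
  times <- sort(runif(79, 50, 4900))
  times <- times[c(TRUE, diff(times) > 25)]
  while (length(times) < 79) {
    cand <- runif(1, 50, 4900)
    if (all(abs(times - cand) > 25)) times <- sort(c(times, cand))
  }
  tr <- make_event_trace(times, duration_ms = 5200, seed = 2)
  f <- response_frequency(tr, window_s = 5)
  expect_equal(as.numeric(f), 79 / 5)
  expect_equal(attr(f, "n_events"), 79L)
  expect_error(response_frequency(tr, window_s = 10), "exceeds trace")
})

test_that("frequency is invariant to voltage rescaling with relative criterion", {
  tr <- make_event_trace(c(500, 1500, 2500, 3800), duration_ms = 5100,
                         seed = 3)
  f1 <- as.numeric(response_frequency(tr, window_s = 5))
  tr$voltage_mv <- tr$voltage_mv * 4.2
  f2 <- as.numeric(response_frequency(tr, window_s = 5))
  expect_equal(f1, f2)
})

test_that("kinetic slope equals the closed-form OLS estimate exactly", {
  s <- make_kinetic_series(5, 3)
  fit <- proteasome_slope(s)
  expect_equal(fit$slope, 3, tolerance = 1e-12)
  expect_equal(fit$intercept, 5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # constant series
  s0 <- data.frame(time_min = 0:5, fluorescence = rep(2, 6))
  expect_equal(proteasome_slope(s0)$slope, 0)
  # any noisy fixture: slope identical to the closed-form formula
  sn <- make_kinetic_series(5, 3, noise_sd = 0.5, seed = 77)
  fitn <- proteasome_slope(sn)
  t <- sn$time_min; y <- sn$fluorescence
  beta <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  expect_equal(fitn$slope, beta, tolerance = 1e-12)
  expect_error(proteasome_slope(data.frame(time_min = 1:2,
                                           fluorescence = 1:2)),
               "3 points")
})
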