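test_that("subthreshold traces contain no spikes", {
  tr <- tibble::tibble(time_s = seq(0, 0.1, by = 2e-5),
                       v_mV = -70 + 5 * sin(2 * pi * 10 * seq(0, 0.1, by = 2e-5)))
  expect_equal(nrow(detect_spikes(tr)), 0)
})

test_that("threshold time is interpolated exactly for an analytic upstroke", {
  # quadratic voltage: dV/dt grows linearly, so central differences are
  # exact and the 10 mV/ms crossing time has a closed form t* = 10/a
  fs <- 50000
  t <- seq(0, 0.01, by = 1 / fs)
  a <- 2500  # mV/ms per s
  v <- -70 + 0.5 * a * 1000 * t^2   # dV/dt in mV/ms = a * t
  tr <- tibble::tibble(time_s = t, v_mV = v)
  st <- detect_spikes(tr)
  expect_equal(nrow(st), 1)
  expect_equal(st$t_s, 10 / a, tolerance = 1e-9)
  expect_equal(st$v_threshold_mV, -70 + 0.5 * a * 1000 * (10 / a)^2,
               tolerance = 1e-4)
})

test_that("coarse sampling is rejected", {
  tr <- tibble::tibble(time_s = seq(0, 1, by = 1e-3), v_mV = -70)
  expect_error(detect_spikes(tr), "coarse")
})

test_that("firing-pattern formulas are evaluated exactly", {
  fp <- firing_pattern(c(0, 6.024e-3, 12.892e-3))
  expect_equal(fp$IF1_Hz, 166, tolerance = 1e-4)
  expect_equal(fp$CFAd, 1.14, tolerance = 1e-3)
  expect_equal(fp$CSAd, fp$CFAd)   # last ISI is the second ISI here
  # uniform train: both adaptation coefficients are 1
  u <- firing_pattern(seq(0, 0.09, by = 0.01))
  expect_equal(u$CFAd, 1)
  expect_equal(u$CSAd, 1)
  # time rescaling halves IF1 and leaves the ratios unchanged
  tr <- gen_spike_train(100, 1.3, 2.1, 8)
  f1 <- firing_pattern(tr)
  f2 <- firing_pattern(tr * 2)
  expect_equal(f2$IF1_Hz, f1$IF1_Hz / 2)
  expect_equal(f2$CFAd, f1$CFAd)
  expect_equal(f2$CSAd, f1$CSAd)
  expect_error(firing_pattern(c(0)), "two spikes")
  expect_warning(firing_pattern(c(0, 0.01)), "fewer than three")
})

test_that("half-maximal-rate selection picks the nearest step, ties low", {
  mk <- function(rates) {
    gen_step_series("current", levels = seq_along(rates) * 50,
                    rates_Hz = rates)
  }
  expect_equal(select_half_max_train(mk(c(0, 10, 20, 40)))$rate_Hz, 20)
  # half of 40 is 20: |12-20| = 8 beats |30-20| = 10
  expect_equal(select_half_max_train(mk(c(0, 12, 30, 40)))$rate_Hz, 12)
  # the rule uses the series' own maximum (~25 -> target ~12.5 -> the
  # lower step, at level 50)
  expect_equal(select_half_max_train(mk(c(15, 25)))$level, 50)
  expect_error(select_half_max_train(mk(c(0, 0))), "no step")
})

test_that("waveform features are exact for a triangular spike", {
  fs <- 1e5
  t <- seq(0, 0.02, by = 1 / fs)
  v <- rep(0, length(t))
  ris <- t >= 0.010 & t < 0.0105
  fal <- t >= 0.0105 & t < 0.011
  v[ris] <- 80 * (t[ris] - 0.010) / 5e-4
  v[fal] <- 80 * (1 - (t[fal] - 0.0105) / 5e-4)
  tr <- tibble::tibble(time_s = t, v_mV = v)
  train <- tibble::tibble(t_s = 0.010, v_threshold_mV = 0,
                          t_peak_s = 0.0105, v_peak_mV = 80)
  f <- waveform_features(tr, train)
  expect_equal(f$APA_mV, 80)
  expect_equal(f$APD_ms, 0.5, tolerance = 1e-3)
  expect_equal(f$AHP_mV, 0)  # no undershoot below threshold
})

test_that("noise-free rendering round-trips every metric below 1%", {
  for (set in c("fast_spiking", "pyramidal")) {
    wf <- generator_defaults()[[set]]
    train <- gen_spike_train(wf$IF1_Hz, wf$CFAd, wf$CSAd, 10, t0 = 0.02)
    tr <- render_voltage_trace(train, wf, fs = 1e5)
    st <- detect_spikes(tr)
    expect_equal(nrow(st), 10)
    expect_true(max(abs(st$t_s - train)) < 1e-4)
    fp <- firing_pattern(st)
    ft <- waveform_features(tr, st, 1)
    got <- c(fp$IF1_Hz, fp$CFAd, fp$CSAd, ft$APA_mV, ft$APD_ms, ft$AHP_mV)
    want <- c(wf$IF1_Hz, wf$CFAd, wf$CSAd, wf$APA_mV, wf$APD_ms, wf$AHP_mV)
    expect_true(all(abs(got - want) / want < 0.01),
                label = paste(set, "round-trip <1%"))
  }
})

test_that("spike detection equals the brute-force all-samples scan", {
  wf <- generator_defaults()$fast_spiking
  train <- gen_spike_train(120, 1.2, 1.8, 6, t0 = 0.02)
  tr <- render_voltage_trace(train, wf, fs = 50000)
  st <- detect_spikes(tr)
  oracle <- brute_force_spike_scan(tr$time_s, tr$v_mV)
  expect_equal(length(oracle), nrow(st))
  expect_equal(st$t_s, oracle, tolerance = 1e-9)
})

test_that("metrics are shift-equivariant in voltage", {
  wf <- generator_defaults()$pyramidal
  train <- gen_spike_train(wf$IF1_Hz, wf$CFAd, wf$CSAd, 6, t0 = 0.02)
  tr <- render_voltage_trace(train, wf, fs = 50000)
  tr2 <- dplyr::mutate(tr, v_mV = v_mV + 12)
  s1 <- detect_spikes(tr)
  s2 <- detect_spikes(tr2)
  expect_equal(s2$t_s, s1$t_s)
  expect_equal(s2$v_threshold_mV, s1$v_threshold_mV + 12)
  f1 <- waveform_features(tr, s1)
  f2 <- waveform_features(tr2, s2)
  expect_equal(f2$APA_mV, f1$APA_mV)
  expect_equal(f2$APD_ms, f1$APD_ms)
  expect_equal(f2$AHP_mV, f1$AHP_mV)
})

test_that("light thresholds recover the configured intensities", {
  ss <- gen_step_series("light")
  th <- light_thresholds(ss)
  expect_equal(th$depolarization_threshold, 0.41)
  expect_equal(th$spiking_threshold, 0.68)
  # flat series: neither threshold is reached
  flat <- gen_step_series("light", levels = c(0.1, 0.2, 0.3))
  th0 <- light_thresholds(flat)
  expect_true(is.na(th0$depolarization_threshold))
  expect_true(is.na(th0$spiking_threshold))
})

test_that("archaerhodopsin hyperpolarization peaks at the configured level", {
  sa <- gen_step_series("arch")
  m <- max_hyperpolarization(sa)
  expect_equal(m$max_hyperpolarization_mV, 10.1, tolerance = 1e-6)
  expect_equal(m$level_at_max, 48)
  # monotone saturating series: maximum at the highest level
  m2 <- max_hyperpolarization(gen_step_series("arch", levels = c(8, 18, 28)))
  expect_equal(m2$level_at_max, 28)
})
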