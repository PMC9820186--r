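test_that("generated spike trains invert the firing-pattern formulas", {
  t1 <- gen_spike_train(100, 1, 1, 10)
  expect_equal(diff(t1), rep(0.01, 9))
  fp <- firing_pattern(gen_spike_train(166, 1.14, 1.40, 10))
  expect_equal(fp$IF1_Hz, 166)
  expect_equal(fp$CFAd, 1.14)
  expect_equal(fp$CSAd, 1.40)
  # shifting the origin shifts every spike time
  expect_equal(gen_spike_train(50, 2, 3, 6, t0 = 1.5),
               gen_spike_train(50, 2, 3, 6) + 1.5)
  # decelerating-then-accelerating trains are allowed for n > 3
  expect_silent(gen_spike_train(100, 2, 1.2, 8))
  expect_error(gen_spike_train(100, 1.2, 1.4, 2), "at least 3")
  expect_error(gen_spike_train(100, 1.2, 1.4, 3), "must equal")
})

test_that("voltage rendering is seeded and degrades gracefully", {
  train <- gen_spike_train(80, 1.3, 2, 5, t0 = 0.02)
  a <- render_voltage_trace(train, noise_sd = 0.2, seed = 4)
  b <- render_voltage_trace(train, noise_sd = 0.2, seed = 4)
  expect_identical(a, b)
  empty <- render_voltage_trace(numeric(0), noise_sd = 0, duration = 0.1)
  expect_equal(unique(empty$v_mV), -70)
  # spikes packed tighter than the waveform support are rejected
  expect_error(render_voltage_trace(c(0.02, 0.0205),
                                    generator_defaults()$pyramidal),
               "support")
})

test_that("empty schedules produce event-free traces", {
  sch <- event_schedule(character(), numeric(), numeric())
  tr <- gen_discharge_trace(sch, fs = 500, duration = 80, seed = 1)
  ev <- detect_discharges(tr, "i_pA", detection_params())
  expect_equal(nrow(ev), 0)
})

test_that("a 0.2 Hz interictal train is detected one for one", {
  n <- 70
  sch <- event_schedule(rep("interictal", n), 20 + 5 * (0:(n - 1)),
                        rep(0.3, n), amplitude = 100)
  tr <- gen_discharge_trace(sch, fs = 500, seed = 6)
  ev <- detect_discharges(tr, "i_pA", detection_params())
  expect_equal(sum(ev$class == "interictal"), n)
  expect_equal(sum(ev$class == "ictal"), 0)
  # smoothing can pull the first detected onset slightly before the
  # scheduled time, so pad the summary window by a second
  s <- regime_summary(ev, c(19, 20 + 350))
  expect_equal(s$n_interictal, n)
  expect_equal(s$regime, "interictal")
})

test_that("schedules must not overlap and classes bound durations", {
  expect_error(event_schedule(c("ictal", "interictal"), c(0, 30), c(56, 0.3)),
               "overlap")
  expect_error(event_schedule("ictal", 0, 5), "ictal")
  expect_error(event_schedule("interictal", 0, 5), "ictal")
})

test_that("electrode traces encode the schedule through the electrode law", {
  kd <- generator_defaults()$k_transients
  cal <- k_calibration()
  sch <- event_schedule(character(), numeric(), numeric())
  tr <- gen_electrode_trace(sch, kd, fs = 20, duration = 30, noise_sd = 0,
                            seed = 1)
  expect_equal(unique(round(tr$voltage_mV, 10)),
               round(k_conc_to_voltage(kd$bath_mM, cal), 10))
  bad <- modifyList(kd, list(bath_mM = 0.1))
  sch2 <- event_schedule("interictal", 5, 0.3, amplitude = -5)
  expect_error(gen_electrode_trace(sch2, bad, fs = 20, duration = 20,
                                   noise_sd = 0, seed = 1),
               "non-positive")
})

test_that("the potassium pipeline recovers scheduled transient amplitudes", {
  kd <- generator_defaults()$k_transients
  sch <- event_schedule("ictal", 60, 56, amplitude = kd$ictal_rise_mM)
  tr <- gen_electrode_trace(sch, kd, fs = 100, noise_sd = 0.02, seed = 3)
  conc <- tibble::tibble(time_s = tr$time_s,
                         conc_mM = k_voltage_to_conc(tr$voltage_mV))
  st <- k_transient_stats(conc, tibble::tibble(onset_s = 60, offset_s = 116,
                                               class = "ictal"))
  expect_equal(st$per_event$rise_mM, 4.8, tolerance = 0.1 / 4.8)
})

test_that("dose-response generation is seeded Bernoulli sampling", {
  a <- gen_dose_response(n_slices = 2, n_per_li = 5, seed = 8)
  b <- gen_dose_response(n_slices = 2, n_per_li = 5, seed = 8)
  expect_identical(a, b)
  # near-step curve: outcomes deterministic by side of the midpoint
  d <- gen_dose_response(li_grid = c(0.35, 0.45), LI0 = 0.40, Delta = 1e-6,
                         n_per_li = 20, n_slices = 1,
                         slice_midpoint_sd = 0, seed = 9)
  expect_equal(unique(d$outcome[d$li_percent < 0.4]), 0)
  expect_equal(unique(d$outcome[d$li_percent > 0.4]), 1)
  # empirical mean at the midpoint approaches 1/2
  m <- gen_dose_response(li_grid = 0.40, LI0 = 0.40, Delta = 0.007,
                         n_per_li = 4000, n_slices = 1,
                         slice_midpoint_sd = 0, seed = 10)
  se <- sqrt(0.25 / 4000)
  expect_lt(abs(mean(m$outcome) - 0.5), 4 * se)
})

test_that("step series without stimulation effects yield no thresholds", {
  quiet <- modifyList(generator_defaults(),
                      list(light_thresholds = list(depolarization = 5,
                                                   spiking = 9)))
  ss <- gen_step_series("light", levels = seq(0.1, 1, by = 0.1),
                        defaults = quiet)
  th <- light_thresholds(ss)
  expect_true(is.na(th$depolarization_threshold))
  expect_true(is.na(th$spiking_threshold))
})
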