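test_that("electrode law conversions are exact inverses", {
  cal <- k_calibration()
  expect_identical(k_voltage_to_conc(0, cal), 2.5)
  expect_equal(k_voltage_to_conc(log(2) / 0.044, cal), 5.0)
  expect_equal(k_conc_to_voltage(2.5 * exp(1), cal), 1 / 0.044)
  v <- seq(-40, 60, by = 0.5)
  expect_equal(k_conc_to_voltage(k_voltage_to_conc(v, cal), cal), v,
               tolerance = 1e-12)
  expect_true(all(diff(k_voltage_to_conc(v, cal)) > 0))
  expect_error(k_conc_to_voltage(-1, cal), class = "ictalsim_domain_error")
})

test_that("noise-free calibration recovers the scaling factor exactly", {
  cal <- k_calibration(S = 0.044)
  conc <- c(2.5, 4, 6, 8, 10, 12)
  set_ <- tibble::tibble(conc_mM = conc,
                         voltage_mV = k_conc_to_voltage(conc, cal))
  fit <- calibrate_k_sensor(set_)
  expect_equal(fit$S, 0.044, tolerance = 1e-12)
  expect_lt(fit$residual_sd, 1e-12)
  # two-point closed form
  two <- tibble::tibble(conc_mM = c(2.5, 5.0), voltage_mV = c(0, 15.753))
  expect_equal(calibrate_k_sensor(two)$S, log(2) / 15.753, tolerance = 1e-9)
  expect_equal(calibrate_k_sensor(two)$S, 0.044, tolerance = 1e-4)
  expect_error(calibrate_k_sensor(two[1, ]), "two distinct")
  same <- tibble::tibble(conc_mM = c(2.5, 5), voltage_mV = c(3, 3))
  expect_error(calibrate_k_sensor(same), "singular")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n, 6)
})

test_that("calibration is unbiased under voltage noise", {
  cal <- k_calibration(S = 0.044)
  conc <- c(2.5, 4, 6, 8, 10, 12)
  v0 <- k_conc_to_voltage(conc, cal)
  set.seed(99)
  est <- replicate(200, {
    calibrate_k_sensor(tibble::tibble(
      conc_mM = conc, voltage_mV = v0 + rnorm(6, 0, 0.5)
    ))$S
  })
  expect_lt(abs(mean(est) - 0.044), 0.001)
})

test_that("transient statistics are zero on a constant trace", {
  tr <- tibble::tibble(time_s = seq(0, 600, by = 0.01), conc_mM = 3.5)
  ev <- tibble::tibble(onset_s = c(100, 200), offset_s = c(100.3, 256),
                       class = c("interictal", "ictal"))
  st <- k_transient_stats(tr, ev, stim_window = c(80, 400))
  expect_equal(st$per_event$rise_mM, c(0, 0))
  expect_equal(st$baseline_elevation_mM, 0)
  expect_equal(st$recovery_s, 0)
})

test_that("recovery time matches the analytic band crossing", {
  # exponential return with a known time constant after the window end
  tau <- 12
  E0 <- 1.4
  t <- seq(0, 400, by = 0.01)
  conc <- 3.5 + ifelse(t < 200, ifelse(t > 50, E0, 0),
                       E0 * exp(-(t - 200) / tau))
  tr <- tibble::tibble(time_s = t, conc_mM = conc)
  ev <- tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                       class = character())
  st <- k_transient_stats(tr, ev, stim_window = c(50, 200))
  expect_equal(st$recovery_s, tau * log(E0 / 0.2), tolerance = 0.02)
  expect_equal(st$baseline_elevation_mM, E0)
})

test_that("transient statistics are invariant to a time offset", {
  kd <- generator_defaults()$k_transients
  mk <- function(shift) {
    sch <- event_schedule("ictal", 60 + shift, 40,
                          amplitude = kd$ictal_rise_mM)
    tr <- gen_electrode_trace(sch, kd, fs = 50, noise_sd = 0, seed = 1,
                              duration = 160 + shift)
    conc <- tibble::tibble(time_s = tr$time_s,
                           conc_mM = k_voltage_to_conc(tr$voltage_mV))
    ev <- tibble::tibble(onset_s = 60 + shift, offset_s = 100 + shift,
                         class = "ictal")
    k_transient_stats(conc, ev)
  }
  expect_equal(mk(0)$per_event$rise_mM, mk(37)$per_event$rise_mM,
               tolerance = 1e-9)
})

test_that("events outside the trace are rejected", {
  tr <- tibble::tibble(time_s = seq(0, 10, by = 0.01), conc_mM = 3.5)
  ev <- tibble::tibble(onset_s = 8, offset_s = 15, class = "ictal")
  expect_error(k_transient_stats(tr, ev), "outside")
})
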