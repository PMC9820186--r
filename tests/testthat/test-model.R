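test_that("firing rate is a bounded increasing sigmoid with exact midpoint", {
  p <- population_params("E1", nu_max = 100, V_theta = 25, k_nu = 5)
  expect_equal(firing_rate(25, p), 50)
  expect_equal(firing_rate(-1e4, p), 0, tolerance = 1e-12)
  expect_equal(firing_rate(1e4, p), 100)
  # independent hand computation at V = 30
  expect_equal(firing_rate(30, p), 100 / (1 + exp(-1)), tolerance = 1e-12)
  v <- seq(-60, 80, by = 0.5)
  r <- firing_rate(v, p)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < 100))
})

test_that("pump flux is a saturating product of two activations", {
  pm <- pump_params(rho = 2, theta_Na = 20, sigma_Na = 2,
                    theta_K = 6, sigma_K = 1)
  expect_equal(pump_flux(20, 6, pm), 2 / 4)
  expect_equal(pump_flux(1e4, 1e4, pm), 2)
  expect_equal(pump_flux(24, 8, pm),
               2 / ((1 + exp(-2)) * (1 + exp(-2))), tolerance = 1e-12)
  expect_error(pump_flux(-1, 3, pm), class = "ictalsim_domain_error")
  # grid-checked monotonicity in both arguments
  na <- seq(5, 45, by = 2)
  ko <- seq(0.5, 12, by = 0.5)
  m <- outer(na, ko, function(a, b) pump_flux(a, b, pm))
  expect_true(all(apply(m, 2, diff) >= 0))
  expect_true(all(apply(m, 1, diff) >= 0))
})

test_that("chloride reversal potential follows the Nernst relation", {
  ion <- ion_params()
  expect_equal(gaba_reversal(130, ion), 0)
  expect_equal(gaba_reversal(10, ion), 26.7 * log(10 / 130))
  expect_lt(gaba_reversal(10, ion), -68)
  expect_gt(gaba_reversal(10, ion), -69)
  # elevated chloride depolarizes the reversal potential
  expect_gt(gaba_reversal(25, ion), gaba_reversal(10, ion))
  expect_equal(gaba_reversal(25, ion), -44.0, tolerance = 0.05)
  expect_error(gaba_reversal(0, ion), class = "ictalsim_domain_error")
})

test_that("stimulus current follows the periodic pulse train", {
  pr <- stim_protocol(frequency = 0.2, pulse_width = 0.2,
                      amplitude = c(E1 = 25, E2 = 25, I = 25),
                      t_start = 0, t_stop = 350)
  expect_equal(stimulus_current(pr, 0.1, "E1"), 25)
  expect_equal(stimulus_current(pr, 0.3, "E1"), 0)
  expect_equal(stimulus_current(pr, 5.05, "E1"), 25)   # period 5 s
  expect_equal(stimulus_current(pr, 360, "E1"), 0)     # after t_stop
  pr2 <- stim_protocol(t_start = 10)
  expect_equal(stimulus_current(pr2, 5, "E1"), 0)      # before t_start
  # partial interneuron expression scales the effective current
  m2 <- stim_protocol("model2", t_start = 0, t_stop = 100)
  expect_equal(stimulus_current(m2, 0.1, "I"), 50)
  expect_equal(stimulus_current(m2, 0.1, "E1"), 0)
  expect_error(stimulus_current(pr, 0.1, "X"))
})

test_that("root-finding locates the quiescent fixed point", {
  # a weakly K-coupled variant: the strongly coupled default set is a pure
  # relaxation oscillator with no quiescent fixed point to find
  params <- network_params(ions = ion_params(delta_K = 0.004))
  rest <- find_resting_state(params)
  d <- network_derivatives(rest, params)
  expect_lt(max(abs(d)), 1e-6)
  expect_gt(rest[["K_o"]], 0)
  expect_gt(rest[["Na_i"]], 0)
  expect_true(rest[["x_D"]] > 0 && rest[["x_D"]] <= 1)
})

test_that("ion relaxation and pump stoichiometry have the right signs", {
  params <- network_params()
  rest <- default_initial_state(params)
  # potassium above bath with silenced network and no pump relaxes down
  silent <- network_params(pump = pump_params(rho = 0))
  st <- rest
  st[["K_o"]] <- params$ions$K_bath + 2
  st[c("V_E1", "V_E2", "V_I")] <- -60   # effectively zero firing
  d <- network_derivatives(st, silent)
  expect_lt(d[["K_o"]], 0)
  # switching the pump on removes Na and K in 3:2 proportion
  active <- st
  active[["Na_i"]] <- params$pump$theta_Na + 5
  d_off <- network_derivatives(active, silent)
  d_on <- network_derivatives(active, params)
  f <- pump_flux(active[["Na_i"]], active[["K_o"]], params$pump)
  expect_equal(d_off[["Na_i"]] - d_on[["Na_i"]], 3 * f, tolerance = 1e-10)
  expect_equal(d_off[["K_o"]] - d_on[["K_o"]], 2 * f, tolerance = 1e-10)
  expect_error(network_derivatives(replace(rest, 1, NaN), params),
               class = "ictalsim_state_error")
})
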