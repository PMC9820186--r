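test_that("Boltzmann probability has exact midpoint and stable tails", {
  expect_equal(boltzmann_p(0.40, 0.40, 0.007), 0.5)
  expect_equal(boltzmann_p(0.44, 0.40, 0.007),
               1 - 1 / (1 + exp(40 / 7)), tolerance = 1e-12)
  expect_equal(boltzmann_p(0, 0.40, 0.007), 0, tolerance = 1e-12)
  # stable far into both tails
  expect_equal(boltzmann_p(0.40 + 700 * 0.007, 0.40, 0.007), 1)
  expect_equal(boltzmann_p(0.40 - 700 * 0.007, 0.40, 0.007), 0)
  li <- seq(0.3, 0.5, by = 1e-3)
  expect_true(all(diff(boltzmann_p(li, 0.4, 0.007)) > 0))
})

test_that("maximum-likelihood fit equals the brute-force likelihood grid", {
  dat <- gen_dose_response(li_grid = seq(0.37, 0.43, by = 0.004),
                           n_per_li = 15, n_slices = 1, seed = 7)
  fit <- fit_boltzmann(dat)
  grid <- fit_boltzmann_grid(dat)
  # the optimizer must do at least as well as, and agree with, the grid
  nll_fit <- boltzmann_nll_oracle(dat$li_percent, dat$outcome,
                                  fit$pooled$LI0, fit$pooled$Delta)
  nll_grid <- boltzmann_nll_oracle(dat$li_percent, dat$outcome,
                                   grid$LI0, grid$Delta)
  expect_lte(nll_fit, nll_grid + 1e-6)
  expect_lt(abs(fit$pooled$LI0 - grid$LI0), 5e-4 + 1e-9)
  expect_lt(abs(log(fit$pooled$Delta) - log(grid$Delta)),
            diff(log(c(1e-4, 0.1))) / 59 + 1e-9)
})

test_that("the fit agrees with logistic regression on well-behaved data", {
  # the Boltzmann curve is a reparameterized logistic CDF, so a binomial
  # GLM provides an independent estimate when the slope is moderate
  dat <- gen_dose_response(li_grid = seq(0.2, 0.6, by = 0.01),
                           LI0 = 0.4, Delta = 0.05,
                           n_per_li = 40, n_slices = 1, seed = 11)
  fit <- fit_boltzmann(dat)
  glmfit <- stats::glm(outcome ~ li_percent, binomial(), data = dat)
  b <- coef(glmfit)
  expect_equal(fit$pooled$LI0, unname(-b[1] / b[2]), tolerance = 1e-3)
  expect_equal(fit$pooled$Delta, unname(1 / b[2]), tolerance = 1e-3)
})

test_that("per-slice fitting recovers the generating parameters", {
  dat <- gen_dose_response(li_grid = seq(0.34, 0.46, by = 0.002),
                           n_per_li = 30, n_slices = 5, seed = 21)
  fit <- fit_boltzmann(dat, per_slice = TRUE)
  expect_equal(nrow(fit$per_slice), 5)
  expect_lt(abs(fit$averaged$LI0 - 0.40), 0.01)
  expect_lt(abs(fit$averaged$Delta - 0.007), 0.003)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "LI0"], fit$averaged$LI0)
  expect_false(glance(fit)$boundary)
})

test_that("the fitted midpoint sits inside the empirical 50% bracket", {
  dat <- gen_dose_response(li_grid = seq(0.36, 0.44, by = 0.002),
                           n_per_li = 25, n_slices = 1, seed = 3)
  fit <- fit_boltzmann(dat)
  p_hat <- tapply(dat$outcome, dat$li_percent, mean)
  lv <- as.numeric(names(p_hat))
  lo <- max(lv[p_hat < 0.5])
  hi <- min(lv[p_hat > 0.5])
  expect_gte(fit$pooled$LI0, min(lo, hi) - 0.002)
  expect_lte(fit$pooled$LI0, max(lo, hi) + 0.002)
})

test_that("shifting all intensities shifts the midpoint only", {
  dat <- gen_dose_response(li_grid = seq(0.36, 0.44, by = 0.002),
                           n_per_li = 25, n_slices = 1, seed = 5)
  f1 <- fit_boltzmann(dat)
  dat2 <- dplyr::mutate(dat, li_percent = li_percent + 0.1)
  f2 <- fit_boltzmann(dat2)
  expect_equal(f2$pooled$LI0, f1$pooled$LI0 + 0.1, tolerance = 1e-4)
  expect_equal(f2$pooled$Delta, f1$pooled$Delta, tolerance = 1e-4)
})

test_that("degenerate and single-class data are handled explicitly", {
  # perfectly separated outcomes drive the slope to its lower bound
  sep <- tibble::tibble(li_percent = rep(seq(0.3, 0.5, by = 0.01), 3))
  sep$outcome <- as.integer(sep$li_percent > 0.4)
  fit <- fit_boltzmann(sep)
  expect_true(fit$pooled$boundary)
  expect_gt(fit$pooled$LI0, 0.40)
  expect_lt(fit$pooled$LI0, 0.41)

  one <- tibble::tibble(slice_id = "s7", li_percent = seq(0.3, 0.5, 0.01),
                        outcome = 1)
  expect_error(fit_boltzmann(one, per_slice = TRUE), "s7",
               class = "ictalsim_fit_error")
})
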