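#' Sigmoidal population rate transfer function
#'
#' @param V Membrane potential (mV relative to rest); vectorized.
#' @param pop A [population_params()] object.
#' @return Firing rate (1/s), strictly increasing in `V` and bounded in
#'   `(0, nu_max)`.
#' @examples
#' p <- population_params("E1", nu_max = 100, V_theta = 25, k_nu = 5)
#' firing_rate(25, p)  # nu_max / 2
#' @export
firing_rate <- function(V, pop) {
  stopifnot(inherits(pop, "population_params"))
  pop$nu_max * plogis((V - pop$V_theta) / pop$k_nu)
}

#' Na-K pump flux
#'
#' Product of sodium and potassium sigmoidal activation, saturating at
#' `rho`.  The pump becomes more active at high intracellular sodium, which
#' is what terminates each ictal discharge.
#'
#' @param Na_i Intracellular sodium (mM); vectorized.
#' @param K_o Extracellular potassium (mM); vectorized.
#' @param pump A [pump_params()] object.
#' @return Pump flux (mM/s), non-decreasing in both arguments.
#' @export
pump_flux <- function(Na_i, K_o, pump) {
  stopifnot(inherits(pump, "pump_params"))
  if (any(Na_i <= 0) || any(K_o <= 0)) {
    abort("concentrations must be positive", class = "ictalsim_domain_error")
  }
  pump$rho * plogis((Na_i - pump$theta_Na) / pump$sigma_Na) *
    plogis((K_o - pump$theta_K) / pump$sigma_K)
}

#' Chloride (GABA-A) reversal potential
#'
#' Nernst potential of chloride, `RT_F * log(Cl_i / Cl_out)`, on the absolute
#' scale (0 mV reference).  With elevated intracellular chloride the reversal
#' potential rises above rest and GABA becomes depolarizing.
#'
#' @param Cl_i Intracellular chloride (mM); vectorized.
#' @param ion An [ion_params()] object.
#' @return Reversal potential (mV, absolute).
#' @examples
#' gaba_reversal(10, ion_params())   # about -68.5 mV
#' gaba_reversal(25, ion_params())   # depolarized, about -44 mV
#' @export
gaba_reversal <- function(Cl_i, ion) {
  stopifnot(inherits(ion, "ion_params"))
  if (any(Cl_i <= 0)) {
    abort("Cl_i must be positive", class = "ictalsim_domain_error")
  }
  ion$RT_F * log(Cl_i / ion$Cl_out)
}

#' Stimulus current of a periodic protocol
#'
#' @param protocol A [stim_protocol()].
#' @param t Time (s); vectorized.
#' @param population `"E1"`, `"E2"` or `"I"`.  For the inhibitory population
#'   the amplitude is scaled by `stimulated_fraction_I` (mean-field treatment
#'   of partial opsin expression).
#' @return Current (pA) at each time.
#' @export
stimulus_current <- function(protocol, t, population) {
  stopifnot(inherits(protocol, "stim_protocol"), all(t >= 0))
  population <- arg_match(population, c("E1", "E2", "I"))
  amp <- protocol$amplitude[[population]]
  if (population == "I") amp <- amp * protocol$stimulated_fraction_I
  period <- 1 / protocol$frequency
  phase <- (t - protocol$t_start) %% period
  active <- t >= protocol$t_start & t < protocol$t_stop &
    phase < protocol$pulse_width
  ifelse(active, amp, 0)
}

state_names <- c("V_E1", "V_E2", "V_I", "K_o", "Na_i",
                 "Cl_E1", "Cl_E2", "x_D")

#' Time derivatives of the network state
#'
#' The deterministic right-hand side of the coupled rate/ion system.  Used
#' directly for resting-state analysis and as the reference implementation
#' against which the compiled integrator is checked.
#'
#' @param state Named numeric vector with elements `V_E1`, `V_E2`, `V_I`
#'   (mV relative to rest), `K_o`, `Na_i`, `Cl_E1`, `Cl_E2` (mM) and `x_D`
#'   (synaptic resource in `[0, 1]`).
#' @param params A [network_params()].
#' @param protocol Optional [stim_protocol()]; `NULL` means no stimulation.
#' @param t Time (s), needed only when a protocol is given.
#' @return Named numeric vector of time derivatives, same order as `state`.
#' @export
network_derivatives <- function(state, params, protocol = NULL, t = 0) {
  stopifnot(inherits(params, "network_params"))
  if (anyNA(state) || any(!is.finite(state))) {
    abort("state contains NaN/Inf", class = "ictalsim_state_error")
  }
  s <- as.list(state[state_names])
  if (anyNA(s)) abort("state must be named with the full state vector")
  ions <- params$ions; pump <- params$pump; syn <- params$syn

  nu <- c(
    E1 = firing_rate(s$V_E1, params$E1),
    E2 = firing_rate(s$V_E2, params$E2),
    I = firing_rate(s$V_I, params$I)
  )
  nu_E <- (nu[["E1"]] + nu[["E2"]]) / 2
  f <- pump_flux(s$Na_i, s$K_o, pump)
  uK <- ions$c_K * log(s$K_o / ions$K_bath)

  e_gaba_rel <- function(Cl) gaba_reversal(Cl, ions) - ions$V_rest
  E_g <- c(E1 = e_gaba_rel(s$Cl_E1), E2 = e_gaba_rel(s$Cl_E2),
           I = e_gaba_rel(ions$Cl_rest_normal))

  I_stim <- if (is.null(protocol)) {
    c(E1 = 0, E2 = 0, I = 0)
  } else {
    c(E1 = stimulus_current(protocol, t, "E1"),
      E2 = stimulus_current(protocol, t, "E2"),
      I = stimulus_current(protocol, t, "I"))
  }

  dV <- vapply(c("E1", "E2", "I"), function(p) {
    pp <- params[[p]]
    V <- s[[paste0("V_", p)]]
    u_syn <- if (p == "I") {
      pp$w_from_E * nu_E +
        pp$w_from_I * nu[["I"]] * (V - E_g[[p]]) / syn$V_norm
    } else {
      pp$w_from_E * s$x_D * nu_E +
        pp$w_from_I * nu[["I"]] * (V - E_g[[p]]) / syn$V_norm
    }
    (-V + uK + u_syn + pp$R_in * I_stim[[p]] / 1000 -
       pump$gamma_electro * f) / pp$tau_m
  }, numeric(1))

  dK <- (ions$K_bath - s$K_o) / ions$tau_K + ions$delta_K * nu_E - 2 * f
  dNa <- (ions$Na_rest - s$Na_i) / ions$tau_Na + ions$delta_Na * nu_E - 3 * f
  dCl1 <- (ions$Cl_rest_normal - s$Cl_E1) / ions$tau_Cl +
    ions$delta_Cl * nu[["I"]] * max(0, s$V_E1 - E_g[["E1"]])
  dCl2 <- (ions$Cl_rest_high - s$Cl_E2) / ions$tau_Cl +
    ions$delta_Cl * nu[["I"]] * max(0, s$V_E2 - E_g[["E2"]])
  dxD <- (1 - s$x_D) / syn$tau_D - syn$delta_D * s$x_D * nu_E

  setNames(c(dV[["E1"]], dV[["E2"]], dV[["I"]], dK, dNa, dCl1, dCl2, dxD),
           state_names)
}

#' Quiescent (interictal) fixed point of the network
#'
#' Finds the resting state numerically by minimizing the squared norm of the
#' deterministic derivatives, starting from a physiologically informed
#' initial guess.  Because the unstimulated system is a slow relaxation
#' oscillator, this fixed point organizes the quiescent phase between
#' discharges rather than being globally attracting.
#'
#' @param params A [network_params()].
#' @param tol Maximum acceptable residual derivative norm.
#' @return Named state vector at the fixed point.
#' @export
find_resting_state <- function(params, tol = 1e-6) {
  ions <- params$ions
  start <- c(V_E1 = -1, V_E2 = -1, V_I = -1,
             K_o = ions$K_bath * 0.9, Na_i = ions$Na_rest,
             Cl_E1 = ions$Cl_rest_normal, Cl_E2 = ions$Cl_rest_high,
             x_D = 0.95)
  f <- function(x) network_derivatives(setNames(x, state_names), params)
  x <- start
  # damped Newton with a forward-difference Jacobian
  for (iter in 1:200) {
    fx <- f(x)
    if (max(abs(fx)) < tol) break
    J <- matrix(0, 8, 8)
    h <- pmax(1e-7, 1e-7 * abs(x))
    for (j in 1:8) {
      xj <- x
      xj[j] <- xj[j] + h[j]
      J[, j] <- (f(xj) - fx) / h[j]
    }
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      ok <- all(xn[4:7] > 0) && all(is.finite(xn)) &&
        sum(f(xn)^2) < sum(fx^2)
      if (ok || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-4) break
    x <- xn
  }
  res <- setNames(x, state_names)
  resid <- max(abs(f(x)))
  if (resid > tol) {
    warn(sprintf("resting-state residual %.2e above tol %.0e", resid, tol))
  }
  res
}
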