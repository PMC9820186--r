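pack_params <- function(params, V_hold = -30) {
  p <- unlist(lapply(c("E1", "E2", "I"), function(nm) {
    pp <- params[[nm]]
    c(pp$nu_max, pp$V_theta, pp$k_nu, pp$tau_m, pp$R_in,
      pp$w_from_E, pp$w_from_I, pp$noise_sigma)
  }))
  pm <- params$pump
  io <- params$ions
  sy <- params$syn
  c(p,
    pm$rho, pm$theta_Na, pm$sigma_Na, pm$theta_K, pm$sigma_K,
    pm$gamma_electro,
    io$K_bath, io$Na_rest, io$Cl_rest_normal, io$Cl_rest_high, io$Cl_out,
    io$tau_K, io$tau_Na, io$tau_Cl, io$delta_K, io$delta_Na, io$delta_Cl,
    io$c_K, io$RT_F, io$V_rest,
    sy$tau_D, sy$delta_D, sy$V_norm, sy$tau_ampa, sy$tau_gaba,
    sy$g_ampa, sy$g_gaba,
    V_hold)
}

pack_protocol <- function(protocol) {
  if (is.null(protocol)) {
    # zero-amplitude placeholder: never active
    return(c(1, 0.1, 0, 0, 0, 0, -1))
  }
  c(protocol$frequency, protocol$pulse_width,
    protocol$amplitude[["E1"]], protocol$amplitude[["E2"]],
    protocol$amplitude[["I"]] * protocol$stimulated_fraction_I,
    protocol$t_start, protocol$t_stop)
}

sim_channels <- c("time_s", "V_E1", "V_E2", "V_I", "K_o", "Na_i",
                  "Cl_E1", "Cl_E2", "x_D", "rate_E1", "rate_E2", "rate_I",
                  "pump", "I_vc")

#' Simulate the three-population ionic network
#'
#' Integrates the stochastic rate/ion system with a fixed-step scheme.  The
#' membrane noise is realized as a piecewise-constant process on a fixed
#' 1 ms grid, so the same seed yields the same forcing at any integration
#' step `dt` that divides the grid; at the default `dt` of 1 ms the scheme
#' is exactly Euler-Maruyama, and halving `dt` refines the same trajectory
#' rather than drawing a new one.
#'
#' @param params A [network_params()]; defaults to the tuned reference set.
#' @param protocol Optional [stim_protocol()]; `NULL` simulates the
#'   unstimulated (control) network.
#' @param duration Simulated time (s).
#' @param seed Integer seed for the membrane noise (mandatory).
#' @param dt Integration step (s); must divide the 1 ms noise grid.
#' @param record_dt Sampling interval of the returned trace (s); must be a
#'   multiple of `dt`.
#' @param init Optional named initial state vector.  The default is a
#'   mildly refractory post-discharge state (potassium somewhat below bath,
#'   sodium above rest), from which the relaxation cycle settles within the
#'   first inter-discharge interval; under the tuned defaults the network
#'   has no globally attracting quiescent fixed point to start from.
#' @param V_hold Holding potential (absolute mV) of the voltage-clamp
#'   observable channel `I_vc`.
#' @return A tibble of class `"network_sim"` with columns `time_s`, the
#'   state channels (`V_E1`, `V_E2`, `V_I` in mV relative to rest; `K_o`,
#'   `Na_i`, `Cl_E1`, `Cl_E2` in mM; `x_D`), the derived channels
#'   `rate_E1`, `rate_E2`, `rate_I`, `rate_E` (1/s), `pump` (mM/s) and
#'   `I_vc` (pA, outward positive).  Simulation metadata (params, protocol,
#'   dt, seed) is stored in attributes.
#' @examples
#' \donttest{
#' sim <- simulate_network(duration = 60, seed = 1)
#' dplyr::glimpse(sim)
#' }
#' @export
simulate_network <- function(params = network_params(),
                             protocol = NULL,
                             duration,
                             seed,
                             dt = 1e-3,
                             record_dt = 0.01,
                             init = NULL,
                             V_hold = -30) {
  stopifnot(inherits(params, "network_params"), duration > 0, dt > 0)
  if (missing(seed)) abort("`seed` is required for the membrane noise")
  if (!is.null(protocol)) stopifnot(inherits(protocol, "stim_protocol"))
  noise_dt <- 1e-3
  if (dt > noise_dt + 1e-12 ||
      abs(noise_dt / dt - round(noise_dt / dt)) > 1e-9) {
    abort("`dt` must divide the 1 ms noise grid (e.g. 1e-3, 5e-4, 2.5e-4)")
  }
  thin <- record_dt / dt
  if (abs(thin - round(thin)) > 1e-9) {
    abort("`record_dt` must be a multiple of `dt`")
  }

  if (is.null(init)) init <- default_initial_state(params)
  init <- init[state_names]
  if (anyNA(init)) abort("`init` must be a full named state vector")

  n_blocks <- ceiling(duration / noise_dt) + 1
  set.seed(seed)
  noise <- matrix(rnorm(3 * n_blocks), nrow = 3)

  raw <- .integrate_network_cpp(
    unname(init), pack_params(params, V_hold), pack_protocol(protocol),
    duration, dt, noise, noise_dt, as.integer(round(thin))
  )
  colnames(raw) <- sim_channels
  out <- as_tibble(as.data.frame(raw))
  out$rate_E <- (out$rate_E1 + out$rate_E2) / 2
  structure(
    out,
    class = c("network_sim", class(out)),
    params = params, protocol = protocol,
    dt = dt, record_dt = record_dt, seed = seed, V_hold = V_hold
  )
}

#' Voltage-clamp current reconstructed from a simulation trace
#'
#' The mixed postsynaptic current a representative `E1` neuron would show
#' under voltage clamp: AMPA and GABA conductances are obtained by
#' exponential filtering (time constants from the parameter set) of the
#' depression-weighted excitatory rate and the inhibitory rate, and the
#' current is `g_AMPA (V_hold - 0) + g_GABA (V_hold - E_GABA)` with outward
#' current positive.  The filters are stepped at the trace's sampling
#' interval, so a finely sampled trace (`record_dt` equal to the integration
#' `dt`) reproduces the simulator's own `I_vc` channel.
#'
#' @param trace A `"network_sim"` tibble (or any tibble with `time_s`,
#'   `rate_E1`, `rate_E2`, `rate_I`, `x_D`, `Cl_E1` columns).
#' @param V_hold Holding potential (absolute mV).
#' @param params A [network_params()]; defaults to the trace's own.
#' @return Numeric vector of clamp current (pA), one value per row.
#' @export
voltage_clamp_current <- function(trace, V_hold = -30, params = NULL) {
  params <- params %||% attr(trace, "params") %||% network_params()
  need <- c("time_s", "rate_E1", "rate_E2", "rate_I", "x_D", "Cl_E1")
  if (!all(need %in% names(trace))) {
    abort(paste("trace must contain columns:", paste(need, collapse = ", ")))
  }
  sy <- params$syn
  io <- params$ions
  dt <- trace$time_s[2] - trace$time_s[1]
  drive_A <- trace$x_D * (trace$rate_E1 + trace$rate_E2) / 2
  drive_G <- trace$rate_I
  n <- nrow(trace)
  aA <- numeric(n)
  aG <- numeric(n)
  for (k in seq_len(n - 1)) {
    aA[k + 1] <- aA[k] + dt * (drive_A[k] - aA[k]) / sy$tau_ampa
    aG[k + 1] <- aG[k] + dt * (drive_G[k] - aG[k]) / sy$tau_gaba
  }
  E_gaba <- io$RT_F * log(trace$Cl_E1 / io$Cl_out)
  sy$g_ampa * aA * V_hold + sy$g_gaba * aG * (V_hold - E_gaba)
}

#' Default initial state of a simulation
#'
#' A mildly refractory post-discharge state: potassium 20% below bath,
#' sodium 10 mM above rest, chloride at rest, full synaptic resource.
#' Starting here avoids beginning the run inside an ictal discharge.
#'
#' @param params A [network_params()].
#' @return Named state vector.
#' @export
default_initial_state <- function(params) {
  ions <- params$ions
  c(V_E1 = -5, V_E2 = -5, V_I = -5,
    K_o = 0.8 * ions$K_bath, Na_i = ions$Na_rest + 10,
    Cl_E1 = ions$Cl_rest_normal, Cl_E2 = ions$Cl_rest_high,
    x_D = 0.95)
}
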