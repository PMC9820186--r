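#' Population parameters for the rate model
#'
#' One neuronal population of the three-population network (`E1`, `E2` or
#' `I`).  The population is described by a sigmoidal rate transfer function
#' \eqn{\nu(V) = \nu_{max} / (1 + e^{-(V-V_\theta)/k_\nu})}, a membrane time
#' constant, an input resistance converting picoampere stimulation into
#' millivolt drive, and synaptic weights from the pooled excitatory and the
#' inhibitory population.
#'
#' All potentials are in mV *relative to rest*; times in seconds.
#'
#' @param label One of `"E1"`, `"E2"`, `"I"`.
#' @param nu_max Maximal firing rate (1/s).
#' @param V_theta Midpoint of the rate function (mV above rest).
#' @param k_nu Slope of the rate function (mV).
#' @param tau_m Membrane time constant (s).
#' @param R_in Input resistance (megaohm); a stimulus of `I` pA adds
#'   `R_in * I / 1000` mV of drive.
#' @param w_from_E Weight of the pooled excitatory rate (mV s).
#' @param w_from_I Weight of the inhibitory GABA term (mV s); negative values
#'   make GABA hyperpolarizing when the membrane is above the chloride
#'   reversal potential.
#' @param noise_sigma Standard deviation of the additive membrane noise (mV);
#'   chosen so the stationary voltage fluctuation is `noise_sigma / sqrt(2)`.
#' @return A list of class `"population_params"`.
#' @export
population_params <- function(label,
                              nu_max = 100,
                              V_theta = 13,
                              k_nu = 2.5,
                              tau_m = 0.02,
                              R_in = 800,
                              w_from_E = 0.6,
                              w_from_I = -0.01,
                              noise_sigma = 4.5) {
  label <- arg_match(label, c("E1", "E2", "I"))
  stopifnot(nu_max > 0, k_nu > 0, tau_m > 0, R_in > 0, noise_sigma >= 0)
  structure(
    list(label = label, nu_max = nu_max, V_theta = V_theta, k_nu = k_nu,
         tau_m = tau_m, R_in = R_in, w_from_E = w_from_E,
         w_from_I = w_from_I, noise_sigma = noise_sigma),
    class = "population_params"
  )
}

#' Na-K pump parameters
#'
#' The electrogenic Na-K ATPase is modelled as a product of two sigmoidal
#' activation terms, one in intracellular sodium and one in extracellular
#' potassium, saturating at the maximal flux `rho`:
#' \deqn{f(Na_i, K_o) = \rho \, \big[(1 + e^{(\theta_{Na}-Na_i)/\sigma_{Na}})
#'   (1 + e^{(\theta_K-K_o)/\sigma_K})\big]^{-1}.}
#' One pump cycle moves 3 Na out for 2 K in; the hyperpolarizing (electrogenic)
#' effect of a flux `f` on the membrane is `gamma_electro * f` mV.
#'
#' @param rho Maximal pump flux (mM/s).
#' @param theta_Na,sigma_Na Sodium half-activation and slope (mM).
#' @param theta_K,sigma_K Potassium half-activation and slope (mM).
#' @param gamma_electro Conversion from pump flux to hyperpolarizing membrane
#'   drive (mV s/mM).
#' @return A list of class `"pump_params"`.
#' @export
pump_params <- function(rho = 3,
                        theta_Na = 40, sigma_Na = 3,
                        theta_K = 2, sigma_K = 1,
                        gamma_electro = 26) {
  stopifnot(rho >= 0, sigma_Na > 0, sigma_K > 0, gamma_electro >= 0)
  structure(
    list(rho = rho, theta_Na = theta_Na, sigma_Na = sigma_Na,
         theta_K = theta_K, sigma_K = sigma_K,
         gamma_electro = gamma_electro),
    class = "pump_params"
  )
}

#' Ionic dynamics parameters
#'
#' Governs the slow variables of the network: extracellular potassium,
#' intracellular sodium, and per-population intracellular chloride.  Each ion
#' relaxes to its resting value and is driven by population firing;
#' potassium and sodium are additionally moved by the Na-K pump with 2:3
#' stoichiometry.  Elevated extracellular potassium depolarizes all
#' populations through the term `c_K * log(K_o / K_bath)`.
#'
#' @param K_bath Bath potassium concentration (mM); the recording solution
#'   contains 3.5 mM KCl.
#' @param Na_rest Resting intracellular sodium (mM).
#' @param Cl_rest_normal,Cl_rest_high Resting intracellular chloride of the
#'   normal (`E1`) and chloride-loaded (`E2`) excitatory population (mM).
#' @param Cl_out Extracellular chloride (mM).
#' @param tau_K,tau_Na,tau_Cl Relaxation time constants (s).
#' @param delta_K,delta_Na Ion flux increment per unit population rate
#'   (mM s).
#' @param delta_Cl Chloride accumulation gain (mM s / mV) multiplying the
#'   inhibitory rate times the rectified GABA driving force.
#' @param c_K Potassium-dependent depolarization gain (mV).
#' @param RT_F Nernst slope (mV).
#' @param V_rest Absolute resting membrane potential (mV) used to express the
#'   chloride Nernst potential relative to rest.
#' @return A list of class `"ion_params"`.
#' @export
ion_params <- function(K_bath = 3.5,
                       Na_rest = 15,
                       Cl_rest_normal = 7,
                       Cl_rest_high = 20,
                       Cl_out = 130,
                       tau_K = 25, tau_Na = 100, tau_Cl = 20,
                       delta_K = 0.04, delta_Na = 0.1,
                       delta_Cl = 2e-4,
                       c_K = 30,
                       RT_F = 26.7,
                       V_rest = -70) {
  stopifnot(
    K_bath > 0, Na_rest > 0, Cl_rest_normal > 0, Cl_rest_high > 0,
    Cl_out > 0, tau_K > 0, tau_Na > 0, tau_Cl > 0, RT_F > 0
  )
  structure(
    list(K_bath = K_bath, Na_rest = Na_rest,
         Cl_rest_normal = Cl_rest_normal, Cl_rest_high = Cl_rest_high,
         Cl_out = Cl_out, tau_K = tau_K, tau_Na = tau_Na, tau_Cl = tau_Cl,
         delta_K = delta_K, delta_Na = delta_Na, delta_Cl = delta_Cl,
         c_K = c_K, RT_F = RT_F, V_rest = V_rest),
    class = "ion_params"
  )
}

#' Synaptic dynamics parameters
#'
#' Short-term depression of the recurrent excitatory synapses
#' (`dx_D/dt = (1 - x_D)/tau_D - delta_D * x_D * nu_E`), the driving-force
#' normalization of the GABA term, and the kernels used to reconstruct the
#' voltage-clamp observable.
#'
#' @param tau_D Recovery time constant of the synaptic resource (s).
#' @param delta_D Depletion per presynaptic spike rate (s).
#' @param V_norm Driving-force normalization of the GABA synaptic term (mV).
#' @param tau_ampa,tau_gaba Exponential conductance kernels of the clamp
#'   observable (s).
#' @param g_ampa,g_gaba Conductance per unit presynaptic rate (nS s) for the
#'   clamp observable.
#' @return A list of class `"syn_params"`.
#' @export
syn_params <- function(tau_D = 1, delta_D = 0.06, V_norm = 10,
                       tau_ampa = 0.005, tau_gaba = 0.010,
                       g_ampa = 0.01, g_gaba = 0.01) {
  stopifnot(tau_D > 0, delta_D >= 0, V_norm > 0,
            tau_ampa > 0, tau_gaba > 0)
  structure(
    list(tau_D = tau_D, delta_D = delta_D, V_norm = V_norm,
         tau_ampa = tau_ampa, tau_gaba = tau_gaba,
         g_ampa = g_ampa, g_gaba = g_gaba),
    class = "syn_params"
  )
}

#' Full parameter set of the three-population ionic network
#'
#' Bundles the three populations, pump, ion and synaptic parameter blocks.
#' The defaults are the package's tuned reference set: under them the
#' unstimulated network produces spontaneous ictal discharges lasting tens
#' of seconds (mostly 30-60 s), recurring every one to several minutes,
#' with an extracellular potassium rise of a few millimolar during the
#' discharge; each evoked interictal discharge raises intracellular sodium
#' by 1-2 mM.  The tuning script that produced this set ships in
#' `scripts/tune_defaults.R`.
#'
#' @param E1,E2,I [population_params()] for the two excitatory populations
#'   (the second chloride-loaded) and the inhibitory population.
#' @param pump [pump_params()].
#' @param ions [ion_params()].
#' @param syn [syn_params()].
#' @return A list of class `"network_params"`.
#' @export
network_params <- function(E1 = population_params("E1"),
                           E2 = population_params("E2"),
                           I = population_params(
                             "I", nu_max = 200, tau_m = 0.01, R_in = 400,
                             w_from_E = 0.03, w_from_I = -0.01
                           ),
                           pump = pump_params(),
                           ions = ion_params(),
                           syn = syn_params()) {
  stopifnot(
    inherits(E1, "population_params"), inherits(E2, "population_params"),
    inherits(I, "population_params"), inherits(pump, "pump_params"),
    inherits(ions, "ion_params"), inherits(syn, "syn_params")
  )
  if (E1$label != "E1" || E2$label != "E2" || I$label != "I") {
    abort("population labels must be E1, E2, I in that order")
  }
  structure(list(E1 = E1, E2 = E2, I = I, pump = pump, ions = ions,
                 syn = syn),
            class = "network_params")
}

#' Periodic stimulation protocol
#'
#' A periodic train of current pulses with per-population signed amplitude.
#' The three experimental stimulation models are available as presets:
#' \describe{
#'   \item{`"model1"`}{200 ms depolarizing 25 pA pulses at 0.2 Hz to all
#'     populations (nonspecific activation of excitatory and inhibitory
#'     neurons).}
#'   \item{`"model2"`}{200 ms depolarizing 100 pA pulses at 0.2 Hz to the
#'     inhibitory population only, with half of the interneurons expressing
#'     the actuator (`stimulated_fraction_I = 0.5`).}
#'   \item{`"model3"`}{200 ms hyperpolarizing 25 pA pulses at 0.2 Hz to both
#'     excitatory populations.}
#' }
#'
#' @param preset Optional preset name (`"model1"`, `"model2"`, `"model3"`);
#'   explicit arguments override preset values.
#' @param frequency Pulse frequency (Hz).
#' @param pulse_width Pulse duration (s); must be shorter than the period.
#' @param amplitude Named numeric vector of pulse amplitudes (pA, signed,
#'   negative = hyperpolarizing) with names `E1`, `E2`, `I`.
#' @param stimulated_fraction_I Fraction of the inhibitory population that
#'   receives the current (mean-field scaling of partial opsin expression).
#' @param t_start,t_stop Stimulation window (s).
#' @return A list of class `"stim_protocol"`.
#' @examples
#' stim_protocol("model1", t_start = 100, t_stop = 450)
#' @export
stim_protocol <- function(preset = NULL,
                          frequency = 0.2,
                          pulse_width = 0.2,
                          amplitude = c(E1 = 0, E2 = 0, I = 0),
                          stimulated_fraction_I = 1,
                          t_start = 0,
                          t_stop = Inf) {
  if (!is.null(preset)) {
    preset <- arg_match(preset, c("model1", "model2", "model3", "none"))
    defaults <- switch(preset,
      model1 = list(amplitude = c(E1 = 25, E2 = 25, I = 25),
                    stimulated_fraction_I = 1),
      model2 = list(amplitude = c(E1 = 0, E2 = 0, I = 100),
                    stimulated_fraction_I = 0.5),
      model3 = list(amplitude = c(E1 = -25, E2 = -25, I = 0),
                    stimulated_fraction_I = 1),
      none = list(amplitude = c(E1 = 0, E2 = 0, I = 0),
                  stimulated_fraction_I = 1)
    )
    if (missing(amplitude)) amplitude <- defaults$amplitude
    if (missing(stimulated_fraction_I)) {
      stimulated_fraction_I <- defaults$stimulated_fraction_I
    }
  }
  amplitude <- amplitude[c("E1", "E2", "I")]
  if (anyNA(amplitude)) {
    abort("`amplitude` must be a named vector with names E1, E2, I")
  }
  stopifnot(
    frequency > 0, pulse_width > 0, pulse_width < 1 / frequency,
    stimulated_fraction_I >= 0, stimulated_fraction_I <= 1,
    t_stop > t_start
  )
  structure(
    list(preset = preset %||% "custom", frequency = frequency,
         pulse_width = pulse_width, amplitude = amplitude,
         stimulated_fraction_I = stimulated_fraction_I,
         t_start = t_start, t_stop = t_stop),
    class = "stim_protocol"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params> three-population ionic rate model\n")
  for (p in c("E1", "E2", "I")) {
    pp <- x[[p]]
    cat(sprintf(
      "  %s: nu_max %g/s, V_theta %g mV, k_nu %g mV, tau_m %g s, R_in %g MOhm\n",
      p, pp$nu_max, pp$V_theta, pp$k_nu, pp$tau_m, pp$R_in
    ))
  }
  cat(sprintf("  pump: rho %g mM/s, theta_Na %g mM, theta_K %g mM\n",
              x$pump$rho, x$pump$theta_Na, x$pump$theta_K))
  cat(sprintf("  ions: K_bath %g mM, Na_rest %g mM, Cl %g/%g mM\n",
              x$ions$K_bath, x$ions$Na_rest, x$ions$Cl_rest_normal,
              x$ions$Cl_rest_high))
  invisible(x)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %s: %g Hz, %g ms pulses, window [%g, %g) s\n",
    x$preset, x$frequency, 1000 * x$pulse_width, x$t_start, x$t_stop
  ))
  cat(sprintf("  amplitude (pA): E1 %g, E2 %g, I %g (fraction I %g)\n",
              x$amplitude[["E1"]], x$amplitude[["E2"]], x$amplitude[["I"]],
              x$stimulated_fraction_I))
  invisible(x)
}
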