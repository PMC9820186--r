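---
title: "Methods: the ionic network model and its measurement pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ionic network model and its measurement pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ictalsim)
```

This vignette is the package's account of its science: the model and its
assumptions, the measurement conventions, the synthetic-data design, and
the numerical choices. Everything quantitative stated here is computed by
the test suite or by `scripts/acceptance.R`; nothing is asserted from
memory.

## 1. The three-population ionic rate model

### Structure and assumptions

The network reduces the 4-AP entorhinal slice to three homogeneous
populations: two excitatory (`E1` with normal intracellular chloride,
`E2` chloride-loaded, so its GABA-A reversal potential lies above rest and
GABA excites it) and one inhibitory population `I`. Each population is a
rate unit: a membrane potential `V_p` (mV relative to rest) driving a
sigmoidal firing rate `nu_p = nu_max / (1 + exp(-(V_p - V_theta)/k_nu))`.
This is a deliberate reduction — population-density machinery that tracks
single-neuron refractoriness is out of scope — but it preserves every
mechanism that matters for the ictal/interictal repertoire:

* **Potassium positive feedback.** Firing releases K⁺ into the
  extracellular space (`delta_K * nu_E`), and elevated K⁺ depolarizes all
  populations through `c_K * ln(K_o / K_bath)`. The logarithmic form is a
  Nernst-type sensitivity: what matters is the relative elevation above
  the bath.
* **Na-K pump termination.** Firing also loads the neurons with sodium
  (`delta_Na * nu_E`). The pump flux
  `f = rho * sigmoid((Na_i - theta_Na)/sigma_Na) * sigmoid((K_o - theta_K)/sigma_K)`
  moves 3 Na⁺ out per 2 K⁺ in, and its electrogenic current
  hyperpolarizes the membrane by `gamma_electro * f` mV. The potassium
  half-activation `theta_K = 2 mM` sits *below* the bath concentration:
  physiological pumps are nearly saturated in K_o at rest, so pump
  activity is gated almost entirely by intracellular sodium. (During
  tuning, placing `theta_K` above bath — so the pump only engaged at
  elevated K_o — made sodium protection impossible: the pump could never
  act at normal K_o, where protection is needed.)
* **Short-term depression.** The recurrent excitatory resource `x_D`
  depletes with firing and recovers with `tau_D = 1 s`. It terminates an
  isolated population burst within a few hundred milliseconds — this is
  what makes an *interictal* discharge brief — while elevated K⁺ can
  sustain firing through depression, which is what makes an *ictal*
  discharge long.
* **Depolarizing GABA.** The GABA term is signed by the driving force
  `V_p - E_GABA(Cl_p)` with `E_GABA = RT/F * ln(Cl_i/Cl_out)` converted to
  the relative-to-rest scale via the stated absolute resting potential
  (`V_rest = -70 mV`). With `Cl_rest_high = 20 mM`, `E_GABA` for `E2`
  lies ~20 mV above rest, so inhibitory firing depolarizes `E2`.
  Chloride itself accumulates with rectified GABAergic driving force.

### The dynamical repertoire

Under the default parameters the unstimulated system is a relaxation
oscillator. A quiet phase (K_o recovering toward bath after the previous
discharge) is punctuated by noise-driven population bursts; each burst
releases K⁺; when enough K⁺ accumulates the network ignites into a
sustained tonic phase, then rhythmic clonic re-ignitions as depression and
the growing pump brake compete with the K⁺ drive; accumulated Na⁺ finally
activates the pump enough to terminate the event and hold the network
refractory while the ions recover. Because the strong K⁺ coupling removes
the quiescent fixed point, simulations start from a documented mildly
refractory state (`default_initial_state()`), not from a root-found
equilibrium; `find_resting_state()` (damped Newton on the derivative
field) still locates the fixed point for weakly coupled parameter sets and
warns when no equilibrium exists.

The three stimulation protocols are periodic pulse trains applied through
each population's input resistance. Partial opsin expression in
interneurons (`model2`) is treated mean-field: the amplitude is scaled by
`stimulated_fraction_I` (default 0.5; the experimental fraction is
unquantified, and duplicating the population adds state without adding
discriminating behaviour). The regime discrimination — pulses to all
populations suppress seizures by keeping Na⁺ elevated, pulses to
interneurons alone or hyperpolarizing pulses do not — is asserted by the
acceptance tests, with the canonical experiment (`run_lfls_experiment()`)
anchoring stimulation onset 5 s after a spontaneous seizure ends, as an
experimenter starting the light train between seizures would. The pulse
delivered within the first seconds of the postictal suppression can fail
to evoke a detectable discharge; the tests therefore accept one silent
pulse out of 70.

### Integration and noise

The system is integrated by a fixed-step Euler scheme (compiled, `src/`)
with additive Gaussian membrane noise per population. The noise is
realized as a piecewise-constant process on a fixed 1 ms grid: at the
default `dt = 1 ms` the scheme is exactly Euler–Maruyama, and any finer
`dt` that divides the grid integrates the *same* realized forcing. This
makes dt-refinement well-posed for a stochastic system: halving `dt`
refines the trajectory instead of drawing a new one, and the seizure
*count* on the reference 1200 s run is invariant (asserted). Individual
onset times are exponentially sensitive to the trajectory near ignition,
so single onsets can still shift by a few seconds under refinement; the
property test asserts count equality and a sub-second *median* onset
shift. The instability guard aborts with the first offending channel if
any |V| exceeds 500 mV or a concentration reaches zero.

### The default parameter set

The defaults in `network_params()` were tuned once, with
`scripts/tune_defaults.R`, against the study conditions: spontaneous
seizures of tens of seconds recurring every one to several minutes in the
control run; zero seizures and one evoked interictal discharge per pulse
under `model1`; persisting seizures under `model2`/`model3`; per-evoked-
discharge sodium increments of ~2 mM; and inter-discharge K_o under
stimulation elevated relative to the control's between-seizure K_o.
Potentials are relative to rest (mV), times in seconds, concentrations in
mM, stimulation in pA converted via `R_in` (megaohm). Values worth noting:

* `theta_Na = 40 mM`, `sigma_Na = 3 mM`: the pump's sodium operating
  point is high for a lumped model; it encodes the range over which
  *population-averaged* sodium must climb before termination, not a
  single-cell kinetic constant.
* `delta_K = 0.04 mM s`: large enough that the evoked discharges'
  potassium release outpaces the pump's 2:3 K⁺ drain during stimulation —
  this is what keeps K_o elevated in the interictal regime, as the
  K⁺-electrode experiments require.
* `noise_sigma = 4.5 mV` gives a stationary membrane fluctuation of
  ~3.2 mV (`noise_sigma / sqrt(2)`), setting the seizure recurrence
  statistics.

### The voltage-clamp observable

`I_vc` reconstructs the mixed postsynaptic current of a representative
`E1` neuron clamped at `V_hold` (default −30 mV; the experimental holding
potential after junction-potential correction, −27 mV, is a parameter):
AMPA and GABA conductances are exponential filters (5 and 10 ms) of the
depression-weighted excitatory rate and of the inhibitory rate, and the
current is `g_AMPA (V_hold - 0) + g_GABA (V_hold - E_GABA)`, outward
positive. The conductance scale is arbitrary (nS per unit rate); only
time course and contrast matter, and the contrast between discharges and
baseline is asserted in the tests.

## 2. Discharge detection

Detection is threshold-based: moving-RMS smoothing over 0.2 s (for
current-like channels; plain moving average for the one-sided rate
channels of the simulator), a 30 s running-median baseline, and a
threshold of 6 robust standard deviations (MAD) above the median of the
baseline-subtracted signal. Maximal supra-threshold runs closer than the
merge gap are merged; runs shorter than 0.05 s are dropped; events of at
least 10 s are classed ictal, shorter ones interictal. Two conventions
deserve justification:

* **The 10 s class boundary.** The preparation's ictal discharges last
  tens of seconds and its interictal discharges are sub-second; any
  boundary in between works, and 10 s is comfortably inside the gap.
* **The 3 s merge gap.** The clonic tail of a simulated seizure
  re-ignites every 2–3 s; a 1 s gap would split one seizure into several
  "events". 3 s unifies the seizure while staying well below the 5 s
  stimulation period (evoked interictal events last ~0.5 s, so
  consecutive evoked events are ~4.5 s apart and never merge).

Classification is a pure function of duration given the parameters, and
detection on small traces is equivalent to an exhaustive threshold-run
scan (both asserted).

## 3. Spike metrics

Spike thresholds follow the interpolated-dV/dt convention: central
differences at native sampling, upward crossings of 10 mV/ms located by
linear interpolation between the bracketing samples, 1 ms refractory
merge. Sampling coarser than 0.5 ms is refused. The firing-pattern
metrics are exact formula evaluations on threshold times (`IF1 = 1/(t2 -
t1)`, `CFAd = (t3 - t2)/(t2 - t1)`, `CSAd = (t_n - t_{n-1})/(t2 - t1)`),
estimated on the step whose rate (spike count over step duration, not
inverse mean ISI) is closest to half the series maximum, ties to the
lower stimulus level. Single-spike features use the first spike: APA
threshold-to-peak, APD as the interpolated width at half-maximal
amplitude, AHP from threshold to the most negative potential between the
peak and the next threshold or +50 ms — the window end is a convention
(the source procedure does not state one), as is the 1.0 mV steady
depolarization criterion behind the light-intensity threshold (mean over
the step excluding its first 100 ms, against a 100 ms pre-step baseline).

## 4. Potassium electrode pipeline

The electrode law is `[K]_o(t) = C_ref * exp(S * V(t))` with
`C_ref = 2.5 mM` at zero voltage; the published reference concentration is
retained even though the recording solution contains 3.5 mM KCl, and both
are exposed as parameters. Calibration regresses `ln(C / C_ref)` on
voltage *through the origin* — the law has no intercept, so a free
intercept would absorb exactly the miscalibration the fit is supposed to
measure. Transient statistics: per-event rise is the maximum from onset
to 2 s past offset minus the median over the 5 s before onset; baseline
elevation compares inter-event medians inside and outside the stimulation
window; recovery is the first post-stimulation time from which the
concentration stays within 0.2 mM of the pre-stimulation baseline for 5 s
(the published "recovered after" has no stated criterion; the band/hold
rule is this package's operationalization, and the generator's slow
component is parameterized so the default recovery target reproduces
itself under this rule).

## 5. Boltzmann dose-response fitting

The induction probability is the rising logistic
`P(LI) = 1 - 1/(1 + exp((LI - LI0)/Delta))`, evaluated through `plogis`
so both tails are exact at machine precision. Fitting is Bernoulli
maximum likelihood (the outcomes are binary; least squares on binned
proportions would mis-weight the tails): L-BFGS-B on `(LI0, log Delta)`
with `Delta` floored at 1e-4 so the likelihood stays finite under complete
separation — fits on the floor are flagged as boundary fits. The
"averaged" curve is the mean of per-slice parameters with SEMs, matching
the convention under which midpoint and slope are reported with standard
errors across slices; a pooled fit over all records is always returned
too, because a steep per-slice slope and a shallow pooled slope are both
legitimate summaries when midpoints vary across slices, and the data
cannot adjudicate which one a reader wants. An exhaustive likelihood-grid
search ships as the independent oracle.

## 6. The synthetic-data generator

Every generator is the documented inverse of a measurement operation, and
round-trip recovery is the master property of the whole pipeline:

* `gen_spike_train()` inverts the firing-pattern formulas exactly;
  intermediate intervals interpolate geometrically (keeps all intervals
  positive for any end ratio).
* `render_voltage_trace()` builds each spike from an analytic geometry —
  linear approach, an exponential "foot" whose slope reaches 10 mV/ms
  exactly at the scheduled time, quarter-sine rise, quarter-cosine fall
  solved so the half-amplitude width equals the requested APD — so
  detection and waveform features recover the configured values to <1%
  noise-free.
* `gen_discharge_trace()` renders interictal events as single biphasic
  0.3 s transients and ictal events as a tonic oscillation followed by
  clonic bursts at a rate decaying from 4 to 1.5 Hz (gaps stay below the
  merge gap, so a seizure detects as one event). Tonic/clonic amplitude
  ratios are free parameters with documented defaults; the published
  traces constrain them only graphically.
* `gen_electrode_trace()` composes per-event concentration transients
  (0.5 s ramp, hold for ictal events, exponential recovery) with a slow
  stimulation-window elevation, then converts to voltage via the
  electrode law and adds voltage-unit noise.
* `gen_dose_response()` draws Bernoulli outcomes from the Boltzmann curve
  with optional across-slice midpoint spread.

Defaults are parameterized from the reported experimental means
(fast-spiking: IF1 166 Hz, CFAd 1.14, CSAd 1.40, APA 70 mV, APD 0.56 ms,
AHP 19 mV; pyramidal: 59 Hz, 2.4, 4.3, 92 mV, 1.4 ms; potassium: 4.8 mM
ictal rise, 1.9 mM first flash, 1.5 mM per flash, 0.7 mM baseline
elevation, 27 s recovery; electrode S = 0.044/mV; Boltzmann LI0 = 0.40,
Delta = 0.007 % of maximum; Arch: 10.1 mV at 48%). The pyramidal AHP is
not reported; its 10 mV default is a conventional regular-spiking value.
What the generator does *not* emulate: biophysically realistic synaptic
kinetics, electrode drift, spike-shape variability, or sample-for-sample
agreement with the published recordings — passing round-trip tests shows
the pipeline is self-consistent and correctly implements its stated
conventions, not that it would extract identical numbers from raw
experimental files.

## 7. Problem sizes and limitations

The test suite runs the control simulation at 1200 s (with a half-step
replicate for the convergence check), the three protocol experiments at
~850 s each, dose-response recovery at 10 slices x 201 intensities x 50
draws, and spike round-trips at 50-100 kHz on 10-spike trains; the whole
suite completes in about two minutes on one core. Known limitations: the
rate reduction has no spatial structure (no discharge propagation), no
oxygen or volume dynamics, a single lumped inhibitory population, and a
pump whose sodium operating range is a population-level abstraction;
onset times of noise-ignited seizures are reproducible only under a fixed
seed and integration step, which is why regime-level statistics — counts,
durations, increments — are the quantities the package treats as its
results.
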