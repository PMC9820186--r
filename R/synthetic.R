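#' Reference parameter sets for the synthetic-data generators
#'
#' Named defaults mirroring the reported experimental means: regular-spiking
#' pyramidal and fast-spiking (parvalbumin) interneuron firing patterns and
#' spike waveforms, potassium transient amplitudes and recovery, electrode
#' calibration, Boltzmann dose-response parameters, archaerhodopsin
#' hyperpolarization, and light-intensity thresholds.
#'
#' The pyramidal afterhyperpolarization is not constrained by a reported
#' mean; its default (10 mV) is a conventional regular-spiking value.
#'
#' @return A named list of parameter lists.
#' @export
generator_defaults <- function() {
  list(
    pyramidal = list(IF1_Hz = 59, CFAd = 2.4, CSAd = 4.3,
                     APA_mV = 92, APD_ms = 1.4, AHP_mV = 10,
                     v_threshold_mV = -50, baseline_mV = -70),
    fast_spiking = list(IF1_Hz = 166, CFAd = 1.14, CSAd = 1.40,
                        APA_mV = 70, APD_ms = 0.56, AHP_mV = 19,
                        v_threshold_mV = -50, baseline_mV = -70),
    k_transients = list(ictal_rise_mM = 4.8, first_flash_rise_mM = 1.9,
                        per_flash_rise_mM = 1.5,
                        baseline_elevation_mM = 0.7,
                        recovery_s = 27, bath_mM = 3.5,
                        ramp_s = 0.5, tau_event_s = 0.45,
                        tau_ictal_s = 10),
    electrode = list(S = 0.044, C_ref = 2.5),
    dose_response = list(LI0 = 0.40, Delta = 0.007),
    arch = list(max_hyperpolarization_mV = 10.1, level_at_max = 48),
    light_thresholds = list(depolarization = 0.41, spiking = 0.68)
  )
}

#' Build a discharge event schedule
#'
#' @param class Character vector, `"ictal"` or `"interictal"` per event.
#' @param onset_s,duration_s Numeric vectors (s); events must not overlap,
#'   ictal durations must be at least 10 s and interictal at most 2 s.
#' @param amplitude Event amplitude in channel units (pA for current
#'   traces, mM for electrode traces); recycled.
#' @param tonic_fraction Fraction of each ictal event spent in the tonic
#'   phase; recycled.
#' @return A tibble of class `"event_schedule"` sorted by onset.
#' @export
event_schedule <- function(class, onset_s, duration_s, amplitude = 100,
                           tonic_fraction = 0.4) {
  stopifnot(length(class) == length(onset_s),
            length(onset_s) == length(duration_s))
  if (!all(class %in% c("ictal", "interictal"))) {
    abort("class must be 'ictal' or 'interictal'")
  }
  sched <- tibble(class = class, onset_s = onset_s,
                  duration_s = duration_s,
                  amplitude = rep_len(amplitude, length(class)),
                  tonic_fraction = rep_len(tonic_fraction, length(class)))
  sched <- arrange(sched, .data$onset_s)
  if (any(sched$duration_s[sched$class == "ictal"] < 10) ||
      any(sched$duration_s[sched$class == "interictal"] > 2)) {
    abort("durations inconsistent with class (ictal >= 10 s, interictal <= 2 s)")
  }
  off <- sched$onset_s + sched$duration_s
  if (nrow(sched) > 1 && any(sched$onset_s[-1] < off[-nrow(sched)])) {
    abort("events overlap")
  }
  structure(sched, class = c("event_schedule", class(sched)))
}

#' Generate spike times with prescribed adaptation metrics
#'
#' The constructed train is the exact inverse of [firing_pattern()]: the
#' first interspike interval is `1/IF1`, the second `CFAd/IF1`, the last
#' `CSAd/IF1`, and intermediate intervals interpolate geometrically between
#' the second and the last (geometric interpolation keeps every interval
#' positive for any positive ratio of end intervals).
#'
#' @param IF1_Hz First instantaneous frequency (Hz).
#' @param CFAd,CSAd Fast and slow adaptation coefficients.
#' @param n_spikes Number of spikes (at least 3; for exactly 3 the two
#'   coefficients must agree because the second interval is also the last).
#' @param t0 Time of the first spike (s).
#' @return Numeric vector of spike times (s).
#' @examples
#' firing_pattern(gen_spike_train(166, 1.14, 1.40, 10))
#' @export
gen_spike_train <- function(IF1_Hz, CFAd, CSAd, n_spikes, t0 = 0) {
  stopifnot(IF1_Hz > 0, CFAd > 0, CSAd > 0)
  if (n_spikes < 3) abort("n_spikes must be at least 3")
  isi1 <- 1 / IF1_Hz
  if (n_spikes == 3) {
    if (abs(CSAd - CFAd) > 1e-12) {
      abort("with 3 spikes the second interval is also the last: CFAd must equal CSAd")
    }
    isis <- c(isi1, CFAd * isi1)
  } else {
    isi2 <- CFAd * isi1
    isi_last <- CSAd * isi1
    k <- seq(0, n_spikes - 3)
    mid <- isi2 * (isi_last / isi2)^(k / (n_spikes - 3))
    isis <- c(isi1, mid)
  }
  t0 + cumsum(c(0, isis))
}

# analytic spike waveform geometry shared by the renderers:
# linear depolarizing ramp -> exponential "foot" whose slope reaches the
# detection threshold (10 mV/ms) exactly at the spike time -> quarter-sine
# rise to the peak -> quarter-cosine fall to threshold - AHP, with the fall
# time solved so the half-amplitude width equals APD.
waveform_geometry <- function(APA_mV, APD_ms, AHP_mV, thr_slope = 10) {
  T_r <- min(0.3 * APD_ms, 0.5)               # rise time, ms
  t_half_up <- T_r / 3                        # sin(pi/6) = 1/2
  w_half <- APD_ms - (T_r - t_half_up)
  if (w_half <= 0) abort("APD too short for the rise-time convention")
  r <- (APA_mV / 2 + AHP_mV) / (APA_mV + AHP_mV)
  T_f2 <- w_half * pi / (2 * acos(r))         # fall time, ms
  list(T_r = T_r, T_f2 = T_f2, T_foot = 1, tau_foot = 0.1,
       foot_drop = thr_slope * 0.1 * (1 - exp(-1 / 0.1)),
       thr_slope = thr_slope)
}

#' Render a spike train as a voltage trace
#'
#' Each spike is a stereotyped waveform honouring the requested amplitude
#' (threshold to peak), duration at half-maximal amplitude, and
#' afterhyperpolarization; the depolarizing approach to each threshold is
#' shaped so the interpolated dV/dt reaches 10 mV/ms exactly at the
#' scheduled spike time, making the trace an exact inverse of
#' [detect_spikes()] plus [waveform_features()] in the noise-free case.
#'
#' @param train Numeric spike times (s) from [gen_spike_train()], or a
#'   `spike_train` tibble.
#' @param waveform List with `APA_mV`, `APD_ms`, `AHP_mV`,
#'   `v_threshold_mV`, `baseline_mV` (see [generator_defaults()]).
#' @param fs Sampling rate (Hz, at least 20 kHz).
#' @param duration Total trace duration (s); defaults to the train span
#'   plus padding.
#' @param noise_sd Gaussian noise SD (mV).
#' @param seed Seed for the noise (required when `noise_sd > 0`).
#' @return Tibble with `time_s`, `v_mV`.
#' @export
render_voltage_trace <- function(train,
                                 waveform = generator_defaults()$fast_spiking,
                                 fs = 50000,
                                 duration = NULL,
                                 noise_sd = 0,
                                 seed = NULL) {
  if (fs < 20000) abort("fs must be at least 20 kHz")
  times <- spike_times(train)
  pad <- 0.15
  duration <- duration %||%
    (if (length(times)) max(times) + pad else 2 * pad)
  t <- seq(0, duration, by = 1 / fs)
  v <- rep(waveform$baseline_mV, length(t))
  if (length(times) > 0) {
    v <- render_spikes_onto(v, t, times, waveform)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) abort("`seed` is required when noise_sd > 0")
    set.seed(seed)
    v <- v + rnorm(length(v), 0, noise_sd)
  }
  tibble(time_s = t, v_mV = v)
}

render_spikes_onto <- function(v, t, times, wf) {
  geo <- waveform_geometry(wf$APA_mV, wf$APD_ms, wf$AHP_mV)
  ms <- 1e-3
  v_th <- wf$v_threshold_mV
  v_min <- v_th - wf$AHP_mV
  cur_t <- t[1]
  cur_v <- v[1]
  assign_seg <- function(from, to, fun) {
    sel <- which(t >= from & t < to)
    if (length(sel)) v[sel] <<- fun(t[sel])
    invisible(NULL)
  }
  for (i in seq_along(times)) {
    ti <- times[i]
    foot_start <- ti - geo$T_foot * ms
    ramp_len <- foot_start - cur_t
    ramp_dv <- (v_th - geo$foot_drop) - cur_v
    if (ramp_len <= 0 ||
        ramp_dv / (ramp_len / ms) >= 0.95 * geo$thr_slope) {
      abort(sprintf("spike spacing shorter than the waveform support near t = %.4f s", ti))
    }
    slope <- ramp_dv / ramp_len
    v0 <- cur_v
    t0 <- cur_t
    assign_seg(cur_t, foot_start, function(u) v0 + slope * (u - t0))
    # foot: dV/dt = thr_slope * exp((u - ti)/tau_foot), reaching the
    # detection threshold exactly at ti
    assign_seg(foot_start, ti, function(u) {
      v_th - geo$thr_slope * geo$tau_foot *
        (1 - exp(((u - ti) / ms) / geo$tau_foot))
    })
    t_pk <- ti + geo$T_r * ms
    assign_seg(ti, t_pk, function(u) {
      v_th + wf$APA_mV * sin(pi * ((u - ti) / ms) / (2 * geo$T_r))
    })
    t_end <- t_pk + geo$T_f2 * ms
    assign_seg(t_pk, t_end, function(u) {
      v_min + (wf$APA_mV + wf$AHP_mV) *
        cos(pi * ((u - t_pk) / ms) / (2 * geo$T_f2))
    })
    cur_t <- t_end
    cur_v <- v_min
  }
  # after the last spike: hold at the AHP minimum through the measurement
  # window, then relax to baseline
  hold_end <- cur_t + 0.06
  assign_seg(cur_t, hold_end, function(u) v_min)
  assign_seg(hold_end, t[length(t)] + 1, function(u) {
    wf$baseline_mV + (v_min - wf$baseline_mV) * exp(-(u - hold_end) / 0.01)
  })
  v
}

#' Generate a synaptic-current trace containing scheduled discharges
#'
#' Interictal events are single brief biphasic transients; ictal events have
#' a tonic segment (sustained high-amplitude oscillation) followed by clonic
#' bursts whose rate decays towards the event end, mimicking the classic
#' tonic-clonic structure.
#'
#' @param schedule An [event_schedule()]; amplitudes in pA.
#' @param fs Sampling rate (Hz).
#' @param duration Trace duration (s); defaults to span plus padding.
#' @param noise_sd Gaussian noise SD (pA).
#' @param seed Seed for the noise.
#' @return Tibble with `time_s`, `i_pA`.
#' @export
gen_discharge_trace <- function(schedule, fs = 1000, duration = NULL,
                                noise_sd = 5, seed = 1) {
  stopifnot(inherits(schedule, "event_schedule"))
  pad <- 40
  duration <- duration %||%
    (if (nrow(schedule)) max(schedule$onset_s + schedule$duration_s) + pad
     else 2 * pad)
  t <- seq(0, duration, by = 1 / fs)
  x <- numeric(length(t))

  biphasic <- function(u, width, A) {
    # one down-up cycle confined to [0, width]
    ifelse(u >= 0 & u < width, -A * sin(2 * pi * u / width), 0)
  }
  for (i in seq_len(nrow(schedule))) {
    on <- schedule$onset_s[i]
    dur <- schedule$duration_s[i]
    A <- schedule$amplitude[i]
    if (schedule$class[i] == "interictal") {
      u <- t - on
      x <- x + biphasic(u, min(0.3, dur), A)
    } else {
      d_tonic <- schedule$tonic_fraction[i] * dur
      sel <- t >= on & t < on + d_tonic
      u <- t[sel] - on
      x[sel] <- x[sel] - 0.3 * A + A * sin(2 * pi * 10 * u)
      # clonic bursts at a rate decaying from 4 to 1.5 Hz
      d_clon <- dur - d_tonic
      bt <- on + d_tonic
      rate <- 4
      while (bt < on + dur - 0.15) {
        u <- t - bt
        decay <- 1 - 0.4 * (bt - on - d_tonic) / d_clon
        x <- x + biphasic(u, 0.15, A * decay)
        rate <- 4 - 2.5 * (bt - on - d_tonic) / d_clon
        bt <- bt + 1 / rate
      }
    }
  }
  set.seed(seed)
  x <- x + rnorm(length(x), 0, noise_sd)
  tibble(time_s = t, i_pA = x)
}

#' Generate a potassium-electrode voltage trace from an event schedule
#'
#' Builds the concentration signal — baseline plus per-event transients
#' (0.5 s ramp to the scheduled rise, held for ictal events until offset,
#' then exponential recovery) plus a slow baseline-elevation component
#' inside the stimulation window — and converts it to electrode voltage
#' through the exponential electrode law, adding noise in voltage units.
#'
#' @param schedule An [event_schedule()] whose `amplitude` column holds the
#'   per-event concentration rise (mM).
#' @param k_params Kinetics: list with `ramp_s`, `tau_event_s` (interictal
#'   recovery), `tau_ictal_s` (ictal recovery), `baseline_elevation_mM`,
#'   `recovery_s`, `bath_mM` (see [generator_defaults()]`$k_transients`).
#' @param stim_window Optional `c(from, to)` (s): the slow baseline
#'   elevation rises inside this window and decays after it with the time
#'   constant implied by `recovery_s` (the time at which the decaying
#'   elevation re-enters a 0.2 mM band around baseline).
#' @param cal A [k_calibration()].
#' @param fs Sampling rate (Hz).
#' @param duration Trace duration (s).
#' @param noise_sd Voltage noise SD (mV).
#' @param seed Seed for the noise.
#' @return Tibble with `time_s`, `voltage_mV`; the underlying concentration
#'   is recoverable with [k_voltage_to_conc()].
#' @export
gen_electrode_trace <- function(schedule,
                                k_params = generator_defaults()$k_transients,
                                stim_window = NULL,
                                cal = k_calibration(),
                                fs = 100,
                                duration = NULL,
                                noise_sd = 0.3,
                                seed = 1) {
  stopifnot(inherits(schedule, "event_schedule"))
  pad <- 60
  duration <- duration %||%
    (if (nrow(schedule)) max(schedule$onset_s + schedule$duration_s) + pad
     else 2 * pad)
  t <- seq(0, duration, by = 1 / fs)
  C <- rep(k_params$bath_mM, length(t))

  for (i in seq_len(nrow(schedule))) {
    on <- schedule$onset_s[i]
    off <- on + schedule$duration_s[i]
    A <- schedule$amplitude[i]
    tau <- if (schedule$class[i] == "ictal") k_params$tau_ictal_s
           else k_params$tau_event_s
    ramp_end <- min(on + k_params$ramp_s, off + k_params$ramp_s)
    hold_end <- max(ramp_end, off)
    shape <- numeric(length(t))
    sel <- t >= on & t < ramp_end
    shape[sel] <- A * (t[sel] - on) / (ramp_end - on)
    shape[t >= ramp_end & t < hold_end] <- A
    sel <- t >= hold_end
    shape[sel] <- A * exp(-(t[sel] - hold_end) / tau)
    C <- C + shape
  }
  if (!is.null(stim_window)) {
    elev <- k_params$baseline_elevation_mM
    tau_slow <- k_params$recovery_s / log(max(elev, 0.21) / 0.2)
    sel_in <- t >= stim_window[1] & t < stim_window[2]
    C[sel_in] <- C[sel_in] +
      elev * (1 - exp(-(t[sel_in] - stim_window[1]) / tau_slow))
    sel_post <- t >= stim_window[2]
    e_end <- elev * (1 - exp(-diff(stim_window) / tau_slow))
    C[sel_post] <- C[sel_post] +
      e_end * exp(-(t[sel_post] - stim_window[2]) / tau_slow)
  }
  if (any(C <= 0)) abort("parameters produce non-positive concentration")
  V <- k_conc_to_voltage(C, cal)
  if (noise_sd > 0) {
    set.seed(seed)
    V <- V + rnorm(length(V), 0, noise_sd)
  }
  tibble(time_s = t, voltage_mV = V)
}

#' Generate Bernoulli dose-response outcomes from a Boltzmann curve
#'
#' Per slice, the midpoint is drawn as `LI0 + Normal(0, slice_midpoint_sd)`
#' and every light intensity on the grid receives `n_per_li` Bernoulli draws
#' with success probability [boltzmann_p()].
#'
#' @param li_grid Light intensities (percent of maximum).
#' @param LI0,Delta Boltzmann parameters of the generating curve.
#' @param n_per_li Bernoulli trials per grid point and slice.
#' @param n_slices Number of slices.
#' @param slice_midpoint_sd Across-slice midpoint SD (percent of maximum).
#' @param seed Seed.
#' @return Tibble with `slice_id`, `li_percent`, `outcome` (0/1).
#' @export
gen_dose_response <- function(li_grid = seq(0.30, 0.50, by = 0.001),
                              LI0 = 0.40, Delta = 0.007,
                              n_per_li = 50, n_slices = 10,
                              slice_midpoint_sd = 0, seed = 42) {
  stopifnot(n_per_li >= 1, n_slices >= 1)
  set.seed(seed)
  out <- map(seq_len(n_slices), function(s) {
    mid <- LI0 + rnorm(1, 0, slice_midpoint_sd)
    li <- rep(li_grid, each = n_per_li)
    tibble(
      slice_id = sprintf("slice%02d", s),
      li_percent = li,
      outcome = stats::rbinom(length(li), 1, boltzmann_p(li, mid, Delta))
    )
  })
  list_rbind(out)
}

#' Generate a stimulus-step response series
#'
#' Builds sub- and supra-threshold voltage responses so the measurement
#' operations recover the configured values: for `kind = "light"`, steady
#' depolarization appears from the configured depolarization threshold and
#' spiking from the spiking threshold; for `kind = "arch"`, steady
#' hyperpolarization follows a bell-shaped intensity dependence peaking at
#' the configured level; for `kind = "current"`, spike trains whose rates
#' grow with the step amplitude.
#'
#' @param kind `"current"`, `"light"` or `"arch"`.
#' @param levels Stimulus levels (pA or percent of maximum).
#' @param defaults The [generator_defaults()] list (or a modified copy).
#' @param rates_Hz For `kind = "current"`: firing rate per level (Hz).
#' @param fs Sampling rate (Hz).
#' @param seed Seed (noise-free traces are returned when `noise_sd = 0`).
#' @param noise_sd Voltage noise SD (mV).
#' @return A [step_series()].
#' @export
gen_step_series <- function(kind = c("current", "light", "arch"),
                            levels = NULL,
                            defaults = generator_defaults(),
                            rates_Hz = NULL,
                            fs = 50000,
                            seed = 1,
                            noise_sd = 0) {
  kind <- arg_match(kind)
  t_on <- 0.2
  step_dur <- if (kind == "current") 1.5 else 1.0
  total <- t_on + step_dur + 0.2
  base <- -70

  if (kind == "current") {
    levels <- levels %||% c(50, 100, 150, 200)
    rates_Hz <- rates_Hz %||% c(0, 10, 20, 40)
    stopifnot(length(rates_Hz) == length(levels))
    wf <- defaults$pyramidal
    traces <- map2(levels, rates_Hz, function(lv, r) {
      n_sp <- round(r * step_dur)
      if (n_sp < 3) {
        return(render_voltage_trace(numeric(0), wf, fs = fs,
                                    duration = total,
                                    noise_sd = noise_sd, seed = seed))
      }
      train <- gen_spike_train(max(r * 2, 3 / step_dur), wf$CFAd, wf$CSAd,
                               n_sp, t0 = 0)
      # rescale to occupy 80% of the step (ratios, hence counts, preserved)
      train <- t_on + 0.02 + train * (0.8 * step_dur / max(max(train), 1e-6))
      render_voltage_trace(train, wf, fs = fs, duration = total,
                           noise_sd = noise_sd, seed = seed)
    })
  } else if (kind == "light") {
    thr <- defaults$light_thresholds
    # default grid includes the configured thresholds so they are
    # recoverable exactly (thresholds are reported at grid resolution)
    levels <- levels %||%
      sort(unique(c(seq(0.1, 1.0, by = 0.1),
                    thr$depolarization, thr$spiking)))
    wf <- defaults$pyramidal
    traces <- map(levels, function(lv) {
      depol <- if (lv >= thr$depolarization - 1e-9) {
        1.2 + 8 * max(0, lv - thr$depolarization) /
          max(thr$spiking - thr$depolarization, 1e-6)
      } else 0
      spiking <- lv >= thr$spiking - 1e-9
      if (spiking) {
        n_sp <- 4 + round(5 * (lv - thr$spiking) /
                            max(1 - thr$spiking, 1e-6))
        train <- gen_spike_train(20, 1.5, 2, max(n_sp, 4),
                                 t0 = t_on + 0.15)
        wf2 <- modifyList(wf, list(baseline_mV = base + depol))
        tr <- render_voltage_trace(train, wf2, fs = fs, duration = total,
                                   noise_sd = noise_sd, seed = seed)
        out <- t_on <= tr$time_s & tr$time_s < t_on + step_dur
        tr$v_mV[!out] <- base
        tr
      } else {
        t <- seq(0, total, by = 1 / fs)
        v <- rep(base, length(t))
        v[t >= t_on & t < t_on + step_dur] <- base + depol
        if (noise_sd > 0) {
          set.seed(seed)
          v <- v + rnorm(length(v), 0, noise_sd)
        }
        tibble(time_s = t, v_mV = v)
      }
    })
  } else {
    levels <- levels %||% c(8, 18, 28, 38, 48, 58, 68, 78, 88)
    peak <- defaults$arch$max_hyperpolarization_mV
    l_max <- defaults$arch$level_at_max
    traces <- map(levels, function(lv) {
      dv <- peak * exp(-((lv - l_max) / 35)^2)
      t <- seq(0, total, by = 1 / fs)
      v <- rep(base, length(t))
      v[t >= t_on & t < t_on + step_dur] <- base - dv
      if (noise_sd > 0) {
        set.seed(seed)
        v <- v + rnorm(length(v), 0, noise_sd)
      }
      tibble(time_s = t, v_mV = v)
    })
  }
  step_series(tibble(level = levels, trace = traces), kind = kind,
              t_on = t_on, step_duration = step_dur)
}
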