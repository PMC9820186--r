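#' Run the canonical low-frequency stimulation experiment
#'
#' Reproduces the in-silico counterpart of the slice experiment: a control
#' simulation is run first, the stimulation onset is placed shortly after
#' the end of a spontaneous ictal discharge (as an experimenter would start
#' the light train between seizures), and the chosen protocol is applied
#' for `stim_duration` seconds with a post-stimulation observation period.
#'
#' @param model `"model1"` (depolarizing pulses to all populations),
#'   `"model2"` (depolarizing pulses to half the inhibitory population) or
#'   `"model3"` (hyperpolarizing pulses to the excitatory populations).
#' @param params A [network_params()].
#' @param seed Noise seed shared by the control and stimulated runs, so the
#'   two trajectories are identical up to stimulation onset.
#' @param lag Delay (s) between the reference ictal offset and stimulation
#'   onset.
#' @param after_event Which spontaneous ictal discharge of the control run
#'   anchors the stimulation onset.
#' @param stim_duration Stimulation window length (s); 350 s at 0.2 Hz
#'   delivers 70 pulses.
#' @param post Post-stimulation observation time (s).
#' @param detection [detection_params()] used for event detection on the
#'   excitatory rate channel.
#' @return A list of class `"lfls_experiment"`: `trace`, `events`,
#'   `protocol`, `window` (`c(from, to)` of the stimulation), `summary`
#'   (the [regime_summary()] of the window), `n_pulses`,
#'   `post_stim_latency_s`, and the `control` trace/events.
#' @export
run_lfls_experiment <- function(model = c("model1", "model2", "model3"),
                                params = network_params(),
                                seed = 1,
                                lag = 5,
                                after_event = 2,
                                stim_duration = 350,
                                post = 200,
                                detection = detection_params(
                                  rectify = "positive")) {
  model <- arg_match(model)
  ctl <- simulate_network(params, NULL, duration = 600, seed = seed)
  ctl_ev <- detect_discharges(ctl, "rate_E", detection)
  ict <- ctl_ev[ctl_ev$class == "ictal", ]
  if (nrow(ict) < after_event) {
    abort("control run produced too few ictal discharges to anchor the protocol")
  }
  t0 <- ict$offset_s[after_event] + lag
  protocol <- stim_protocol(model, t_start = t0, t_stop = t0 + stim_duration)
  trace <- simulate_network(params, protocol,
                            duration = t0 + stim_duration + post,
                            seed = seed)
  events <- detect_discharges(trace, "rate_E", detection)
  window <- c(t0, t0 + stim_duration)
  # detection smoothing can place an evoked onset ~0.1 s before its pulse,
  # so the summary window opens 1 s early to keep the first pulse inside
  structure(
    list(trace = trace, events = events, protocol = protocol,
         window = window,
         summary = regime_summary(events, c(window[1] - 1, window[2])),
         n_pulses = floor(stim_duration * protocol$frequency),
         post_stim_latency_s = event_latency_after(events, window[2]),
         control = list(trace = ctl, events = ctl_ev)),
    class = "lfls_experiment"
  )
}

#' @export
print.lfls_experiment <- function(x, ...) {
  cat(sprintf("<lfls_experiment> %s, %d pulses over [%.0f, %.0f) s\n",
              x$protocol$preset, x$n_pulses, x$window[1], x$window[2]))
  print(x$summary)
  cat(sprintf("  post-stimulation ictal latency: %s s\n",
              format(x$post_stim_latency_s)))
  invisible(x)
}

#' Per-pulse intracellular sodium rise
#'
#' For every stimulus pulse, the rise of `Na_i` from pulse onset to its
#' local maximum within `search_s` seconds — the sodium increment of the
#' evoked interictal discharge that feeds Na-K pump activation.
#'
#' @param trace A `"network_sim"` tibble containing an `Na_i` channel.
#' @param protocol The [stim_protocol()] that was applied.
#' @param search_s Search window after each pulse onset (s).
#' @return A tibble with `pulse_time_s` and `na_rise_mM`.
#' @export
sodium_rise_per_pulse <- function(trace, protocol, search_s = 4) {
  stopifnot(inherits(protocol, "stim_protocol"))
  t_stop <- min(protocol$t_stop, max(trace$time_s))
  pulses <- seq(protocol$t_start, t_stop - 1e-9, by = 1 / protocol$frequency)
  rises <- map_dbl(pulses, function(tp) {
    seg <- trace$Na_i[trace$time_s >= tp & trace$time_s <= tp + search_s]
    max(seg) - seg[1]
  })
  tibble(pulse_time_s = pulses, na_rise_mM = rises)
}
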