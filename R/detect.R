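#' Detection parameters for epileptiform events
#'
#' Threshold-based detection: the channel is smoothed with a moving RMS,
#' a slow running-median baseline is subtracted, and events are maximal runs
#' where the deviation exceeds `k_mad` robust standard deviations.  Runs
#' closer than `merge_gap` are merged; runs shorter than
#' `min_interictal_duration` are dropped; runs lasting at least
#' `min_ictal_duration` are classed ictal, shorter ones interictal.  Ictal
#' discharges in this preparation last tens of seconds while interictal
#' discharges are sub-second transients, so the default 10 s boundary
#' separates the two cleanly.
#'
#' @param smoothing_window Moving-RMS window (s).
#' @param baseline_window Running-median baseline window (s).
#' @param k_mad Threshold in MAD units of the baseline-subtracted signal.
#' @param merge_gap Runs separated by less than this (s) are merged; the
#'   default is matched to the interval between clonic bursts in the tail of
#'   an ictal discharge so one seizure is reported as one event, while
#'   staying well below the 5 s period of the stimulation protocols.
#' @param min_interictal_duration Minimum event duration (s).
#' @param min_ictal_duration Duration (s) at and above which an event is
#'   classed ictal.
#' @param rectify `"abs"` to detect deviations of either sign (current-like
#'   channels), `"positive"` to detect upward deviations only (rate
#'   channels).
#' @return A list of class `"detection_params"`.
#' @export
detection_params <- function(smoothing_window = 0.2,
                             baseline_window = 30,
                             k_mad = 6,
                             merge_gap = 3,
                             min_interictal_duration = 0.05,
                             min_ictal_duration = 10,
                             rectify = c("abs", "positive")) {
  rectify <- arg_match(rectify)
  stopifnot(
    smoothing_window > 0, baseline_window > 0, k_mad > 0, merge_gap > 0,
    min_interictal_duration > 0,
    min_ictal_duration > min_interictal_duration
  )
  structure(
    list(smoothing_window = smoothing_window,
         baseline_window = baseline_window, k_mad = k_mad,
         merge_gap = merge_gap,
         min_interictal_duration = min_interictal_duration,
         min_ictal_duration = min_ictal_duration, rectify = rectify),
    class = "detection_params"
  )
}

check_uniform_time <- function(time_s, rel_tol = 1e-6) {
  dt <- diff(time_s)
  if (length(dt) == 0 || any(dt <= 0)) {
    abort("time axis must be strictly increasing")
  }
  bad <- which(abs(dt - dt[1]) > rel_tol * dt[1])
  if (length(bad) > 0) {
    abort(sprintf("non-uniform time axis (first offending index %d)",
                  bad[1] + 1),
          class = "ictalsim_time_error")
  }
  dt[1]
}

moving_rms <- function(x, w) {
  if (w <= 1) return(abs(x))
  kern <- rep(1 / w, w)
  sq <- stats::filter(x^2, kern, sides = 2)
  # pad the filter's NA margins with the nearest interior value
  sq <- as.numeric(sq)
  first_ok <- which(!is.na(sq))[1]
  last_ok <- tail(which(!is.na(sq)), 1)
  sq[seq_len(first_ok - 1)] <- sq[first_ok]
  if (last_ok < length(sq)) sq[(last_ok + 1):length(sq)] <- sq[last_ok]
  sqrt(pmax(sq, 0))
}

running_median <- function(x, w) {
  w <- min(w, length(x))
  if (w %% 2 == 0) w <- w - 1
  if (w < 3) return(rep(median(x), length(x)))
  runmed(x, w, endrule = "median")
}

#' Detect and classify epileptiform discharges
#'
#' @param trace A data frame with a `time_s` column (uniformly sampled) and
#'   the channel named by `channel`.
#' @param channel Column to analyse; defaults to `"rate_E"` for simulation
#'   traces, otherwise the first non-time column.
#' @param params A [detection_params()].  Rate channels of
#'   [simulate_network()] are detected one-sided on the raw signal; for
#'   current-like channels use the default two-sided `rectify = "abs"`.
#' @return A tibble of class `"discharge_events"` with columns `onset_s`,
#'   `offset_s`, `duration_s`, `class` (`"ictal"`/`"interictal"`) and
#'   `peak` (maximum absolute deviation of the smoothed signal, in channel
#'   units), sorted by onset and non-overlapping.
#' @export
detect_discharges <- function(trace, channel = NULL,
                              params = detection_params()) {
  stopifnot(is.data.frame(trace), inherits(params, "detection_params"))
  if (!"time_s" %in% names(trace)) abort("trace must have a `time_s` column")
  channel <- channel %||%
    (if ("rate_E" %in% names(trace)) "rate_E" else
       setdiff(names(trace), "time_s")[1])
  if (!channel %in% names(trace)) {
    abort(sprintf("channel `%s` not found in trace", channel))
  }
  dt <- check_uniform_time(trace$time_s)
  x <- trace[[channel]]
  w_s <- max(1L, round(params$smoothing_window / dt))
  if (length(x) <= w_s) abort("trace shorter than the smoothing window")

  smooth <- if (params$rectify == "abs") {
    moving_rms(x - running_median(x, round(params$baseline_window / dt)), w_s)
  } else {
    sm <- as.numeric(stats::filter(x, rep(1 / w_s, w_s), sides = 2))
    sm[is.na(sm)] <- x[is.na(sm)]
    sm - running_median(sm, round(params$baseline_window / dt))
  }
  thr <- params$k_mad * mad(smooth, center = median(smooth))
  above <- smooth > median(smooth) + thr

  events <- runs_to_events(above, trace$time_s, dt, smooth, params)
  class(events) <- c("discharge_events", class(tibble()))
  attr(events, "channel") <- channel
  attr(events, "params") <- params
  events
}

# maximal TRUE runs -> merged, filtered, classified event table
runs_to_events <- function(above, time_s, dt, smooth, params) {
  empty <- tibble(onset_s = numeric(), offset_s = numeric(),
                  duration_s = numeric(), class = character(),
                  peak = numeric())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(empty)
  on_idx <- starts[keep]
  off_idx <- ends[keep]
  onset <- time_s[on_idx]
  offset <- time_s[off_idx] + dt

  # merge runs separated by less than merge_gap
  if (length(onset) > 1) {
    gap <- onset[-1] - offset[-length(offset)]
    grp <- factor(cumsum(c(1, gap >= params$merge_gap)))
    onset <- unname(vapply(split(onset, grp), min, numeric(1)))
    offset <- unname(vapply(split(offset, grp), max, numeric(1)))
    on_idx <- unname(vapply(split(on_idx, grp), min, numeric(1)))
    off_idx <- unname(vapply(split(off_idx, grp), max, numeric(1)))
  }
  dur <- offset - onset
  sel <- dur >= params$min_interictal_duration
  if (!any(sel)) return(empty)
  peak <- mapply(function(a, b) max(abs(smooth[a:b])),
                 on_idx[sel], off_idx[sel])
  tibble(
    onset_s = as.numeric(onset[sel]),
    offset_s = as.numeric(offset[sel]),
    duration_s = as.numeric(dur[sel]),
    class = ifelse(dur[sel] >= params$min_ictal_duration,
                   "ictal", "interictal"),
    peak = as.numeric(peak)
  )
}

#' Latency of the first ictal event after a time point
#'
#' After low-frequency stimulation ends, ictal discharges reappear with a
#' finite latency; this measures it.
#'
#' @param events A `discharge_events` tibble (sorted by onset).
#' @param t0 Reference time (s).
#' @return Latency (s) of the first ictal onset at or after `t0`, or `NA`
#'   if there is none.
#' @export
event_latency_after <- function(events, t0) {
  stopifnot(is.data.frame(events))
  ict <- events$onset_s[events$class == "ictal" & events$onset_s >= t0]
  if (length(ict) == 0) return(NA_real_)
  min(ict) - t0
}

#' Percent change between two positive quantities
#'
#' @param before,after Positive values (e.g. mean ictal durations).
#' @return `100 * (after - before) / before`.
#' @examples
#' percent_change(56, 106)  # ~89%
#' @export
percent_change <- function(before, after) {
  if (any(before <= 0)) abort("`before` must be positive")
  100 * (after - before) / before
}

#' Summarize the discharge regime within a time window
#'
#' @param events A `discharge_events` tibble.
#' @param window Numeric length-2 `c(from, to)` in seconds; events are
#'   included if their onset falls inside the window.
#' @return A one-row tibble with `window_from`, `window_to`, `n_ictal`,
#'   `n_interictal`, `mean_ictal_duration_s`, `sem_ictal_duration_s`,
#'   `mean_interictal_interval_s` (between consecutive ictal onsets) and a
#'   `regime` label: `"silent"`, `"interictal"` (interictal events only),
#'   `"ictal"` (ictal events only) or `"mixed"`.
#' @export
regime_summary <- function(events, window) {
  stopifnot(is.data.frame(events), length(window) == 2)
  if (window[2] <= window[1]) abort("empty window")
  ev <- events[events$onset_s >= window[1] & events$onset_s < window[2], ]
  ict <- ev$duration_s[ev$class == "ictal"]
  n_ict <- length(ict)
  n_iid <- sum(ev$class == "interictal")
  regime <- if (n_ict == 0 && n_iid == 0) "silent"
    else if (n_ict == 0) "interictal"
    else if (n_iid == 0) "ictal"
    else "mixed"
  onsets <- sort(ev$onset_s[ev$class == "ictal"])
  tibble(
    window_from = window[1], window_to = window[2],
    n_ictal = n_ict, n_interictal = n_iid,
    mean_ictal_duration_s = if (n_ict > 0) mean(ict) else NA_real_,
    sem_ictal_duration_s = if (n_ict > 1) sd(ict) / sqrt(n_ict) else NA_real_,
    mean_interictal_interval_s =
      if (n_ict > 1) mean(diff(onsets)) else NA_real_,
    regime = regime
  )
}
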