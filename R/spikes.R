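#' Detect action potentials by interpolated dV/dt threshold
#'
#' A spike threshold is the point at which the interpolated rate of voltage
#' increase reaches `dvdt_threshold` (10 mV/ms by convention).  dV/dt is
#' computed by central differences at the native sampling; each upward
#' crossing of the threshold is located by linear interpolation between the
#' bracketing samples, crossings within 1 ms of the previous accepted spike
#' are merged, and the spike peak is the voltage maximum before the next
#' threshold.
#'
#' @param trace Data frame with `time_s` and a voltage column `v_mV`
#'   (uniformly sampled; the sampling interval must not exceed 0.5 ms).
#' @param dvdt_threshold Threshold rate of rise (mV/ms).
#' @return A tibble of class `"spike_train"` with one row per spike:
#'   `t_s` (interpolated threshold time), `v_threshold_mV` (interpolated
#'   threshold potential), `t_peak_s`, `v_peak_mV`.
#' @export
detect_spikes <- function(trace, dvdt_threshold = 10) {
  stopifnot(is.data.frame(trace))
  if (!all(c("time_s", "v_mV") %in% names(trace))) {
    abort("trace must have `time_s` and `v_mV` columns")
  }
  dt <- check_uniform_time(trace$time_s)
  if (dt > 0.5e-3 + 1e-12) {
    abort("sampling too coarse to resolve dV/dt (interval > 0.5 ms)")
  }
  v <- trace$v_mV
  t <- trace$time_s
  n <- length(v)
  # central-difference dV/dt in mV/ms
  dvdt <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt * 1000), NA)

  cross <- which(dvdt[-n] < dvdt_threshold & dvdt[-1] >= dvdt_threshold)
  cross <- cross[!is.na(dvdt[cross]) & !is.na(dvdt[cross + 1])]
  empty <- tibble(t_s = numeric(), v_threshold_mV = numeric(),
                  t_peak_s = numeric(), v_peak_mV = numeric())
  if (length(cross) == 0) {
    return(structure(empty, class = c("spike_train", class(empty))))
  }
  frac <- (dvdt_threshold - dvdt[cross]) / (dvdt[cross + 1] - dvdt[cross])
  t_thr <- t[cross] + frac * dt
  v_thr <- v[cross] + frac * (v[cross + 1] - v[cross])

  # 1 ms refractory merge
  keep <- c(TRUE, diff(t_thr) > 1e-3)
  t_thr <- t_thr[keep]; v_thr <- v_thr[keep]; idx <- cross[keep]

  m <- length(t_thr)
  t_peak <- v_peak <- numeric(m)
  for (i in seq_len(m)) {
    to <- if (i < m) idx[i + 1] else n
    seg <- idx[i]:to
    j <- seg[which.max(v[seg])]
    t_peak[i] <- t[j]
    v_peak[i] <- v[j]
  }
  out <- tibble(t_s = t_thr, v_threshold_mV = v_thr,
                t_peak_s = t_peak, v_peak_mV = v_peak)
  structure(out, class = c("spike_train", class(out)))
}

spike_times <- function(train) {
  if (is.numeric(train)) return(sort(train))
  stopifnot(is.data.frame(train))
  if (!"t_s" %in% names(train)) abort("spike train must have a `t_s` column")
  sort(train$t_s)
}

#' Firing-pattern metrics of a spike train
#'
#' The first instantaneous frequency `IF1 = 1 / (t2 - t1)`, the coefficient
#' of fast adaptation `CFAd = (t3 - t2) / (t2 - t1)` and the coefficient of
#' slow adaptation `CSAd = (t_n - t_{n-1}) / (t2 - t1)`, where `t_i` is the
#' threshold time of the i-th spike.
#'
#' @param train A `"spike_train"` tibble or a numeric vector of spike
#'   threshold times (s).
#' @return A one-row tibble with `n_spikes`, `IF1_Hz`, `CFAd`, `CSAd`.
#'   With fewer than three spikes the adaptation coefficients are `NA` (a
#'   warning is signalled); fewer than two spikes is an error.
#' @examples
#' firing_pattern(c(0, 6.024e-3, 12.892e-3))  # IF1 = 166 Hz
#' @export
firing_pattern <- function(train) {
  t <- spike_times(train)
  n <- length(t)
  if (n < 2) abort("at least two spikes are required for IF1")
  isi1 <- t[2] - t[1]
  if (n < 3) {
    warn("fewer than three spikes: CFAd/CSAd undefined")
    return(tibble(n_spikes = n, IF1_Hz = 1 / isi1,
                  CFAd = NA_real_, CSAd = NA_real_))
  }
  tibble(
    n_spikes = n,
    IF1_Hz = 1 / isi1,
    CFAd = (t[3] - t[2]) / isi1,
    CSAd = (t[n] - t[n - 1]) / isi1
  )
}

#' Bundle stimulus-step response traces
#'
#' A set of response traces to 1.5 s current steps or 1 s light steps of
#' increasing level, as used for firing-pattern characterization and light
#' threshold estimation.
#'
#' @param data Tibble with a numeric `level` column (strictly increasing;
#'   pA for current steps, percent of maximum for light) and a `trace`
#'   list-column of `time_s`/`v_mV` data frames sharing one sampling rate.
#' @param kind `"current"`, `"light"` or `"arch"`.
#' @param t_on Step onset time within each trace (s).
#' @param step_duration Step duration (s).
#' @return The tibble with class `"step_series"` and the step geometry in
#'   attributes.
#' @export
step_series <- function(data, kind = c("current", "light", "arch"),
                        t_on, step_duration) {
  kind <- arg_match(kind)
  stopifnot(is.data.frame(data),
            all(c("level", "trace") %in% names(data)),
            t_on >= 0, step_duration > 0)
  if (nrow(data) == 0) abort("empty step series")
  if (is.unsorted(data$level, strictly = TRUE)) {
    abort("levels must be strictly increasing")
  }
  structure(as_tibble(data),
            class = c("step_series", class(tibble())),
            kind = kind, t_on = t_on, step_duration = step_duration)
}

step_window <- function(series) {
  c(attr(series, "t_on"),
    attr(series, "t_on") + attr(series, "step_duration"))
}

step_spikes <- function(series, dvdt_threshold = 10) {
  win <- step_window(series)
  map(series$trace, function(tr) {
    st <- detect_spikes(tr, dvdt_threshold)
    st[st$t_s >= win[1] & st$t_s < win[2], ]
  })
}

#' Select the step with half-maximal firing rate
#'
#' Firing-pattern and single-spike features are estimated on the spike train
#' whose rate is closest to half the maximal rate across the series.  Rate
#' per step is spike count divided by step duration; ties go to the lower
#' stimulus level.
#'
#' @param series A [step_series()].
#' @param dvdt_threshold Spike-detection threshold (mV/ms).
#' @return A list with `level`, `rate_Hz`, `train` (the selected
#'   `spike_train`) and `rates` (per-step rate table).
#' @export
select_half_max_train <- function(series, dvdt_threshold = 10) {
  stopifnot(inherits(series, "step_series"))
  trains <- step_spikes(series, dvdt_threshold)
  rates <- map_dbl(trains, nrow) / attr(series, "step_duration")
  if (all(rates == 0)) abort("no step evoked any spikes")
  target <- max(rates) / 2
  sel <- which.min(abs(rates - target))  # which.min takes the first tie
  list(
    level = series$level[sel],
    rate_Hz = rates[sel],
    train = trains[[sel]],
    rates = tibble(level = series$level, rate_Hz = rates)
  )
}

#' Action-potential waveform features
#'
#' For one spike of a detected train: amplitude `APA` from threshold to
#' peak; duration `APD` as the width at half-maximal amplitude, both
#' crossings linearly interpolated; afterhyperpolarization `AHP` from the
#' threshold to the most negative potential between the peak and the next
#' spike threshold (or 50 ms, whichever comes first), floored at zero when
#' the trajectory never falls below threshold.
#'
#' @param trace The voltage trace the train was detected on.
#' @param train A `"spike_train"` from [detect_spikes()].
#' @param spike_index Which spike to measure (1 = first, the convention for
#'   single-spike properties).
#' @return A one-row tibble with `APA_mV`, `APD_ms`, `AHP_mV`,
#'   `v_threshold_mV`.
#' @export
waveform_features <- function(trace, train, spike_index = 1) {
  stopifnot(is.data.frame(train), nrow(train) >= spike_index,
            spike_index >= 1)
  t <- trace$time_s; v <- trace$v_mV
  sp <- train[spike_index, ]
  apa <- sp$v_peak_mV - sp$v_threshold_mV
  if (apa <= 0) abort("non-positive spike amplitude")
  half <- sp$v_threshold_mV + apa / 2

  cross_time <- function(i1, i2, level, rising) {
    idx <- i1:(i2 - 1)
    hit <- if (rising) which(v[idx] < level & v[idx + 1] >= level)
           else which(v[idx] >= level & v[idx + 1] < level)
    if (length(hit) == 0) return(NA_real_)
    k <- idx[hit[1]]
    t[k] + (level - v[k]) / (v[k + 1] - v[k]) * (t[k + 1] - t[k])
  }
  i_thr <- max(1L, findInterval(sp$t_s, t))
  i_pk <- which.min(abs(t - sp$t_peak_s))
  i_next <- if (nrow(train) > spike_index) {
    findInterval(train$t_s[spike_index + 1], t)
  } else {
    length(t)
  }
  i_end <- min(i_next, i_pk + ceiling(0.050 / (t[2] - t[1])), length(t))

  t_up <- cross_time(i_thr, i_pk + 1, half, rising = TRUE)
  t_down <- cross_time(i_pk, i_end, half, rising = FALSE)
  if (is.na(t_up) || is.na(t_down)) {
    abort("truncated waveform: half-amplitude crossings not resolved")
  }
  post <- v[i_pk:i_end]
  ahp <- max(0, sp$v_threshold_mV - min(post))
  tibble(
    APA_mV = apa,
    APD_ms = (t_down - t_up) * 1000,
    AHP_mV = ahp,
    v_threshold_mV = sp$v_threshold_mV
  )
}

step_baseline <- function(tr, t_on) {
  pre <- tr$v_mV[tr$time_s >= t_on - 0.1 & tr$time_s < t_on]
  if (length(pre) == 0) abort("no 100 ms pre-step baseline available")
  mean(pre)
}

step_steady <- function(tr, win) {
  # steady-state response: step window excluding the first 100 ms
  sel <- tr$time_s >= win[1] + 0.1 & tr$time_s < win[2]
  mean(tr$v_mV[sel])
}

#' Light-intensity thresholds for depolarization and spiking
#'
#' The depolarization threshold is the lowest light level whose steady
#' response (mean over the step, excluding the first 100 ms) exceeds the
#' 100 ms pre-step baseline by at least `depol_criterion_mV`; the spiking
#' threshold is the lowest level evoking at least one detected spike.
#'
#' @param series A [step_series()] with levels in percent of maximum light.
#' @param depol_criterion_mV Depolarization criterion (mV).
#' @param dvdt_threshold Spike-detection threshold (mV/ms).
#' @return One-row tibble with `depolarization_threshold` and
#'   `spiking_threshold` (percent of maximum; `NA` when never reached).
#' @export
light_thresholds <- function(series, depol_criterion_mV = 1.0,
                             dvdt_threshold = 10) {
  stopifnot(inherits(series, "step_series"))
  win <- step_window(series)
  t_on <- attr(series, "t_on")
  depol <- map_dbl(series$trace, function(tr) {
    step_steady(tr, win) - step_baseline(tr, t_on)
  })
  n_sp <- map_dbl(step_spikes(series, dvdt_threshold), nrow)
  dep_idx <- which(depol >= depol_criterion_mV)
  sp_idx <- which(n_sp >= 1)
  tibble(
    depolarization_threshold =
      if (length(dep_idx)) series$level[min(dep_idx)] else NA_real_,
    spiking_threshold =
      if (length(sp_idx)) series$level[min(sp_idx)] else NA_real_
  )
}

#' Maximal light-evoked hyperpolarization across a step series
#'
#' For archaerhodopsin-type responses: per step, the steady membrane
#' deviation below the pre-step baseline; returns the largest magnitude and
#' the level at which it occurs.
#'
#' @param series A [step_series()].
#' @return One-row tibble with `max_hyperpolarization_mV` (positive
#'   magnitude) and `level_at_max`.
#' @export
max_hyperpolarization <- function(series) {
  stopifnot(inherits(series, "step_series"))
  if (nrow(series) == 0) abort("empty step series")
  win <- step_window(series)
  t_on <- attr(series, "t_on")
  dv <- map_dbl(series$trace, function(tr) {
    step_baseline(tr, t_on) - step_steady(tr, win)
  })
  dv <- pmax(dv, 0)
  sel <- which.max(dv)
  tibble(max_hyperpolarization_mV = dv[sel], level_at_max = series$level[sel])
}
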