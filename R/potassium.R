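#' Potassium electrode calibration parameters
#'
#' The ion-selective electrode obeys the exponential law
#' \eqn{[K^+]_o(t) = C_{ref} \, e^{S V(t)}}, with a reference concentration
#' of 2.5 mM at zero electrode voltage and a per-electrode scaling factor
#' `S` (typically 0.043-0.045 per mV, average 0.044).
#'
#' @param S Scaling factor (1/mV).
#' @param C_ref Reference concentration at zero voltage (mM).
#' @return A list of class `"k_calibration"`.
#' @export
k_calibration <- function(S = 0.044, C_ref = 2.5) {
  stopifnot(S > 0, C_ref > 0)
  structure(list(S = S, C_ref = C_ref), class = "k_calibration")
}

#' Convert electrode voltage to potassium concentration
#'
#' @param V Electrode voltage (mV); vectorized.
#' @param cal A [k_calibration()].
#' @return Concentration (mM), `C_ref * exp(S * V)`.
#' @examples
#' k_voltage_to_conc(0, k_calibration())  # 2.5 mM
#' @export
k_voltage_to_conc <- function(V, cal = k_calibration()) {
  stopifnot(inherits(cal, "k_calibration"))
  cal$C_ref * exp(cal$S * V)
}

#' Convert potassium concentration to electrode voltage
#'
#' Exact inverse of [k_voltage_to_conc()]; used by the synthetic electrode
#' trace generator.
#'
#' @param C Concentration (mM, positive); vectorized.
#' @param cal A [k_calibration()].
#' @return Electrode voltage (mV), `log(C / C_ref) / S`.
#' @export
k_conc_to_voltage <- function(C, cal = k_calibration()) {
  stopifnot(inherits(cal, "k_calibration"))
  if (any(C <= 0)) {
    abort("concentration must be positive", class = "ictalsim_domain_error")
  }
  log(C / cal$C_ref) / cal$S
}

#' Estimate the electrode scaling factor from calibration solutions
#'
#' Through-origin least squares of `log(C / C_ref)` on the measured steady
#' voltage (the electrode law has no intercept: zero voltage corresponds to
#' the reference concentration by construction).
#'
#' @param cal_set Data frame with columns `conc_mM` (known concentration of
#'   the applied solution) and `voltage_mV` (measured steady voltage); at
#'   least two distinct concentrations.
#' @param C_ref Reference concentration (mM).
#' @return An object of class `"k_sensor_fit"` with elements `S`,
#'   `residual_sd`, `n`, `C_ref` and the underlying `lm` fit.  `tidy()` and
#'   `glance()` methods are provided.
#' @export
calibrate_k_sensor <- function(cal_set, C_ref = 2.5) {
  stopifnot(is.data.frame(cal_set),
            all(c("conc_mM", "voltage_mV") %in% names(cal_set)))
  if (nrow(cal_set) < 2 || length(unique(cal_set$conc_mM)) < 2) {
    abort("calibration needs at least two distinct concentrations")
  }
  if (any(cal_set$conc_mM <= 0)) abort("concentrations must be positive")
  if (sd(cal_set$voltage_mV) == 0) {
    abort("identical voltages: singular calibration fit")
  }
  df <- tibble(y = log(cal_set$conc_mM / C_ref), V = cal_set$voltage_mV)
  fit <- lm(y ~ 0 + V, data = df)
  structure(
    list(S = unname(coef(fit)[["V"]]),
         residual_sd = sqrt(mean(fit$residuals^2)),
         n = nrow(cal_set), C_ref = C_ref, fit = fit),
    class = "k_sensor_fit"
  )
}

#' @export
print.k_sensor_fit <- function(x, ...) {
  cat(sprintf(
    "<k_sensor_fit> S = %.5f /mV (C_ref %.2f mM, n = %d, residual SD %.2e)\n",
    x$S, x$C_ref, x$n, x$residual_sd
  ))
  invisible(x)
}

#' @export
tidy.k_sensor_fit <- function(x, ...) {
  # vcov warns on an exactly interpolating fit; the zero SE is still valid
  se <- suppressWarnings(unname(sqrt(diag(stats::vcov(x$fit)))[1]))
  tibble(term = "S", estimate = x$S, std.error = se)
}

#' @export
glance.k_sensor_fit <- function(x, ...) {
  tibble(S = x$S, C_ref = x$C_ref, residual_sd = x$residual_sd, n = x$n)
}

#' Potassium transient statistics around discharge events
#'
#' Measures, on a concentration-unit electrode trace: the per-event rise
#' (maximum concentration from event onset to 2 s past offset, minus the
#' median over the 5 s preceding onset), the inter-event baseline elevation
#' during the stimulation window relative to the inter-event baseline
#' outside it, and the recovery time after stimulation end (first time the
#' concentration stays within `band_mM` of the pre-stimulation baseline for
#' at least `hold_s` seconds).
#'
#' @param trace Data frame with `time_s` and `conc_mM` columns.
#' @param events A `discharge_events` tibble (onsets/offsets in seconds).
#' @param stim_window Length-2 numeric `c(from, to)` of the stimulation
#'   window (s), or `NULL` when no stimulation was applied.
#' @param band_mM,hold_s Recovery criterion: band half-width (mM) and hold
#'   duration (s).
#' @return A list with `per_event` (tibble: `onset_s`, `class`, `rise_mM`),
#'   `baseline_elevation_mM` and `recovery_s` (both `NA` without a
#'   stimulation window).
#' @export
k_transient_stats <- function(trace, events, stim_window = NULL,
                              band_mM = 0.2, hold_s = 5) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "conc_mM") %in% names(trace)),
            is.data.frame(events))
  t <- trace$time_s; C <- trace$conc_mM
  if (nrow(events) > 0 &&
      (min(events$onset_s) < min(t) || max(events$offset_s) > max(t))) {
    abort("event windows fall outside the trace")
  }

  rise <- map_dbl(seq_len(nrow(events)), function(i) {
    on <- events$onset_s[i]; off <- events$offset_s[i]
    pre <- C[t >= on - 5 & t < on]
    win <- C[t >= on & t <= off + 2]
    max(win) - median(pre)
  })
  per_event <- tibble(onset_s = events$onset_s, class = events$class,
                      rise_mM = rise)

  baseline_elev <- recovery <- NA_real_
  if (!is.null(stim_window)) {
    stopifnot(length(stim_window) == 2, stim_window[2] > stim_window[1])
    in_event <- rep(FALSE, length(t))
    for (i in seq_len(nrow(events))) {
      in_event <- in_event |
        (t >= events$onset_s[i] - 1 & t <= events$offset_s[i] + 2)
    }
    inside <- t >= stim_window[1] & t < stim_window[2] & !in_event
    outside <- t < stim_window[1] & !in_event
    if (any(inside) && any(outside)) {
      baseline_elev <- median(C[inside]) - median(C[outside])
    }
    # recovery: first post-window time from which C stays inside the band
    pre_base <- median(C[outside])
    post <- which(t >= stim_window[2])
    if (length(post) > 0) {
      ok <- abs(C[post] - pre_base) <= band_mM
      dt <- t[2] - t[1]
      need <- max(1L, round(hold_s / dt))
      run <- rle(ok)
      ends <- cumsum(run$lengths)
      starts <- ends - run$lengths + 1
      good <- which(run$values &
                      (run$lengths >= need | ends == length(ok)))
      if (length(good) > 0) {
        recovery <- t[post[starts[good[1]]]] - stim_window[2]
      }
    }
  }
  list(per_event = per_event,
       baseline_elevation_mM = baseline_elev,
       recovery_s = max(0, recovery))
}
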