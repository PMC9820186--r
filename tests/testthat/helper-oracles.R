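# Independent brute-force oracles used by the round-trip and equivalence
# tests. These deliberately re-derive results with naive loops, never by
# calling the package's own vectorized implementations.

# naive all-samples spike scan: central-difference dV/dt, upward crossings
# of the threshold, linear interpolation, 1 ms refractory merge
brute_force_spike_scan <- function(time_s, v_mV, thr = 10) {
  dt <- time_s[2] - time_s[1]
  n <- length(v_mV)
  out <- numeric(0)
  last <- -Inf
  for (k in 2:(n - 2)) {
    d0 <- (v_mV[k + 1] - v_mV[k - 1]) / (2 * dt * 1000)
    d1 <- (v_mV[k + 2] - v_mV[k]) / (2 * dt * 1000)
    if (!is.na(d0) && !is.na(d1) && d0 < thr && d1 >= thr) {
      tc <- time_s[k] + (thr - d0) / (d1 - d0) * dt
      if (tc - last > 1e-3) {
        out <- c(out, tc)
        last <- tc
      }
    }
  }
  out
}

# naive threshold-run scan for event detection on an already smoothed,
# baseline-subtracted signal: maximal runs above a fixed threshold with a
# merge gap, returning count of runs at least min_dur long
brute_force_run_scan <- function(time_s, above, merge_gap, min_dur) {
  dt <- time_s[2] - time_s[1]
  runs <- list()
  i <- 1
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(time_s[i], time_s[j] + dt)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(runs) == 0) return(data.frame(onset = numeric(),
                                           offset = numeric()))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    lastr <- merged[[length(merged)]]
    if (r[1] - lastr[2] < merge_gap) {
      merged[[length(merged)]] <- c(lastr[1], r[2])
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  df <- do.call(rbind, merged)
  df <- data.frame(onset = df[, 1], offset = df[, 2])
  df[df$offset - df$onset >= min_dur, ]
}

# Bernoulli negative log-likelihood of the Boltzmann curve, written directly
boltzmann_nll_oracle <- function(li, y, LI0, Delta) {
  p <- 1 - 1 / (1 + exp((li - LI0) / Delta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

rate_detection <- function() detection_params(rectify = "positive")
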