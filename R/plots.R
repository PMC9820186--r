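#' Plot a network simulation trace
#'
#' Faceted time-series view of the main channels: excitatory firing rate,
#' clamp current, extracellular potassium, intracellular sodium and the
#' synaptic resource.
#'
#' @param object A `"network_sim"` tibble from [simulate_network()].
#' @param channels Channels to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.network_sim <- function(object,
                                 channels = c("rate_E", "I_vc", "K_o",
                                              "Na_i", "x_D"),
                                 ...) {
  df <- pivot_longer(
    as_tibble(object)[, c("time_s", channels)],
    cols = all_of(channels), names_to = "channel", values_to = "value"
  )
  df$channel <- factor(df$channel, levels = channels)
  ggplot(df, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_grid(rows = vars(.data$channel), scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' Plot detected discharges on top of a trace channel
#'
#' @param trace Data frame with `time_s` and the detected channel.
#' @param events A `discharge_events` tibble.
#' @param channel Channel name.
#' @return A ggplot object.
#' @export
plot_discharges <- function(trace, events,
                            channel = attr(events, "channel") %||% "rate_E") {
  ggplot() +
    geom_rect(
      data = events,
      aes(xmin = .data$onset_s, xmax = .data$offset_s,
          ymin = -Inf, ymax = Inf, fill = .data$class),
      alpha = 0.25
    ) +
    geom_line(
      data = trace,
      aes(x = .data$time_s, y = .data[[channel]]),
      linewidth = 0.3
    ) +
    scale_fill_manual(values = c(ictal = "firebrick",
                                 interictal = "steelblue")) +
    labs(x = "time (s)", y = channel, fill = "event") +
    theme_minimal()
}

#' Plot a fitted Boltzmann dose-response curve
#'
#' Empirical induction probabilities (binned over the light-intensity grid)
#' with the pooled fit and, when available, the per-slice and averaged
#' curves.
#'
#' @param object A `"boltzmann_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  emp <- object$data |>
    group_by(.data$li_percent) |>
    summarise(p = mean(.data$outcome), .groups = "drop")
  grid <- tibble(li_percent = seq(min(emp$li_percent), max(emp$li_percent),
                                  length.out = 400))
  pooled <- mutate(grid, p = boltzmann_p(.data$li_percent,
                                         object$pooled$LI0,
                                         object$pooled$Delta),
                   curve = "pooled")
  curves <- pooled
  if (!is.null(object$averaged)) {
    avg <- mutate(grid, p = boltzmann_p(.data$li_percent,
                                        object$averaged$LI0,
                                        object$averaged$Delta),
                  curve = "averaged")
    curves <- bind_rows(pooled, avg)
  }
  ggplot() +
    geom_point(data = emp, aes(x = .data$li_percent, y = .data$p),
               alpha = 0.4, size = 0.8) +
    geom_line(data = curves,
              aes(x = .data$li_percent, y = .data$p,
                  colour = .data$curve)) +
    labs(x = "light intensity (% of maximum)",
         y = "P(interictal discharge)", colour = NULL) +
    theme_minimal()
}

#' Plot a spike train over its voltage trace
#'
#' @param trace Data frame with `time_s`, `v_mV`.
#' @param train A `"spike_train"` tibble.
#' @return A ggplot object.
#' @export
plot_spike_train <- function(trace, train) {
  ggplot(trace, aes(x = .data$time_s, y = .data$v_mV)) +
    geom_line(linewidth = 0.3) +
    geom_point(data = train,
               aes(x = .data$t_s, y = .data$v_threshold_mV),
               colour = "firebrick", size = 1) +
    labs(x = "time (s)", y = "membrane potential (mV)") +
    theme_minimal()
}
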