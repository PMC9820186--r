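#' Write a time-series trace to CSV
#'
#' Tidy interchange schema: first column `time_s`, remaining columns named
#' with a unit suffix (`_mV`, `_pA`, `_mM`) or the dimensionless simulation
#' channels.
#'
#' @param trace Data frame with a `time_s` first column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  if (names(trace)[1] != "time_s") abort("first column must be `time_s`")
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Read a time-series trace from CSV
#'
#' Validates a header with leading `time_s`, strictly increasing uniform
#' sampling (relative tolerance `1e-6`), and — when `expected_channels` is
#' given — the presence of every requested channel.
#'
#' @param path CSV path.
#' @param expected_channels Optional character vector of required columns.
#' @return A tibble.
#' @export
read_trace <- function(path, expected_channels = NULL) {
  df <- as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!"time_s" %in% names(df) || names(df)[1] != "time_s") {
    abort("trace file must start with a `time_s` column")
  }
  check_uniform_time(df$time_s)
  missing_ch <- setdiff(expected_channels, names(df))
  if (length(missing_ch) > 0) {
    # distinguish a wrong unit suffix from a truly absent channel
    base <- sub("_(mV|pA|mM)$", "", names(df))
    for (ch in missing_ch) {
      ch_base <- sub("_(mV|pA|mM)$", "", ch)
      hit <- which(base == ch_base)
      if (length(hit) > 0) {
        abort(sprintf("unit mismatch for channel `%s`: file has `%s`",
                      ch, names(df)[hit[1]]))
      }
    }
    abort(paste("missing channel(s):", paste(missing_ch, collapse = ", ")))
  }
  df
}

#' Write a simulation trace with a metadata sidecar
#'
#' Writes the trace as `<prefix>.csv` and the run metadata — seed,
#' integration step, sampling interval, protocol preset and a hash of the
#' full parameter set — as `<prefix>.json`.
#'
#' @param sim A `"network_sim"` tibble from [simulate_network()].
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "network_sim"))
  csv <- paste0(prefix, ".csv")
  meta <- paste0(prefix, ".json")
  write_trace(as.data.frame(sim), csv)
  protocol <- attr(sim, "protocol")
  jsonlite::write_json(
    list(seed = attr(sim, "seed"), dt = attr(sim, "dt"),
         record_dt = attr(sim, "record_dt"),
         V_hold = attr(sim, "V_hold"),
         protocol = if (is.null(protocol)) "none" else protocol$preset,
         params_hash = rlang::hash(attr(sim, "params")),
         package_version = as.character(utils::packageVersion("ictalsim"))),
    meta, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(csv, meta))
}

#' Write detected events to CSV
#'
#' @param events A `discharge_events` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML configuration with optional `model`, `pump`, `ions`, `syn`,
#' `protocol` and `integration` sections; unknown top-level keys are
#' rejected.  Values override the package defaults.
#'
#' @param path YAML file path.
#' @return A list with `params` ([network_params()]), `protocol`
#'   ([stim_protocol()] or `NULL`) and `integration` (list with `duration`,
#'   `dt`, `record_dt`, `seed`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("model", "pump", "ions", "syn", "protocol", "integration")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    abort(paste("unknown config section(s):", paste(extra, collapse = ", ")))
  }
  pops <- lapply(c("E1", "E2", "I"), function(nm) {
    base <- formals(network_params)[[nm]]
    pp <- eval(base)
    over <- cfg$model[[nm]]
    if (!is.null(over)) pp <- do.call(population_params,
                                      modifyList(unclass(pp), over))
    pp
  })
  params <- network_params(
    E1 = pops[[1]], E2 = pops[[2]], I = pops[[3]],
    pump = do.call(pump_params, cfg$pump %||% list()),
    ions = do.call(ion_params, cfg$ions %||% list()),
    syn = do.call(syn_params, cfg$syn %||% list())
  )
  protocol <- if (!is.null(cfg$protocol)) {
    do.call(stim_protocol, cfg$protocol)
  }
  integ <- modifyList(list(duration = 600, dt = 1e-3, record_dt = 0.01,
                           seed = NULL),
                      cfg$integration %||% list())
  if (is.null(integ$seed)) abort("integration section must provide a seed")
  list(params = params, protocol = protocol, integration = integ)
}

#' Run the simulate -> detect -> summarize pipeline
#'
#' Executes the full analysis chain from a configuration (file path or the
#' list returned by [read_run_config()]) and wraps the outputs with
#' provenance metadata: package version, configuration hash and seed.
#' Re-running the same configuration reproduces the envelope exactly.
#'
#' @param config Path to a YAML configuration or a config list.
#' @param detection A [detection_params()] for the event detector.
#' @return A list of class `"result_envelope"` with elements `stage`,
#'   `package_version`, `config_hash`, `seed`, `trace`, `events`, `summary`
#'   and `warnings`.
#' @export
run_pipeline <- function(config, detection = detection_params(
                           rectify = "positive")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config), !is.null(config$params))
  integ <- config$integration
  warns <- character()
  trace <- withCallingHandlers(
    simulate_network(config$params, config$protocol,
                     duration = integ$duration, dt = integ$dt,
                     record_dt = integ$record_dt, seed = integ$seed),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  events <- detect_discharges(trace, channel = "rate_E", params = detection)
  window <- if (!is.null(config$protocol) &&
                is.finite(config$protocol$t_stop)) {
    c(config$protocol$t_start, config$protocol$t_stop)
  } else {
    c(0, integ$duration)
  }
  summary <- regime_summary(events, window)
  structure(
    list(stage = "pipeline",
         package_version = as.character(utils::packageVersion("ictalsim")),
         config_hash = rlang::hash(config),
         seed = integ$seed,
         trace = trace, events = events, summary = summary,
         warnings = warns),
    class = "result_envelope"
  )
}

#' @export
print.result_envelope <- function(x, ...) {
  cat(sprintf("<result_envelope> %s (ictalsim %s, seed %s, config %s)\n",
              x$stage, x$package_version, x$seed,
              substr(x$config_hash, 1, 8)))
  print(x$summary)
  invisible(x)
}

#' Serialize a result envelope to JSON
#'
#' Writes the summary-level content (not the full trace) with provenance.
#'
#' @param envelope A `"result_envelope"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(envelope, path) {
  stopifnot(inherits(envelope, "result_envelope"))
  out <- list(
    stage = envelope$stage,
    package_version = envelope$package_version,
    config_hash = envelope$config_hash,
    seed = envelope$seed,
    summary = envelope$summary,
    n_events = nrow(envelope$events),
    warnings = envelope$warnings
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
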