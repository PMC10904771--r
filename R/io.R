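#' Read / write a trace as a two-column CSV
#'
#' The on-disk format for electrode traces: columns `time_ms` and `value`,
#' uniformly sampled. The reader checks sampling uniformity.
#'
#' @param x An `axf_ts`.
#' @param path CSV path.
#' @return `path` invisibly (writer); an `axf_ts` (reader).
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "axf_ts"))
  utils::write.csv(data.frame(time_ms = ts_time(x), value = x$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param units Unit label attached to the trace read back.
#' @export
read_trace_csv <- function(path, units = "") {
  d <- utils::read.csv(path)
  if (!all(c("time_ms", "value") %in% names(d))) {
    stop("trace CSV needs columns 'time_ms' and 'value'")
  }
  dts <- diff(d$time_ms)
  if (length(dts) < 1L || any(abs(dts - dts[1]) > 1e-6 * dts[1])) {
    stop("trace is not uniformly sampled")
  }
  time_series(d$value, dt = dts[1], t0 = d$time_ms[1], units = units)
}

#' Build a run configuration from a YAML file
#'
#' Recognised top-level keys (all optional): `seed`, `cohort_n`,
#' `toxin_conc_nm`, `jitter_sd`, `noise_sd`, `indicators`,
#' `n_trials_range`, and nested maps `toxin:` (`ec50`, `hill_n`,
#' `slowdown`, `persistent_frac`) and `pulse:` (`amp_nA`, `dur_ms`,
#' `onset_ms`).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  tox_args <- y$toxin %||% list()
  toxin <- do.call(toxin_model, tox_args)
  cfg <- neuron_sim_config()
  if (!is.null(y$pulse)) {
    cfg <- neuron_sim_config(pulse = utils::modifyList(cfg$pulse, y$pulse))
  }
  args <- list(toxin = toxin, config = cfg)
  for (key in c("seed", "cohort_n", "toxin_conc_nm", "jitter_sd",
                "noise_sd", "indicators", "n_trials_range")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
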