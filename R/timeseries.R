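#' Uniformly sampled time series
#'
#' The carrier object for every recorded or simulated signal in the package:
#' membrane potential, voltage-clamp current, raw fluorescence and dF/F0
#' traces are all `axf_ts` objects (possibly with a subclass). Time is in
#' milliseconds throughout.
#'
#' @param values Numeric vector of samples (length >= 2).
#' @param dt Sampling interval in ms (> 0).
#' @param t0 Time of the first sample in ms.
#' @param units Free-text unit label for the samples (e.g. "mV", "nA").
#'
#' @return An object of class `axf_ts`: a list with fields `t0`, `dt`,
#'   `values` and `units`.
#' @export
#' @examples
#' x <- time_series(sin(seq(0, 2 * pi, length.out = 100)), dt = 0.05)
#' ts_time(x)[1:3]
time_series <- function(values, dt, t0 = 0, units = "") {
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (ms)")
  }
  if (length(values) < 2L) {
    stop("a time series needs at least 2 samples")
  }
  structure(
    list(t0 = as.numeric(t0), dt = dt, values = values, units = units),
    class = "axf_ts"
  )
}

#' @export
print.axf_ts <- function(x, ...) {
  cat(sprintf(
    "<%s> %d samples, dt = %g ms (%.4g kHz), t = [%g, %g] ms%s\n",
    paste(class(x), collapse = "/"), length(x$values), x$dt, 1 / x$dt,
    x$t0, ts_end(x), if (nzchar(x$units)) paste0(", units: ", x$units) else ""
  ))
  invisible(x)
}

#' Time axis of a time series
#'
#' @param x An `axf_ts` object.
#' @return Numeric vector of sample times in ms.
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "axf_ts"))
  x$t0 + x$dt * (seq_along(x$values) - 1L)
}

#' @rdname ts_time
#' @export
ts_end <- function(x) {
  stopifnot(inherits(x, "axf_ts"))
  x$t0 + x$dt * (length(x$values) - 1L)
}

#' @export
length.axf_ts <- function(x) length(x$values)

#' Replace the sample values of a time series, keeping its time base
#'
#' @param x An `axf_ts` object.
#' @param values Replacement samples (same length as `x`).
#' @return `x` with new values.
#' @export
ts_with_values <- function(x, values) {
  stopifnot(inherits(x, "axf_ts"), length(values) == length(x$values))
  x$values <- as.numeric(values)
  x
}

# check that a list of traces share t0/dt/length; returns invisible(TRUE)
check_same_grid <- function(traces, what = "traces") {
  stopifnot(length(traces) >= 1L)
  ref <- traces[[1L]]
  for (tr in traces) {
    stopifnot(inherits(tr, "axf_ts"))
    if (!isTRUE(all.equal(tr$t0, ref$t0)) ||
        !isTRUE(all.equal(tr$dt, ref$dt)) ||
        length(tr$values) != length(ref$values)) {
      stop(sprintf("%s must share t0, dt and length", what))
    }
  }
  invisible(TRUE)
}

# indices of samples with t in [from, to] (closed window)
ts_window_idx <- function(x, from, to) {
  tt <- ts_time(x)
  idx <- which(tt >= from - 1e-9 & tt <= to + 1e-9)
  if (length(idx) == 0L) {
    stop(sprintf("window [%g, %g] ms contains no samples", from, to))
  }
  idx
}

#' Membrane-potential trace
#'
#' An `axf_ts` subclass carrying membrane potential in mV.
#'
#' @inheritParams time_series
#' @param source Either "electrode" or "optical".
#' @return An object of class `c("axf_vm", "axf_ts")`.
#' @export
vm_trace <- function(values, dt, t0 = 0, source = "electrode") {
  x <- time_series(values, dt, t0, units = "mV")
  x$source <- match.arg(source, c("electrode", "optical"))
  class(x) <- c("axf_vm", class(x))
  x
}

#' Voltage-clamp current trace
#'
#' An `axf_ts` subclass carrying a whole-cell current in nA, together with
#' the step protocol that elicited it.
#'
#' @inheritParams time_series
#' @param protocol A [vc_protocol()] object.
#' @return An object of class `c("axf_vc", "axf_ts")`.
#' @export
vc_current_trace <- function(values, dt, t0 = 0, protocol = vc_protocol()) {
  x <- time_series(values, dt, t0, units = "nA")
  x$protocol <- protocol
  class(x) <- c("axf_vc", class(x))
  x
}
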