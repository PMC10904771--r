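#' Region of interest along the axon
#'
#' ROIs are half-open intervals `[a, b)` of axial distance from the soma
#' edge, in um. Three presets match the segments commonly used for AIS
#' analysis: `"mid"` = \[10, 30) (AP-shape analysis), `"proximal"` =
#' \[5, 15) and `"distal"` = \[30, 40) (spatial Ca2+ decomposition).
#'
#' @param span_um Numeric length-2: `c(a, b)` with `0 <= a < b`, or a preset
#'   name.
#' @param label Text label; defaults to the preset name or `"a-b um"`.
#' @return An object of class `axf_roi`.
#' @export
#' @examples
#' roi_spec("mid")
#' roi_spec(c(12, 28), label = "custom")
roi_spec <- function(span_um = "mid", label = NULL) {
  presets <- list(mid = c(10, 30), proximal = c(5, 15), distal = c(30, 40))
  if (is.character(span_um)) {
    name <- match.arg(span_um, names(presets))
    if (is.null(label)) label <- name
    span_um <- presets[[name]]
  }
  stopifnot(length(span_um) == 2L, span_um[1] >= 0,
            span_um[1] < span_um[2])
  if (is.null(label)) label <- sprintf("%g-%g um", span_um[1], span_um[2])
  structure(list(label = label, span_um = as.numeric(span_um)),
            class = "axf_roi")
}

as_roi_spec <- function(roi) {
  if (inherits(roi, "axf_roi")) roi else roi_spec(roi)
}

#' Extract an ROI-averaged trace from a fluorescence movie
#'
#' Per-frame mean over the pixels whose axial coordinate falls in the ROI's
#' half-open span `[a, b)` (half-open so adjacent ROIs never share pixels).
#'
#' @param movie An `axf_movie` (see [fluor_movie()]).
#' @param roi An [roi_spec()] or preset name.
#' @return An `axf_ts` trace of per-frame means.
#' @export
extract_roi_trace <- function(movie, roi) {
  stopifnot(inherits(movie, "axf_movie"))
  roi <- as_roi_spec(roi)
  px_center <- (seq_len(ncol(movie$frames)) - 0.5) * movie$um_per_px
  sel <- px_center >= roi$span_um[1] & px_center < roi$span_um[2]
  axon_um <- ncol(movie$frames) * movie$um_per_px
  if (roi$span_um[2] > axon_um + 1e-9 || !any(sel)) {
    stop(sprintf(
      "ROI '%s' [%g, %g) um selects no pixels (movie covers 0-%g um)",
      roi$label, roi$span_um[1], roi$span_um[2], axon_um
    ))
  }
  time_series(rowMeans(movie$frames[, sel, drop = FALSE]),
              dt = movie$dt, t0 = movie$t0)
}

#' Average repeated trials with an optional somatic-response match
#'
#' Pointwise mean over trials sharing one time grid. When `somatic` traces
#' are supplied (one electrode V_m trace per trial), trials whose somatic AP
#' deviates from the first trial's by more than `peak_time_tol_ms` in peak
#' time or `peak_mv_tol` in peak V_m are excluded before averaging, and the
#' exclusions are reported via a warning and the `"excluded"` attribute.
#'
#' @param trials List of `axf_ts` traces on one grid.
#' @param somatic Optional list of somatic [vm_trace()]s, parallel to
#'   `trials`.
#' @param peak_time_tol_ms,peak_mv_tol Matching tolerances for the somatic
#'   AP peak (defaults 0.1 ms, 2 mV).
#' @return The mean trace (`axf_ts`), with attribute `excluded` (integer
#'   indices of dropped trials).
#' @export
average_trials <- function(trials, somatic = NULL,
                           peak_time_tol_ms = 0.1, peak_mv_tol = 2) {
  stopifnot(is.list(trials), length(trials) >= 1L)
  check_same_grid(trials, "trials")
  keep <- rep(TRUE, length(trials))
  if (!is.null(somatic)) {
    stopifnot(length(somatic) == length(trials))
    check_same_grid(somatic, "somatic traces")
    pk <- function(v) {
      i <- which.max(v$values)
      c(time = ts_time(v)[i], mv = v$values[i])
    }
    ref <- pk(somatic[[1L]])
    for (i in seq_along(somatic)[-1L]) {
      p <- pk(somatic[[i]])
      keep[i] <- abs(p["time"] - ref["time"]) <= peak_time_tol_ms &&
        abs(p["mv"] - ref["mv"]) <= peak_mv_tol
    }
    if (!all(keep)) {
      warning(sprintf("excluded %d/%d trial(s) with non-matching somatic AP: %s",
                      sum(!keep), length(trials),
                      paste(which(!keep), collapse = ", ")))
    }
  }
  if (!any(keep)) stop("no trials left after somatic-response matching")
  kept <- trials[keep]
  mean_vals <- Reduce(`+`, lapply(kept, `[[`, "values")) / length(kept)
  out <- ts_with_values(trials[[1L]], mean_vals)
  attr(out, "excluded") <- which(!keep)
  out
}

#' Multi-exponential photobleaching model
#'
#' `bleach(t) = offset + sum(amps * exp(-t / taus))`, fitted to signal-free
#' trials and used to flatten slow fluorescence decay before computing
#' dF/F0.
#'
#' @param amps Amplitudes, camera counts.
#' @param taus Time constants, ms (> 0), same length as `amps`.
#' @param offset Constant term, counts.
#' @param residual_rms RMS of the fit residuals (filled by [fit_bleach()]).
#' @return An object of class `axf_bleach`.
#' @export
bleach_model <- function(amps, taus, offset, residual_rms = NA_real_) {
  stopifnot(length(amps) == length(taus), all(taus > 0))
  structure(
    list(n_exp = length(amps), amps = as.numeric(amps),
         taus = as.numeric(taus), offset = as.numeric(offset),
         residual_rms = residual_rms),
    class = "axf_bleach"
  )
}

bleach_eval <- function(model, t_rel) {
  v <- rep(model$offset, length(t_rel))
  for (k in seq_len(model$n_exp)) {
    v <- v + model$amps[k] * exp(-t_rel / model$taus[k])
  }
  v
}

#' Fit a multi-exponential bleach model to signal-free trials
#'
#' Least-squares fit of `offset + sum(a_k exp(-t/tau_k))` to the mean of
#' the dark trials, with a multi-start over log-spaced time constants
#' (Levenberg-Marquardt via \pkg{minpack.lm}).
#'
#' @param dark_trials List of signal-free `axf_ts` trials on one grid (or a
#'   single trace).
#' @param n_exp Number of exponentials, 1-3.
#' @return A [bleach_model()] with `residual_rms` filled in.
#' @export
fit_bleach <- function(dark_trials, n_exp = 1L) {
  stopifnot(n_exp %in% 1:3)
  if (inherits(dark_trials, "axf_ts")) dark_trials <- list(dark_trials)
  m <- average_trials(dark_trials)
  t_rel <- ts_time(m) - m$t0
  y <- m$values
  span <- max(t_rel)
  resid_fn <- function(p) {
    amps <- p[seq_len(n_exp)]
    taus <- exp(p[n_exp + seq_len(n_exp)])
    offset <- p[2 * n_exp + 1]
    v <- rep(offset, length(t_rel))
    for (k in seq_len(n_exp)) v <- v + amps[k] * exp(-t_rel / taus[k])
    v - y
  }
  amp0 <- (y[1] - y[length(y)])
  tau_grid <- list(span / 2, c(span / 8, span), c(span / 20, span / 3, span * 1.5))
  starts <- list(
    c(rep(amp0 / n_exp, n_exp), log(tau_grid[[n_exp]]), y[length(y)]),
    c(rep(amp0 / n_exp, n_exp), log(tau_grid[[n_exp]] * 3), mean(y))
  )
  best <- NULL
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 400)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rms <- sqrt(mean(fit$fvec^2))
    if (is.null(best) || rms < best$rms) best <- list(fit = fit, rms = rms)
  }
  if (is.null(best)) stop("bleach fit did not converge from any start")
  p <- best$fit$par
  bleach_model(amps = p[seq_len(n_exp)],
               taus = exp(p[n_exp + seq_len(n_exp)]),
               offset = p[2 * n_exp + 1],
               residual_rms = best$rms)
}

#' Divide out a fitted bleach curve
#'
#' The bleach curve is normalised to 1 at the first sample so that the
#' correction leaves the initial fluorescence level untouched; correcting a
#' trace and re-multiplying by the same curve is an exact round trip.
#'
#' @param raw Raw fluorescence `axf_ts`.
#' @param model A fitted [bleach_model()].
#' @return The corrected trace.
#' @export
correct_bleach <- function(raw, model) {
  stopifnot(inherits(raw, "axf_ts"), inherits(model, "axf_bleach"))
  t_rel <- ts_time(raw) - raw$t0
  b <- bleach_eval(model, t_rel)
  if (any(b <= 0)) stop("bleach curve reaches zero or below within the record")
  ts_with_values(raw, raw$values / (b / b[1]))
}

#' Fractional fluorescence change dF/F0
#'
#' `F0` is the mean over a baseline window preceding the stimulus; the
#' output is `(F - F0) / F0`, a dimensionless `axf_dff` trace whose mean
#' over the baseline window is zero by construction.
#'
#' @param raw Fluorescence `axf_ts` (typically bleach-corrected).
#' @param baseline_window Length-2 ms interval used for `F0`; default the
#'   first 1 ms of the record.
#' @param indicator One of "vm", "na", "ca".
#' @param roi Optional [roi_spec()] recorded on the trace.
#' @return An object of class `c("axf_dff", "axf_ts")` with fields
#'   `indicator`, `roi`, `baseline_window`, `f0`.
#' @export
compute_dff <- function(raw, baseline_window = NULL,
                        indicator = c("vm", "na", "ca"), roi = NULL) {
  stopifnot(inherits(raw, "axf_ts"))
  indicator <- match.arg(indicator)
  if (is.null(baseline_window)) baseline_window <- raw$t0 + c(0, 1)
  idx <- ts_window_idx(raw, baseline_window[1], baseline_window[2])
  f0 <- mean(raw$values[idx])
  if (f0 <= 0) stop("baseline fluorescence F0 is not positive")
  out <- ts_with_values(raw, (raw$values - f0) / f0)
  out$units <- "dF/F0"
  out$indicator <- indicator
  out$roi <- if (is.null(roi)) NULL else as_roi_spec(roi)
  out$baseline_window <- baseline_window
  out$f0 <- f0
  class(out) <- c("axf_dff", class(out))
  out
}

#' Calibrate a Na+ indicator dF/F0 trace to concentration change
#'
#' Applies a linear calibration factor (mM of Na+ change per unit dF/F0),
#' the operating regime of low-affinity Na+ indicators.
#'
#' @param dff An `axf_dff` trace with `indicator == "na"`.
#' @param cal_factor mM per unit dF/F0 (> 0).
#' @return An `axf_ts` trace in mM.
#' @export
calibrate_na <- function(dff, cal_factor) {
  stopifnot(inherits(dff, "axf_dff"))
  if (!identical(dff$indicator, "na")) {
    stop("calibration applies to the Na+ indicator only (indicator = 'na')")
  }
  if (!is.numeric(cal_factor) || cal_factor <= 0) {
    stop("`cal_factor` must be positive")
  }
  out <- ts_with_values(dff, dff$values * cal_factor)
  out$units <- "mM"
  class(out) <- "axf_ts"
  out[c("indicator", "roi", "baseline_window", "f0")] <- NULL
  out
}

#' Normalise an optical AP waveform to the somatic AP
#'
#' Voltage-dye transients have no absolute scale; because the AP amplitude
#' in the proximal AIS is comparable to the somatic one, the optical
#' waveform is mapped affinely so that its baseline matches the somatic
#' baseline mean and its peak matches the somatic peak. The result is
#' invariant to any positive affine transform of the optical input.
#'
#' @param optical Optical `axf_dff` (indicator "vm") or plain `axf_ts`.
#' @param somatic Somatic electrode [vm_trace()].
#' @param baseline_window ms interval defining the baselines (default first
#'   1 ms of each trace).
#' @param min_snr Minimum (peak - baseline) / baseline-SD for the optical
#'   trace; below it the AP is indistinguishable from noise and an error is
#'   raised.
#' @return A [vm_trace()] on the optical time base, in mV.
#' @export
normalize_optical_ap <- function(optical, somatic, baseline_window = NULL,
                                 min_snr = 5) {
  stopifnot(inherits(optical, "axf_ts"), inherits(somatic, "axf_vm"))
  bw_opt <- if (is.null(baseline_window)) optical$t0 + c(0, 1) else baseline_window
  bw_som <- if (is.null(baseline_window)) somatic$t0 + c(0, 1) else baseline_window
  oidx <- ts_window_idx(optical, bw_opt[1], bw_opt[2])
  sidx <- ts_window_idx(somatic, bw_som[1], bw_som[2])
  o_base <- mean(optical$values[oidx])
  o_sd <- stats::sd(optical$values[oidx])
  o_peak <- max(optical$values)
  if (!is.finite(o_sd)) o_sd <- 0
  if (o_peak - o_base < min_snr * max(o_sd, .Machine$double.eps)) {
    stop("optical AP peak is not distinguishable from baseline noise")
  }
  s_base <- mean(somatic$values[sidx])
  s_peak <- max(somatic$values)
  scale <- (s_peak - s_base) / (o_peak - o_base)
  vm_trace(s_base + (optical$values - o_base) * scale,
           dt = optical$dt, t0 = optical$t0, source = "optical")
}

#' Offline bridge and junction-potential correction
#'
#' Removes the series-resistance voltage drop (`r_bridge * i_inj`) using
#' the recorded injected current, and subtracts the liquid-junction
#' potential (default 11 mV).
#'
#' @param vm_raw Recorded [vm_trace()].
#' @param i_inj Injected current `axf_ts` in nA, same grid as `vm_raw`.
#' @param r_bridge Uncompensated series resistance, MOhm.
#' @param junction_mv Junction potential to subtract, mV.
#' @return Corrected [vm_trace()].
#' @export
bridge_junction_correct <- function(vm_raw, i_inj, r_bridge,
                                    junction_mv = 11) {
  stopifnot(inherits(vm_raw, "axf_vm"), inherits(i_inj, "axf_ts"))
  check_same_grid(list(vm_raw, i_inj), "vm and injected-current traces")
  ts_with_values(vm_raw,
                 vm_raw$values - r_bridge * i_inj$values - junction_mv)
}
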