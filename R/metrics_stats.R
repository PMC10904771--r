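#' Half-inactivation time (T50) of a voltage-clamp Na+ current
#'
#' T50 quantifies how fast a Na+ current inactivates during a depolarising
#' step: with `peak` the maximal current magnitude and `residual` the
#' magnitude at the end of the step, T50 is the time elapsed from the peak
#' to the first crossing of `peak - 0.5 * (peak - residual)`, the crossing
#' located by linear interpolation between samples. Slowed inactivation
#' (e.g. by an alpha-toxin) increases T50.
#'
#' @param trace A [vc_current_trace()] (analysis is on `abs(values)`).
#' @return A list of class `axf_t50`: `t50`, `peak_time`, `peak_value`,
#'   `residual_value` (magnitudes, nA).
#' @export
#' @examples
#' tr <- simulate_vc_current(conc = 0)
#' compute_t50(tr)
compute_t50 <- function(trace) {
  stopifnot(inherits(trace, "axf_ts"))
  a <- abs(trace$values)
  tt <- ts_time(trace)
  ipk <- which.max(a)
  peak <- a[ipk]
  residual <- a[length(a)]
  if (peak - residual <= 1e-9 * peak) {
    stop("no inactivation: current never decays from its peak")
  }
  level <- peak - 0.5 * (peak - residual)
  after <- a[ipk:length(a)]
  below <- which(after <= level)
  below <- below[below > 1L]
  if (length(below) == 0L) {
    stop("no inactivation: current never falls to the half level after the peak")
  }
  j <- ipk + below[1L] - 1L       # first sample at/below the level
  # linear interpolation between samples j-1 and j
  frac <- (a[j - 1L] - level) / (a[j - 1L] - a[j])
  t_cross <- tt[j - 1L] + frac * (tt[j] - tt[j - 1L])
  structure(
    list(t50 = t_cross - tt[ipk], peak_time = tt[ipk], peak_value = peak,
         residual_value = residual),
    class = "axf_t50"
  )
}

#' Normalise a dose-response table of T50 increases
#'
#' Per isoform, divides the mean relative T50 increase at each concentration
#' by the maximal mean across concentrations, so the maximum becomes exactly
#' 1. Expects a data.frame with columns `conc_nm`, `mean_increase` and
#' optionally `isoform` (and any others, which are kept).
#'
#' @param table Data frame of per-concentration mean relative T50 increases.
#' @return The table with a `normalized` column added, concentration order
#'   preserved.
#' @export
#' @examples
#' tab <- data.frame(conc_nm = c(0.1, 1, 3), mean_increase = c(0.5, 1, 2))
#' normalize_dose_response(tab)$normalized
normalize_dose_response <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("conc_nm", "mean_increase") %in% names(table)))
  if (any(table$conc_nm <= 0)) stop("concentrations must be positive")
  split_f <- if ("isoform" %in% names(table)) table$isoform else
    rep(1L, nrow(table))
  if (anyDuplicated(data.frame(split_f, table$conc_nm))) {
    stop("concentrations must be unique per isoform")
  }
  norm_one <- function(d) {
    m <- max(d$mean_increase)
    if (m <= 0) stop("all mean T50 increases are <= 0; nothing to normalise to")
    d$normalized <- d$mean_increase / m
    d
  }
  out <- do.call(rbind, lapply(split(table, split_f), norm_one))
  rownames(out) <- NULL
  out[order(match(
    paste(if ("isoform" %in% names(out)) out$isoform else 1L, out$conc_nm),
    paste(split_f, table$conc_nm)
  )), , drop = FALSE]
}

#' Action-potential amplitude and width
#'
#' `amp` is baseline-to-peak (mV); `wid` is the total time the membrane
#' potential stays above the threshold (default -30 mV), with threshold
#' crossings located by linear interpolation and multiple supra-threshold
#' intervals summed. A trace that never crosses the threshold has
#' `wid = 0`.
#'
#' @param trace A [vm_trace()].
#' @param baseline_window ms interval for the baseline mean (default first
#'   1 ms).
#' @param threshold_mv Width threshold, mV.
#' @return A list of class `axf_apm`: `amp` (mV), `wid` (ms), plus
#'   `peak_mv`, `baseline_mv`.
#' @export
ap_metrics <- function(trace, baseline_window = NULL, threshold_mv = -30) {
  stopifnot(inherits(trace, "axf_ts"))
  if (is.null(baseline_window)) baseline_window <- trace$t0 + c(0, 1)
  idx <- ts_window_idx(trace, baseline_window[1], baseline_window[2])
  baseline <- mean(trace$values[idx])
  peak <- max(trace$values)
  v <- trace$values - threshold_mv
  tt <- ts_time(trace)
  wid <- 0
  above <- v > 0
  i <- 1L
  n <- length(v)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      t_in <- if (i == 1L) tt[1L] else {
        # linear root between samples i-1 (below) and i (above)
        tt[i - 1L] + (0 - v[i - 1L]) / (v[i] - v[i - 1L]) * (tt[i] - tt[i - 1L])
      }
      t_out <- if (j == n) tt[n] else {
        tt[j] + (0 - v[j]) / (v[j + 1L] - v[j]) * (tt[j + 1L] - tt[j])
      }
      wid <- wid + (t_out - t_in)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  structure(
    list(amp = peak - baseline, wid = wid, peak_mv = peak,
         baseline_mv = baseline),
    class = "axf_apm"
  )
}

#' Percent change of a positive quantity
#'
#' `100 * (after - before) / before`; the reference value must be positive.
#'
#' @param before,after Numeric values (vectorised; `before > 0`).
#' @return Percent change(s).
#' @export
percent_change <- function(before, after) {
  if (any(before <= 0)) stop("`before` must be positive")
  100 * (after - before) / before
}

#' Percent change of the maximum of two indicator transients
#'
#' Compares the peak of a control transient with the peak of a toxin (or
#' otherwise treated) transient recorded at the same ROI with the same
#' indicator. When fitted models are supplied the maxima are taken from the
#' model curves (noise-robust); otherwise from the averaged traces.
#'
#' @param dff_ctrl,dff_toxin `axf_dff` traces on one grid with matching
#'   indicator.
#' @param fit_ctrl,fit_toxin Optional fitted models (`axf_na_fit` /
#'   `axf_ca_fit`) for the two conditions.
#' @param noise_floor Minimal admissible control maximum; at or below it the
#'   control transient is indistinguishable from noise and an error is
#'   raised.
#' @return Percent change, with attribute `peaks_from` ("fit" or "trace").
#' @export
peak_transient_change <- function(dff_ctrl, dff_toxin,
                                  fit_ctrl = NULL, fit_toxin = NULL,
                                  noise_floor = 0) {
  stopifnot(inherits(dff_ctrl, "axf_ts"), inherits(dff_toxin, "axf_ts"))
  if (inherits(dff_ctrl, "axf_dff") && inherits(dff_toxin, "axf_dff") &&
      !identical(dff_ctrl$indicator, dff_toxin$indicator)) {
    stop("control and toxin traces use different indicators")
  }
  check_same_grid(list(dff_ctrl, dff_toxin), "control/toxin traces")
  use_fit <- !is.null(fit_ctrl) && !is.null(fit_toxin)
  m_ctrl <- if (use_fit) max(model_eval(fit_ctrl)) else max(dff_ctrl$values)
  m_tox <- if (use_fit) max(model_eval(fit_toxin)) else max(dff_toxin$values)
  if (m_ctrl <= noise_floor) {
    stop("control transient maximum does not exceed the noise floor")
  }
  out <- percent_change(m_ctrl, m_tox)
  attr(out, "peaks_from") <- if (use_fit) "fit" else "trace"
  out
}

#' Regional Ca2+ transient change (proximal vs distal AIS)
#'
#' Computes [peak_transient_change()] per ROI from paired control/toxin
#' Ca2+ movies or per-region trace lists, separating the proximal AIS
#' (5-15 um, VGCC-dominated) from the distal AIS (30-40 um, where the Ca2+
#' entry through Na_v channels dominates).
#'
#' @param ctrl,toxin Either `axf_movie` objects or named lists of `axf_dff`
#'   traces (names = region labels).
#' @param regions List of [roi_spec()]s (default proximal + distal).
#' @param baseline_window Passed to [compute_dff()] when movies are given.
#' @param ... Passed to [peak_transient_change()].
#' @return Named numeric vector of percent changes, one per region.
#' @export
regional_ca_change <- function(ctrl, toxin,
                               regions = list(roi_spec("proximal"),
                                              roi_spec("distal")),
                               baseline_window = NULL, ...) {
  get_trace <- function(obj, roi) {
    if (inherits(obj, "axf_movie")) {
      compute_dff(extract_roi_trace(obj, roi),
                  baseline_window = baseline_window,
                  indicator = "ca", roi = roi)
    } else {
      tr <- obj[[roi$label]]
      if (is.null(tr)) stop(sprintf("no trace for region '%s'", roi$label))
      tr
    }
  }
  out <- vapply(regions, function(roi) {
    roi <- as_roi_spec(roi)
    as.numeric(peak_transient_change(get_trace(ctrl, roi),
                                     get_trace(toxin, roi), ...))
  }, numeric(1))
  names(out) <- vapply(regions, function(r) as_roi_spec(r)$label,
                       character(1))
  out
}

#' Paired t-test on per-cell percent changes
#'
#' Two-sided paired t-test (via [stats::t.test()] on the differences)
#' with significance declared at p < 0.01, the conventional threshold for
#' these cohort comparisons.
#'
#' @param changes Numeric vector of per-cell paired differences (e.g.
#'   percent changes), length >= 2.
#' @param alpha Significance threshold (default 0.01).
#' @return A list of class `axf_paired`: `n`, `mean_change`, `sd_change`,
#'   `t_stat`, `p_value`, `significant`.
#' @export
paired_test <- function(changes, alpha = 0.01) {
  changes <- as.numeric(changes)
  stopifnot(length(changes) >= 2L)
  if (stats::sd(changes) == 0) {
    stop("degenerate pairs: differences have zero variance")
  }
  ht <- stats::t.test(changes)
  structure(
    list(n = length(changes), mean_change = mean(changes),
         sd_change = stats::sd(changes),
         t_stat = unname(ht$statistic), p_value = ht$p.value,
         significant = ht$p.value < alpha, alpha = alpha),
    class = "axf_paired"
  )
}

#' @export
print.axf_paired <- function(x, ...) {
  cat(sprintf(
    "Paired t-test: n = %d, mean change = %.3g +/- %.3g (SD), t = %.3g, p = %.3g (%s at %.2g)\n",
    x$n, x$mean_change, x$sd_change, x$t_stat, x$p_value,
    if (x$significant) "significant" else "not significant", x$alpha
  ))
  invisible(x)
}
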