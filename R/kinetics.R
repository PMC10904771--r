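#' Model functions for ion-indicator transients
#'
#' Cumulative ion influx reported by a low-affinity indicator is monotone
#' and step-like, so transients are fitted with logistic building blocks
#' `sigma(u) = 1 / (1 + exp(-u))`:
#' * Na+: a sum `sum_i a_i * sigma((t - t_i) / tau_i)` with `a_i >= 0`
#'   (a multi-sigmoid sum, monotone non-decreasing);
#' * Ca2+: a product `A * prod_{i=1..4} sigma((t - t_i) / tau_i)` with
#'   `A >= 0` (a 4-sigmoid product, values in `[0, A]`).
#'
#' The ionic current is the analytic time-derivative of the fitted model,
#' never a numerical derivative of the raw data — the whole point of the
#' model fit is a noise-free derivative.
#'
#' @name sigmoid_models
#' @keywords internal
NULL

# sum-of-sigmoids model and its analytic derivative
na_model_eval <- function(t, amps, t_half, tau) {
  f <- numeric(length(t))
  for (i in seq_along(amps)) {
    f <- f + amps[i] * stats::plogis((t - t_half[i]) / tau[i])
  }
  f
}

na_model_deriv <- function(t, amps, t_half, tau) {
  d <- numeric(length(t))
  for (i in seq_along(amps)) {
    s <- stats::plogis((t - t_half[i]) / tau[i])
    d <- d + amps[i] * s * (1 - s) / tau[i]
  }
  d
}

ca_model_eval <- function(t, amplitude, t_half, tau) {
  f <- rep(amplitude, length(t))
  for (i in seq_along(t_half)) {
    f <- f * stats::plogis((t - t_half[i]) / tau[i])
  }
  f
}

ca_model_deriv <- function(t, amplitude, t_half, tau) {
  k <- length(t_half)
  s <- vapply(seq_len(k),
              function(i) stats::plogis((t - t_half[i]) / tau[i]),
              numeric(length(t)))
  s <- matrix(s, ncol = k)
  prod_all <- apply(s, 1, prod)
  d <- numeric(length(t))
  for (i in seq_len(k)) {
    # A * sigma_i'(t)/tau_i * prod_{j != i} sigma_j ; sigma' = s(1-s)
    d <- d + amplitude * (1 - s[, i]) / tau[i] * prod_all
  }
  d
}

# bounded multi-start Levenberg-Marquardt; returns best par and rms.
# starts: matrix, one start per row. residual fn takes par.
multistart_lm <- function(resid_fn, starts, lower, upper) {
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(starts[r, ], lower), upper),
      fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-14,
                                           ftol = 1e-14)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rms <- sqrt(mean(fit$fvec^2))
    if (is.null(best) || rms < best$rms) best <- list(par = fit$par, rms = rms)
  }
  if (is.null(best)) stop("no optimiser start converged")
  best
}

#' Fit a multi-sigmoid sum to a Na+ indicator transient
#'
#' Bounded nonlinear least squares (`a_i >= 0`, `tau_i` in `[0.02, 5]` ms,
#' half-rise times inside the fitted window), multi-started from a seeded
#' Latin-hypercube plus a data-driven start. Deterministic given `seed`.
#'
#' @param dff A baseline-corrected `axf_dff` (or plain `axf_ts`) trace.
#' @param n Number of sigmoid components, 1-6.
#' @param seed Integer RNG seed for the multi-start.
#' @param n_starts Number of Latin-hypercube starts (default 8).
#' @param window Optional ms interval to fit; default the full trace.
#' @return An object of class `axf_na_fit`: `components` (data.frame with
#'   `amp`, `t_half`, `tau`), `n`, `residual_rms`, `window`, `t0`, `dt`,
#'   `fitted`, and `data`.
#' @export
fit_na_model <- function(dff, n = 2L, seed = 1L, n_starts = 8L,
                         window = NULL) {
  stopifnot(inherits(dff, "axf_ts"), n >= 1L, n <= 6L)
  tt <- ts_time(dff)
  if (is.null(window)) window <- range(tt)
  idx <- ts_window_idx(dff, window[1], window[2])
  t_fit <- tt[idx]
  y <- dff$values[idx]
  tau_lo <- 0.02; tau_hi <- 5
  lower <- c(rep(0, n), rep(window[1], n), rep(tau_lo, n))
  upper <- c(rep(Inf, n), rep(window[2], n), rep(tau_hi, n))
  resid_fn <- function(p) {
    na_model_eval(t_fit, p[seq_len(n)], p[n + seq_len(n)],
                  p[2 * n + seq_len(n)]) - y
  }
  amp_scale <- max(max(y), .Machine$double.eps)
  # data-driven start: components at the quantile times of the rise
  qs <- (seq_len(n) - 0.5) / n
  t_guess <- vapply(qs, function(q) {
    i <- which(y >= q * max(y))[1]
    if (is.na(i)) mean(window) else t_fit[i]
  }, numeric(1))
  heuristic <- c(rep(amp_scale / n, n), t_guess, rep(0.3, n))
  lhs_starts <- with_private_rng(seed, lhs::randomLHS(n_starts, 3L * n))
  starts <- rbind(
    heuristic,
    t(apply(lhs_starts, 1, function(u) {
      c(u[seq_len(n)] * 2 * amp_scale,
        window[1] + u[n + seq_len(n)] * diff(window),
        exp(log(0.05) + u[2 * n + seq_len(n)] * log(2 / 0.05)))
    }))
  )
  best <- multistart_lm(resid_fn, starts, lower, upper)
  p <- best$par
  ord <- order(p[n + seq_len(n)])
  comp <- data.frame(amp = p[seq_len(n)][ord],
                     t_half = p[n + seq_len(n)][ord],
                     tau = p[2 * n + seq_len(n)][ord])
  structure(
    list(components = comp, n = n, residual_rms = best$rms,
         window = window, t0 = t_fit[1], dt = dff$dt,
         fitted = na_model_eval(t_fit, comp$amp, comp$t_half, comp$tau),
         data = y, time = t_fit, source = "na"),
    class = "axf_na_fit"
  )
}

#' Fit a 4-sigmoid product to a Ca2+ indicator transient
#'
#' Same bounded multi-start least squares as [fit_na_model()], with the
#' product model `A * prod_{i=1..4} sigma((t - t_i)/tau_i)`. The individual
#' factors of a sigmoid product are generally non-identifiable; treat the
#' fitted curve (and its derivative), not the parameters, as the result.
#'
#' @inheritParams fit_na_model
#' @return An object of class `axf_ca_fit` with fields `amplitude`,
#'   `components` (`t_half`, `tau`), `residual_rms`, `window`, `fitted`,
#'   `data`.
#' @export
fit_ca_model <- function(dff, seed = 1L, n_starts = 8L, window = NULL) {
  stopifnot(inherits(dff, "axf_ts"))
  k <- 4L
  tt <- ts_time(dff)
  if (is.null(window)) window <- range(tt)
  idx <- ts_window_idx(dff, window[1], window[2])
  t_fit <- tt[idx]
  y <- dff$values[idx]
  tau_lo <- 0.02; tau_hi <- 5
  lower <- c(0, rep(window[1], k), rep(tau_lo, k))
  upper <- c(Inf, rep(window[2], k), rep(tau_hi, k))
  resid_fn <- function(p) {
    ca_model_eval(t_fit, p[1], p[1 + seq_len(k)], p[1 + k + seq_len(k)]) - y
  }
  amp_scale <- max(max(y), .Machine$double.eps)
  i_half <- which(y >= 0.5 * max(y))[1]
  t_mid <- if (is.na(i_half)) mean(window) else t_fit[i_half]
  heuristic <- c(amp_scale, t_mid + c(-0.3, -0.1, 0.1, 0.3), rep(0.3, k))
  lhs_starts <- with_private_rng(seed, lhs::randomLHS(n_starts, 1L + 2L * k))
  starts <- rbind(
    heuristic,
    t(apply(lhs_starts, 1, function(u) {
      c(u[1] * 2 * amp_scale,
        window[1] + u[1 + seq_len(k)] * diff(window),
        exp(log(0.05) + u[1 + k + seq_len(k)] * log(2 / 0.05)))
    }))
  )
  best <- multistart_lm(resid_fn, starts, lower, upper)
  p <- best$par
  ord <- order(p[1 + seq_len(k)])
  structure(
    list(amplitude = p[1],
         components = data.frame(t_half = p[1 + seq_len(k)][ord],
                                 tau = p[1 + k + seq_len(k)][ord]),
         residual_rms = best$rms, window = window,
         t0 = t_fit[1], dt = dff$dt,
         fitted = ca_model_eval(t_fit, p[1], p[1 + seq_len(k)],
                                p[1 + k + seq_len(k)]),
         data = y, time = t_fit, source = "ca"),
    class = "axf_ca_fit"
  )
}

#' Evaluate a fitted transient model on arbitrary times
#'
#' @param fit An `axf_na_fit` or `axf_ca_fit`.
#' @param t Times in ms (default the fit's own grid).
#' @return Model values.
#' @export
model_eval <- function(fit, t = fit$time) {
  if (inherits(fit, "axf_na_fit")) {
    na_model_eval(t, fit$components$amp, fit$components$t_half,
                  fit$components$tau)
  } else if (inherits(fit, "axf_ca_fit")) {
    ca_model_eval(t, fit$amplitude, fit$components$t_half,
                  fit$components$tau)
  } else {
    stop("not a fitted transient model")
  }
}

#' Estimate the ionic current as the analytic derivative of a fit
#'
#' Evaluates the closed-form time-derivative of the fitted model function on
#' the acquisition time grid. For a single logistic component the derivative
#' peaks at exactly `a / (4 tau)` at `t = t_half`. Because the fitted
#' models are non-decreasing, the estimated current is non-negative
#' everywhere, and its integral over the window equals the fitted influx.
#'
#' @param fit An `axf_na_fit` or `axf_ca_fit`.
#' @return An object of class `c("axf_current", "axf_ts")` (units: signal
#'   per ms) with fields `source` and `fit_ref`.
#' @export
estimate_current <- function(fit) {
  d <- if (inherits(fit, "axf_na_fit")) {
    na_model_deriv(fit$time, fit$components$amp, fit$components$t_half,
                   fit$components$tau)
  } else if (inherits(fit, "axf_ca_fit")) {
    ca_model_deriv(fit$time, fit$amplitude, fit$components$t_half,
                   fit$components$tau)
  } else {
    stop("not a fitted transient model")
  }
  out <- time_series(d, dt = fit$dt, t0 = fit$t0, units = "per ms")
  out$source <- fit$source
  out$fit_ref <- fit
  class(out) <- c("axf_current", class(out))
  out
}

#' Choose the number of Na+ model components by residual improvement
#'
#' Fits 1..`n_max` components and returns the smallest `n` whose residual
#' RMS improves on `n - 1` by less than `rel_tol` (default 5%).
#'
#' @inheritParams fit_na_model
#' @param n_max Maximum components to consider (<= 6).
#' @param rel_tol Minimum relative residual improvement to justify an extra
#'   component.
#' @return The selected `axf_na_fit`.
#' @export
select_n_components <- function(dff, n_max = 4L, seed = 1L, rel_tol = 0.05,
                                n_starts = 8L) {
  stopifnot(n_max >= 1L, n_max <= 6L)
  fits <- vector("list", n_max)
  fits[[1L]] <- fit_na_model(dff, n = 1L, seed = seed, n_starts = n_starts)
  if (n_max == 1L) return(fits[[1L]])
  for (n in 2:n_max) {
    fits[[n]] <- fit_na_model(dff, n = n, seed = seed, n_starts = n_starts)
    prev <- fits[[n - 1L]]$residual_rms
    if (prev <= .Machine$double.eps ||
        (prev - fits[[n]]$residual_rms) / prev < rel_tol) {
      return(fits[[n - 1L]])
    }
  }
  fits[[n_max]]
}
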