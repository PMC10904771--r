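test_that("ROI extraction averages the right pixels", {
  mov <- two_band_movie()
  expect_equal(extract_roi_trace(mov, roi_spec(c(0, 40)))$values,
               rep(2, 10))
  # hand-computable mean over [10, 30): ten pixels of 1, ten of 3
  expect_equal(extract_roi_trace(mov, roi_spec(c(10, 30)))$values,
               rep(2, 10))
  expect_equal(extract_roi_trace(mov, roi_spec(c(0, 20)))$values,
               rep(1, 10))
  expect_error(extract_roi_trace(mov, roi_spec(c(50, 60))), "no pixels")
})

test_that("constant movies give constant traces", {
  mov <- fluor_movie(matrix(7, nrow = 5, ncol = 30), um_per_px = 1.5,
                     dt = 0.05)
  expect_equal(extract_roi_trace(mov, "mid")$values, rep(7, 5))
})

test_that("trial averaging is a pointwise mean", {
  t1 <- time_series(rep(0, 10), dt = 0.1)
  t2 <- time_series(rep(2, 10), dt = 0.1)
  expect_equal(average_trials(list(t1, t2))$values, rep(1, 10))
  expect_equal(average_trials(rep(list(t2), 5))$values, t2$values)
  expect_error(average_trials(list(t1, time_series(rep(1, 9), dt = 0.1))),
               "share")
})

test_that("trials with deviant somatic APs are excluded with a warning", {
  base <- triangle_vm()
  shifted <- triangle_vm(t_start = 2.4) # peak 0.4 ms late
  trials <- list(time_series(rep(0, 801), dt = 0.01),
                 time_series(rep(2, 801), dt = 0.01),
                 time_series(rep(4, 801), dt = 0.01))
  expect_warning(
    avg <- average_trials(trials, somatic = list(base, base, shifted)),
    "excluded"
  )
  expect_equal(attr(avg, "excluded"), 3L)
  expect_equal(avg$values, rep(1, 801)) # mean of trials 1 and 2 only
})

test_that("averaging n trials shrinks noise by sqrt(n)", {
  truth <- na_truth_trace(0.05, 3, 0.3)
  sd_single <- numeric(50); sd_avg <- numeric(50)
  for (s in 1:50) {
    fwd <- fluor_forward_model(f0 = 1000, gain = 100,
                               bleach_amps = numeric(),
                               bleach_taus = numeric(), noise_sd = 5,
                               frame_khz = 10, seed = s)
    rend <- render_fluorescence(truth, fwd, n_trials = 7)
    avg <- average_trials(rend$trials)
    resid_1 <- rend$trials[[1]]$values - rend$truth_frames$values
    resid_m <- avg$values - rend$truth_frames$values
    sd_single[s] <- stats::sd(resid_1)
    sd_avg[s] <- stats::sd(resid_m)
  }
  expect_equal(mean(sd_single) / mean(sd_avg), sqrt(7), tolerance = 0.1)
})

test_that("bleach fitting recovers exact exponentials", {
  tt <- seq(0, 80, by = 0.1)
  # constant input: amplitude ~ 0, offset ~ the constant
  flat <- time_series(rep(500, length(tt)), dt = 0.1)
  bm <- fit_bleach(flat, n_exp = 1)
  expect_lt(abs(bm$amps), 1e-6)
  expect_equal(bm$offset, 500, tolerance = 1e-6)
  # exact single exponential, parameters within 0.5% relative
  f0 <- 1000
  y <- f0 * ((1 - 0.1) + 0.1 * exp(-tt / 200))
  bm1 <- fit_bleach(time_series(y, dt = 0.1), n_exp = 1)
  expect_equal(bm1$amps, 100, tolerance = 5e-3)
  expect_equal(bm1$taus, 200, tolerance = 5e-3)
  expect_equal(bm1$offset, 900, tolerance = 5e-3)
  # exact double exponential: residual below 1e-6 * f0
  y2 <- f0 * (0.85 + 0.1 * exp(-tt / 150) + 0.05 * exp(-tt / 15))
  bm2 <- fit_bleach(time_series(y2, dt = 0.1), n_exp = 2)
  expect_lt(bm2$residual_rms, 1e-6 * f0)
})

test_that("bleach correction is exact on identity and round trips", {
  tt <- seq(0, 8, by = 0.1)
  raw <- time_series(1000 + 20 * sin(tt), dt = 0.1)
  ident <- bleach_model(amps = 0, taus = 1, offset = 1000)
  expect_equal(correct_bleach(raw, ident)$values, raw$values)
  model <- bleach_model(amps = c(80, 30), taus = c(150, 12), offset = 890)
  corrected <- correct_bleach(raw, model)
  b <- axoflux:::bleach_eval(model, tt)
  back <- ts_with_values(corrected, corrected$values * b / b[1])
  expect_equal(back$values, raw$values, tolerance = 1e-12)
})

test_that("bleach-corrected signal-free traces are flat (seeded cohort)", {
  truth <- time_series(rep(0, 81), dt = 0.1)
  ok <- logical(100)
  for (s in 1:100) {
    fwd <- fluor_forward_model(f0 = 1000, gain = 1,
                               bleach_amps = c(0.05, 0.02),
                               bleach_taus = c(300, 30), noise_sd = 2,
                               frame_khz = 10, seed = s)
    rend <- render_fluorescence(truth, fwd, n_trials = 5)
    bm <- fit_bleach(rend$dark, n_exp = 2)
    corr <- correct_bleach(average_trials(rend$dark), bm)
    drift <- abs(stats::coef(stats::lm(corr$values ~ ts_time(corr)))[2]) *
      (ts_end(corr) - corr$t0)
    ok[s] <- drift < 1e-3 * 1000
  }
  expect_gte(mean(ok), 0.95)
})

test_that("dF/F0 has the documented closed forms and invariances", {
  flat <- time_series(rep(123.4, 50), dt = 0.1)
  expect_true(all(compute_dff(flat)$values == 0))
  x <- time_series(c(rep(100, 20), 103, rep(100, 29)), dt = 0.1)
  expect_equal(compute_dff(x, baseline_window = c(0, 1))$values[21], 0.03)
  # scale invariance
  y <- time_series(100 + cumsum(runif(50)), dt = 0.1)
  expect_equal(compute_dff(y)$values,
               compute_dff(ts_with_values(y, 3.7 * y$values))$values,
               tolerance = 1e-12)
  # zero baseline mean by construction
  dff <- compute_dff(y, baseline_window = c(0, 2))
  idx <- which(ts_time(dff) <= 2)
  expect_lt(abs(mean(dff$values[idx])), 1e-12)
  expect_error(compute_dff(time_series(c(-1, -1, -1), dt = 1)), "F0")
})

test_that("averaging commutes with dF/F0 when trials share F0", {
  truth <- na_truth_trace(0.03, 3, 0.2)
  fwd <- fluor_forward_model(f0 = 1000, gain = 50, bleach_amps = numeric(),
                             bleach_taus = numeric(), noise_sd = 0,
                             frame_khz = 10, seed = 3)
  rend <- render_fluorescence(truth, fwd, n_trials = 4)
  # perturb trials with zero-baseline-mean offsets so F0 is shared
  a <- compute_dff(average_trials(rend$trials), baseline_window = c(0, 1))
  b <- average_trials(lapply(rend$trials, compute_dff,
                             baseline_window = c(0, 1)))
  expect_equal(a$values, b$values, tolerance = 1e-9)
})

test_that("Na+ calibration is a guarded linear map", {
  dff <- compute_dff(time_series(c(rep(100, 10), rep(102, 10)), dt = 0.1),
                     baseline_window = c(0, 0.5), indicator = "na")
  expect_equal(calibrate_na(dff, 1)$values, dff$values)
  expect_equal(max(calibrate_na(dff, 50)$values), 0.02 * 50)
  dff_ca <- compute_dff(time_series(rep(100, 20), dt = 0.1),
                        indicator = "ca")
  expect_error(calibrate_na(dff_ca, 50), "indicator")
  expect_error(calibrate_na(dff, -2), "positive")
})

test_that("optical AP normalisation is invariant to positive affine maps", {
  somatic <- triangle_vm()
  optical <- ts_with_values(somatic, somatic$values)
  base <- normalize_optical_ap(optical, somatic)
  for (ab in list(c(0.3, 5), c(2, -40), c(0.01, 0.2))) {
    mapped <- ts_with_values(optical, ab[1] * optical$values + ab[2])
    out <- normalize_optical_ap(mapped, somatic)
    expect_equal(out$values, base$values, tolerance = 1e-9)
  }
  # baseline and peak pinned to the somatic trace
  expect_equal(max(base$values), max(somatic$values))
  expect_equal(mean(base$values[1:50]), mean(somatic$values[1:50]),
               tolerance = 1e-9)
})

test_that("flat optical traces are rejected", {
  somatic <- triangle_vm()
  flat <- time_series(rep(0.5, length(somatic)), dt = somatic$dt)
  expect_error(normalize_optical_ap(flat, somatic), "distinguishable")
})

test_that("optical width matches ground truth after normalisation", {
  sim <- simulate_ap_experiment(neuron_sim_config(), default_toxin(), 0)
  truth <- sim_roi_trace(sim, "vm", "mid")
  rel <- ts_with_values(truth, truth$values - truth$values[1])
  fwd <- fluor_forward_model(f0 = 800, gain = 1.2, bleach_amps = numeric(),
                             bleach_taus = numeric(), noise_sd = 0,
                             frame_khz = 20, seed = 2)
  rend <- render_fluorescence(rel, fwd, n_trials = 1)
  dff <- compute_dff(rend$trials[[1]], baseline_window = c(0, 0.3))
  opt <- normalize_optical_ap(dff, sim$soma_vm, baseline_window = NULL)
  bw <- c(0, 0.3)
  # reference: the same normalisation applied to the noise-free truth,
  # isolating the render -> dF/F0 -> normalise measurement chain
  ref <- normalize_optical_ap(truth, sim$soma_vm, baseline_window = NULL)
  w_ref <- ap_metrics(ref, baseline_window = bw)$wid
  w_opt <- ap_metrics(opt, baseline_window = bw)$wid
  expect_lt(abs(w_opt - w_ref), 1 / 20 + 1e-9) # within one frame interval
})

test_that("bridge and junction corrections are exact arithmetic", {
  n <- 100
  vm <- vm_trace(rep(-69, n), dt = 0.05)
  zero_i <- time_series(rep(0, n), dt = 0.05)
  expect_equal(bridge_junction_correct(vm, zero_i, 10, junction_mv = 0)$values,
               vm$values)
  expect_equal(bridge_junction_correct(vm, zero_i, 10)$values,
               rep(-80, n))
  pulse <- time_series(c(rep(0, 20), rep(2, 60), rep(0, 20)), dt = 0.05)
  corr <- bridge_junction_correct(vm, pulse, r_bridge = 10,
                                  junction_mv = 0)
  expect_equal(vm$values - corr$values, 10 * pulse$values)
  expect_error(
    bridge_junction_correct(vm, time_series(rep(0, n - 1), dt = 0.05), 10),
    "share"
  )
})

test_that("Na+ calibration round-trips the simulator ground truth", {
  sim <- simulate_ap_experiment(neuron_sim_config(), default_toxin(), 0)
  truth <- sim_roi_trace(sim, "na_influx", "mid")
  f0 <- 1000; gain <- 2.5
  fwd <- fluor_forward_model(f0 = f0, gain = gain,
                             bleach_amps = numeric(),
                             bleach_taus = numeric(), noise_sd = 1,
                             frame_khz = 10, seed = 8)
  rend <- render_fluorescence(truth, fwd, n_trials = 6)
  dff <- compute_dff(average_trials(rend$trials),
                     baseline_window = c(0, 0.3), indicator = "na")
  # the forward gain maps influx -> dF/F0 as gain/f0; inverting it
  # recovers the ground-truth influx up to camera noise
  rec <- calibrate_na(dff, cal_factor = f0 / gain)
  ref <- axoflux:::resample_to_frames(truth, 10)
  noise_bound <- 5 * 1 / sqrt(6) / gain
  expect_lt(max(abs(rec$values - ref$values)), noise_bound)
})
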