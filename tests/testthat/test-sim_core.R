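test_that("hill occupancy obeys its closed form and bounds", {
  tox <- toxin_model(ec50 = 0.3, hill_n = 1)
  expect_equal(hill_occupancy(0.3, tox), 0.5)
  expect_equal(hill_occupancy(0, tox), 0)
  expect_equal(hill_occupancy(3, tox), 10 / 11, tolerance = 1e-12)
  # midpoint identity holds for any hill coefficient
  for (n in c(0.5, 1, 2, 3.7)) {
    expect_equal(hill_occupancy(1.2, toxin_model(ec50 = 1.2, hill_n = n)),
                 0.5)
  }
  expect_error(hill_occupancy(-1, tox), "non-negative")
})

test_that("hill occupancy is strictly increasing and near-saturating at 10x EC50", {
  for (n in c(1, 1.5, 2, 4)) {
    tox <- toxin_model(ec50 = 2, hill_n = n)
    occ <- hill_occupancy(seq(0, 40, by = 0.5), tox)
    expect_true(all(diff(occ) > 0))
    expect_true(hill_occupancy(20, tox) > 0.9)
  }
})

test_that("voltage-clamp current inactivates fully without toxin", {
  tox <- toxin_model(persistent_frac = 0)
  tr <- simulate_vc_current(vc_protocol(), na_channel(tau_inact_ms = 1),
                            tox, conc = 0)
  a <- abs(tr$values)
  expect_length(tr$values, 50 * 20)
  expect_lt(a[length(a)], 0.02 * max(a))
  expect_true(all(tr$values <= 0)) # inward throughout
})

test_that("zero channel density gives an identically zero trace", {
  tr <- simulate_vc_current(channel = na_channel(gmax_us = 0))
  expect_true(all(tr$values == 0))
})

test_that("saturating toxin with slowdown k scales T50 by k", {
  # activation much faster than inactivation; no persistent component
  ch <- na_channel(tau_act_ms = 0.02, tau_inact_ms = 1.5)
  tox <- toxin_model(ec50 = 0.3, slowdown = 3, persistent_frac = 0)
  t50_ctrl <- compute_t50(simulate_vc_current(vc_protocol(), ch, tox, 0))$t50
  t50_sat <- compute_t50(simulate_vc_current(vc_protocol(), ch, tox,
                                             conc = 300))$t50
  expect_equal(t50_sat / t50_ctrl, 3, tolerance = 0.05)
})

test_that("T50 is monotone non-decreasing in concentration", {
  ch <- na_channel()
  tox <- toxin_model(ec50 = 0.3, slowdown = 4, persistent_frac = 0.1)
  t50s <- vapply(c(0, 0.03, 0.1, 0.3, 1, 3, 10), function(conc) {
    compute_t50(simulate_vc_current(vc_protocol(), ch, tox, conc))$t50
  }, numeric(1))
  expect_true(all(diff(t50s) >= 0))
})

test_that("default AP simulation matches control width ranges", {
  sim <- simulate_ap_experiment(neuron_sim_config(), default_toxin(), 0)
  bw <- c(0, 0.3)
  soma <- ap_metrics(sim$soma_vm, baseline_window = bw)
  ais <- ap_metrics(sim_roi_trace(sim, "vm", "mid"), baseline_window = bw)
  expect_gt(soma$wid, 0.7); expect_lt(soma$wid, 1.4)
  expect_gt(ais$wid, 0.45); expect_lt(ais$wid, 1.0)
})

test_that("cumulative influx traces are non-decreasing everywhere", {
  sim <- simulate_ap_experiment(neuron_sim_config(), default_toxin(), 7)
  for (what in c("na_influx", "ca_influx")) {
    expect_true(all(apply(sim[[what]], 2, function(q) all(diff(q) >= -1e-12))))
  }
})

test_that("zero occupancy reproduces the control trace for trace", {
  cfg <- neuron_sim_config()
  s0 <- simulate_ap_experiment(cfg, default_toxin(), 0)
  # a toxin with zero occupancy at this concentration (conc = 0)
  s0b <- simulate_ap_experiment(cfg, toxin_model(ec50 = 1, slowdown = 9,
                                                 persistent_frac = 0.9), 0)
  expect_identical(s0$vm, s0b$vm)
  expect_identical(s0$na_influx, s0b$na_influx)
})

test_that("total Na influx is non-decreasing in concentration", {
  cfg <- neuron_sim_config()
  tox <- default_toxin()
  totals <- vapply(c(0, 3, 7, 30, 300), function(conc) {
    sim <- simulate_ap_experiment(cfg, tox, conc)
    sim$na_influx[nrow(sim$na_influx), 5L]
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("disabling both Ca2+ pathways removes all Ca2+ influx", {
  cfg <- neuron_sim_config(vgcc_density = function(x) 0 * x,
                           ca_perm_frac = function(x) 0 * x)
  sim <- simulate_ap_experiment(cfg, default_toxin(), 7)
  expect_true(all(sim$ca_influx == 0))
})

test_that("toxin widens the AIS AP more than the somatic AP", {
  cfg <- neuron_sim_config()
  tox <- default_toxin()
  s0 <- simulate_ap_experiment(cfg, tox, 0)
  s1 <- simulate_ap_experiment(cfg, tox, 10 * tox$ec50)
  bw <- c(0, 0.3)
  wid <- function(s, roi = NULL) {
    tr <- if (is.null(roi)) s$soma_vm else sim_roi_trace(s, "vm", roi)
    ap_metrics(tr, baseline_window = bw)$wid
  }
  soma_chg <- percent_change(wid(s0), wid(s1))
  ais_chg <- percent_change(wid(s0, "mid"), wid(s1, "mid"))
  expect_gt(ais_chg, soma_chg)
  expect_gt(soma_chg, 0)
})

test_that("toxin-induced Ca2+ gain is distal-dominant", {
  cfg <- neuron_sim_config()
  tox <- default_toxin()
  s0 <- simulate_ap_experiment(cfg, tox, 0)
  s1 <- simulate_ap_experiment(cfg, tox, 10 * tox$ec50)
  peak <- function(s, roi) max(sim_roi_trace(s, "ca_influx", roi)$values)
  distal <- percent_change(peak(s0, "distal"), peak(s1, "distal"))
  proximal <- percent_change(peak(s0, "proximal"), peak(s1, "proximal"))
  expect_gt(distal, proximal)
})

test_that("fluorescence rendering is an exact affine map when clean", {
  truth <- na_truth_trace(0.02, 3, 0.3, dt = 0.1)
  fwd <- fluor_forward_model(f0 = 500, gain = 2, bleach_amps = numeric(),
                             bleach_taus = numeric(), noise_sd = 0,
                             frame_khz = 10, seed = 5)
  rend <- render_fluorescence(truth, fwd, n_trials = 2)
  expected <- 500 * (1 + 2 * truth$values / 500)
  expect_equal(rend$trials[[1]]$values, expected, tolerance = 1e-12)
  dff <- compute_dff(rend$trials[[1]], baseline_window = c(0, 0.5))
  # truth is not exactly zero in the baseline window, so F0 differs from
  # f0 by ~1e-8 relative; compare at that precision
  expect_lt(max(abs(dff$values - 2 * truth$values / 500)), 1e-7)
})

test_that("signal-free rendering follows the bleach curve exactly", {
  truth <- time_series(rep(0, 81), dt = 0.1)
  fwd <- fluor_forward_model(f0 = 1000, gain = 3, bleach_amps = 0.1,
                             bleach_taus = 200, noise_sd = 0,
                             frame_khz = 10, seed = 1)
  rend <- render_fluorescence(truth, fwd, n_trials = 1)
  t_rel <- ts_time(rend$dark[[1]]) - rend$dark[[1]]$t0
  expect_equal(rend$dark[[1]]$values / 1000,
               (1 - 0.1) + 0.1 * exp(-t_rel / 200), tolerance = 1e-12)
})

test_that("identical seeds render bitwise-identical trials", {
  truth <- na_truth_trace(0.02, 3, 0.3)
  fwd <- fluor_forward_model(seed = 77)
  r1 <- render_fluorescence(truth, fwd, n_trials = 3)
  r2 <- render_fluorescence(truth, fwd, n_trials = 3)
  expect_identical(r1, r2)
})

test_that("rendering rejects frame rates above the truth sampling rate", {
  truth <- time_series(rep(1, 50), dt = 0.1) # 10 kHz
  fwd <- fluor_forward_model(frame_khz = 20)
  expect_error(render_fluorescence(truth, fwd), "frame rate")
})

test_that("trial mean converges to the noise-free trace", {
  truth <- na_truth_trace(0.05, 3, 0.3)
  fwd <- fluor_forward_model(f0 = 1000, gain = 100, bleach_amps = numeric(),
                             bleach_taus = numeric(), noise_sd = 4,
                             frame_khz = 10, seed = 12)
  rend <- render_fluorescence(truth, fwd, n_trials = 100)
  m <- Reduce(`+`, lapply(rend$trials, `[[`, "values")) / 100
  expect_true(all(abs(m - rend$truth_frames$values) < 3 * 4 / sqrt(100)))
})

test_that("integration blow-ups raise an explicit error", {
  cfg <- neuron_sim_config(nav_density = function(x) rep(500, length(x)))
  expect_error(simulate_ap_experiment(cfg, default_toxin(), 0),
               "integration failed")
})
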