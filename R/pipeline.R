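#' Configuration of a full synthetic-cohort run
#'
#' Bundles everything a reproducible run needs: the master seed (every other
#' seed in the run is derived from it deterministically), the cohort size
#' (default 9 cells, the usual size of these paired imaging cohorts), the
#' toxin concentration, and the simulator/forward-model settings.
#'
#' Per-cell heterogeneity: channel densities and the somatic pulse are
#' jittered per cell (log-normal, `jitter_sd` relative SD) so that control
#' AP widths straddle realistic ranges and the paired statistics see
#' cell-to-cell variance.
#'
#' @param seed Master integer seed.
#' @param cohort_n Number of cells (>= 2).
#' @param toxin_conc_nm Toxin concentration(s), nM.
#' @param toxin A [toxin_model()].
#' @param config A [neuron_sim_config()] template.
#' @param jitter_sd Relative SD of the per-cell density jitter.
#' @param n_trials_range Integer range the per-cell trial count is drawn
#'   from.
#' @param noise_sd Camera noise SD (counts) for the forward models.
#' @param indicators Character subset of c("vm", "na", "ca").
#' @return An object of class `axf_runcfg`.
#' @export
run_config <- function(seed = 1L, cohort_n = 9L, toxin_conc_nm = 7,
                       toxin = toxin_model(ec50 = 30, hill_n = 1.5,
                                           slowdown = 3,
                                           persistent_frac = 0.05),
                       config = neuron_sim_config(),
                       jitter_sd = 0.06,
                       n_trials_range = c(4L, 7L),
                       noise_sd = 1.2,
                       indicators = c("vm", "na", "ca")) {
  stopifnot(cohort_n >= 2L, all(toxin_conc_nm >= 0))
  indicators <- match.arg(indicators, c("vm", "na", "ca"),
                          several.ok = TRUE)
  structure(
    list(seed = as.integer(seed), cohort_n = as.integer(cohort_n),
         toxin_conc_nm = toxin_conc_nm, toxin = toxin, config = config,
         jitter_sd = jitter_sd, n_trials_range = as.integer(n_trials_range),
         noise_sd = noise_sd, indicators = indicators),
    class = "axf_runcfg"
  )
}

# deterministic per-cell seed derived from the master seed (kept < 2^31)
cell_seed <- function(master, cell, salt = 0L) {
  (as.integer(master) * 7919L + as.integer(cell) * 104729L +
     as.integer(salt) * 1299709L) %% 2147483647L
}

# per-cell jittered simulator config
jitter_config <- function(cfg, rc, cell) {
  with_private_rng(cell_seed(rc$seed, cell, 1L), {
    f_nav <- exp(stats::rnorm(1, 0, rc$jitter_sd))
    f_kv <- exp(stats::rnorm(1, 0, rc$jitter_sd))
    f_vgcc <- exp(stats::rnorm(1, 0, rc$jitter_sd))
    amp <- stats::runif(1, 2, 3)
    base_nav <- cfg$nav_density; base_kv <- cfg$kv_density
    base_vgcc <- cfg$vgcc_density
    neuron_sim_config(
      compartments = cfg$compartments,
      nav_density = function(x) f_nav * base_nav(x),
      kv_density = function(x) f_kv * base_kv(x),
      vgcc_density = function(x) f_vgcc * base_vgcc(x),
      ca_perm_frac = cfg$ca_perm_frac,
      pulse = list(amp_nA = amp, dur_ms = cfg$pulse$dur_ms,
                   onset_ms = cfg$pulse$onset_ms),
      v_init = cfg$v_init, record_ms = cfg$record_ms,
      biophys = cfg$biophys
    )
  })
}

# render + preprocess one ground-truth trace into an averaged dF/F0 trace
render_and_preprocess <- function(truth, frame_khz, gain, f0, noise_sd,
                                  seed, n_trials, indicator, roi = NULL,
                                  baseline_ms = 1) {
  fwd <- fluor_forward_model(f0 = f0, gain = gain, noise_sd = noise_sd,
                             frame_khz = frame_khz, seed = seed)
  rend <- render_fluorescence(truth, fwd, n_trials = n_trials)
  bleach <- fit_bleach(rend$dark, n_exp = 2L)
  avg <- average_trials(rend$trials)
  corrected <- correct_bleach(avg, bleach)
  compute_dff(corrected, baseline_window = corrected$t0 + c(0, baseline_ms),
              indicator = indicator, roi = roi)
}

# analyse a single cell; returns rows for the tidy results tables
analyze_cell <- function(rc, cell, conc) {
  cfg <- jitter_config(rc$config, rc, cell)
  sims <- list(ctrl = simulate_ap_experiment(cfg, rc$toxin, 0),
               toxin = simulate_ap_experiment(cfg, rc$toxin, conc))
  n_trials <- with_private_rng(
    cell_seed(rc$seed, cell, 2L),
    sample(seq(rc$n_trials_range[1], rc$n_trials_range[2]), 1L)
  )
  widths <- list(); changes <- list()
  bw <- c(0, cfg$pulse$onset_ms - 0.2) # baseline before pulse onset

  # --- AP width: electrode soma trace + optical AIS trace (mid ROI)
  ap <- lapply(names(sims), function(cond) {
    sim <- sims[[cond]]
    soma <- ap_metrics(sim$soma_vm, baseline_window = bw)
    ais_row <- NULL
    if ("vm" %in% rc$indicators) {
      truth <- sim_roi_trace(sim, "vm", "mid")
      # dye signal is proportional to V_m; render relative to baseline
      rel <- ts_with_values(truth, truth$values - truth$values[1])
      dff <- render_and_preprocess(
        rel, frame_khz = 20, gain = 1.2, f0 = 800,
        noise_sd = rc$noise_sd, seed = cell_seed(rc$seed, cell,
                                                 3L + (cond == "toxin")),
        n_trials = n_trials, indicator = "vm", roi = roi_spec("mid"),
        baseline_ms = bw[2]
      )
      opt <- normalize_optical_ap(dff, sim$soma_vm,
                                  baseline_window = NULL)
      ais <- ap_metrics(opt, baseline_window = bw)
      ais_row <- data.frame(cell = cell, condition = cond, site = "ais",
                            amp = ais$amp, wid = ais$wid)
    }
    rbind(data.frame(cell = cell, condition = cond, site = "soma",
                     amp = soma$amp, wid = soma$wid), ais_row)
  })
  widths <- do.call(rbind, ap)

  wchg <- function(site) {
    w <- widths[widths$site == site, ]
    percent_change(w$wid[w$condition == "ctrl"],
                   w$wid[w$condition == "toxin"])
  }
  changes$soma_wid <- wchg("soma")
  if ("vm" %in% rc$indicators) changes$ais_wid <- wchg("ais")

  # --- Na+ transient (mid ROI, 10 kHz)
  if ("na" %in% rc$indicators) {
    dffs <- lapply(names(sims), function(cond) {
      truth <- sim_roi_trace(sims[[cond]], "na_influx", "mid")
      render_and_preprocess(
        truth, frame_khz = 10, gain = 2.5, f0 = 1000,
        noise_sd = rc$noise_sd,
        seed = cell_seed(rc$seed, cell, 5L + (cond == "toxin")),
        n_trials = n_trials, indicator = "na", roi = roi_spec("mid"),
        baseline_ms = bw[2]
      )
    })
    names(dffs) <- names(sims)
    fits <- lapply(dffs, fit_na_model, n = 2L,
                   seed = cell_seed(rc$seed, cell, 7L))
    changes$na_peak <- as.numeric(peak_transient_change(
      dffs$ctrl, dffs$toxin, fits$ctrl, fits$toxin
    ))
  }

  # --- Ca2+ transients (mid for the headline change, proximal/distal split)
  if ("ca" %in% rc$indicators) {
    ca_dff <- function(cond, roi, salt) {
      truth <- sim_roi_trace(sims[[cond]], "ca_influx", roi)
      render_and_preprocess(
        truth, frame_khz = 10, gain = 500, f0 = 1000,
        noise_sd = rc$noise_sd,
        seed = cell_seed(rc$seed, cell, salt + (cond == "toxin")),
        n_trials = n_trials, indicator = "ca", roi = roi_spec(roi),
        baseline_ms = bw[2]
      )
    }
    for (spec in list(list(roi = "mid", name = "ca_peak", salt = 9L),
                      list(roi = "proximal", name = "ca_proximal",
                           salt = 11L),
                      list(roi = "distal", name = "ca_distal", salt = 13L))) {
      d_ctrl <- ca_dff("ctrl", spec$roi, spec$salt)
      d_tox <- ca_dff("toxin", spec$roi, spec$salt)
      f_ctrl <- fit_ca_model(d_ctrl, seed = cell_seed(rc$seed, cell, 15L))
      f_tox <- fit_ca_model(d_tox, seed = cell_seed(rc$seed, cell, 15L))
      changes[[spec$name]] <- as.numeric(
        peak_transient_change(d_ctrl, d_tox, f_ctrl, f_tox)
      )
    }
  }

  list(
    widths = widths,
    changes = data.frame(cell = cell, conc_nm = conc,
                         metric = names(changes),
                         change_pct = unname(unlist(changes)))
  )
}

#' Run the full synthetic-cohort pipeline
#'
#' For each cell: simulate control and toxin conditions, render seeded
#' fluorescence trials for the enabled indicators, preprocess (trial
#' averaging, bleach correction, dF/F0, optical-AP normalisation), fit the
#' transient models, and compute the per-cell percent changes; then run the
#' paired statistics across the cohort. Identical configurations produce
#' identical results.
#'
#' @param rc A [run_config()].
#' @param out_dir Optional directory; when given, tidy CSV tables, a JSON
#'   summary and a run manifest are written there.
#' @return A list of class `axf_run`: `widths` and `changes` (tidy data
#'   frames), `summary` (per-metric cohort statistics), `tests` (paired
#'   test objects), `manifest`.
#' @export
run_pipeline <- function(rc = run_config(), out_dir = NULL) {
  stopifnot(inherits(rc, "axf_runcfg"))
  conc <- rc$toxin_conc_nm[1]
  res <- lapply(seq_len(rc$cohort_n), function(cell) {
    tryCatch(analyze_cell(rc, cell, conc),
             error = function(e) {
               stop(sprintf("pipeline failed at cell %d: %s", cell,
                            conditionMessage(e)), call. = FALSE)
             })
  })
  widths <- do.call(rbind, lapply(res, `[[`, "widths"))
  changes <- do.call(rbind, lapply(res, `[[`, "changes"))
  rownames(widths) <- rownames(changes) <- NULL

  tests <- lapply(split(changes$change_pct, changes$metric), function(x) {
    if (length(x) >= 2 && stats::sd(x) > 0) paired_test(x) else NULL
  })
  summary_df <- do.call(rbind, lapply(names(tests), function(m) {
    x <- changes$change_pct[changes$metric == m]
    tst <- tests[[m]]
    data.frame(metric = m, n = length(x), mean_change = mean(x),
               sd_change = stats::sd(x),
               t_stat = if (is.null(tst)) NA_real_ else tst$t_stat,
               p_value = if (is.null(tst)) NA_real_ else tst$p_value,
               significant = if (is.null(tst)) NA else tst$significant)
  }))

  manifest <- list(
    package_version = as.character(utils::packageVersion("axoflux")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = rc$seed, cohort_n = rc$cohort_n, toxin_conc_nm = conc,
    indicators = rc$indicators,
    config_hash = config_hash(rc),
    cell_seeds = vapply(seq_len(rc$cohort_n), cell_seed,
                        integer(1), master = rc$seed)
  )
  out <- structure(
    list(widths = widths, changes = changes, summary = summary_df,
         tests = tests, manifest = manifest, config = rc),
    class = "axf_run"
  )
  if (!is.null(out_dir)) write_run_bundle(out, out_dir)
  out
}

# stable hash of the run configuration (via serialised JSON -> md5)
config_hash <- function(rc) {
  plain <- list(seed = rc$seed, cohort_n = rc$cohort_n,
                toxin_conc_nm = rc$toxin_conc_nm,
                toxin = unclass(rc$toxin),
                jitter_sd = rc$jitter_sd,
                n_trials_range = rc$n_trials_range,
                noise_sd = rc$noise_sd, indicators = rc$indicators,
                compartments = rc$config$compartments,
                pulse = rc$config$pulse, v_init = rc$config$v_init,
                record_ms = rc$config$record_ms)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Write a run's results bundle as plain-text tables
#'
#' Emits `widths.csv`, `changes.csv`, `summary.csv`, `summary.json` and
#' `manifest.json` into `out_dir`.
#'
#' @param run An `axf_run` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run_bundle <- function(run, out_dir) {
  stopifnot(inherits(run, "axf_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$widths, file.path(out_dir, "widths.csv"),
                   row.names = FALSE)
  utils::write.csv(run$changes, file.path(out_dir, "changes.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulated voltage-clamp dose-response table
#'
#' Runs [simulate_vc_current()] for a cohort of cells (channel conductance
#' jittered per cell) at each concentration, computes the per-cell relative
#' T50 increase over the cell's own control, and aggregates to a
#' per-concentration table ready for [normalize_dose_response()].
#'
#' @param concs_nm Concentrations, nM (> 0).
#' @param n_cells Cells per concentration.
#' @param toxin A [toxin_model()].
#' @param channel A [na_channel()].
#' @param protocol A [vc_protocol()].
#' @param seed Integer seed for the per-cell jitter.
#' @param isoform Label stored in the table.
#' @param jitter_sd Relative SD of per-cell `tau_inact` jitter.
#' @return List with `cells` (per-cell rows) and `table` (per-concentration
#'   means, with `normalized` column).
#' @export
simulate_dose_response <- function(concs_nm, n_cells = 6L,
                                   toxin = toxin_model(),
                                   channel = na_channel(),
                                   protocol = vc_protocol(),
                                   seed = 1L, isoform = "Nav1.2",
                                   jitter_sd = 0.1) {
  stopifnot(all(concs_nm > 0))
  rows <- list()
  for (ci in seq_along(concs_nm)) {
    conc <- concs_nm[ci]
    for (cell in seq_len(n_cells)) {
      ch <- with_private_rng(cell_seed(seed, cell, ci), {
        f <- exp(stats::rnorm(1, 0, jitter_sd))
        na_channel(gmax_us = channel$gmax_us,
                   tau_act_ms = channel$tau_act_ms,
                   tau_inact_ms = channel$tau_inact_ms * f,
                   e_rev_mv = channel$e_rev_mv)
      })
      t50_ctrl <- compute_t50(simulate_vc_current(protocol, ch, toxin, 0))
      t50_tox <- compute_t50(simulate_vc_current(protocol, ch, toxin, conc))
      amp_chg <- percent_change(t50_ctrl$peak_value, t50_tox$peak_value)
      rows[[length(rows) + 1L]] <- data.frame(
        isoform = isoform, conc_nm = conc, cell = cell,
        t50_ctrl = t50_ctrl$t50, t50_toxin = t50_tox$t50,
        rel_t50_increase = (t50_tox$t50 - t50_ctrl$t50) / t50_ctrl$t50,
        amp_change_pct = amp_chg
      )
    }
  }
  cells <- do.call(rbind, rows)
  agg <- stats::aggregate(
    cbind(mean_increase = rel_t50_increase,
          mean_amp_change = amp_change_pct) ~ isoform + conc_nm,
    data = cells, FUN = mean
  )
  agg <- agg[order(agg$isoform, agg$conc_nm), ]
  list(cells = cells, table = normalize_dose_response(agg))
}
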