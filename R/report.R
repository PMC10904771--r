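#' Human-readable report of a pipeline run
#'
#' Assembles figure-level summaries of a cohort run: a paired soma-vs-AIS
#' width scatter, per-metric transient-change plots, and (when a
#' dose-response table is supplied) the normalised T50 dose curve. Missing
#' tables are listed rather than fatal, so a partial bundle still yields a
#' partial report.
#'
#' @param run An `axf_run` from [run_pipeline()] (or a partial list with
#'   some of its tables).
#' @param dose Optional dose-response list from [simulate_dose_response()].
#' @param out_dir Optional directory; when given, panels are written as PNG
#'   files and the summary as CSV.
#' @return A list of class `axf_report`: `panels` (named list of ggplot
#'   objects), `summary` (data frame or NULL), `missing` (character vector
#'   of absent tables), `warnings`.
#' @export
make_report <- function(run, dose = NULL, out_dir = NULL) {
  panels <- list()
  missing <- character()
  warns <- character()

  widths <- run$widths
  if (is.null(widths) || nrow(widths) == 0) {
    missing <- c(missing, "widths")
  } else {
    wchg <- stats::reshape(
      widths[, c("cell", "condition", "site", "wid")],
      direction = "wide", idvar = c("cell", "site"),
      timevar = "condition"
    )
    wchg$change <- percent_change(wchg$wid.ctrl, wchg$wid.toxin)
    panels$width_change <- ggplot2::ggplot(
      wchg, ggplot2::aes(x = .data$site, y = .data$change,
                         group = .data$cell)
    ) +
      ggplot2::geom_line(colour = "grey60") +
      ggplot2::geom_point(ggplot2::aes(colour = .data$site), size = 2) +
      ggplot2::labs(x = NULL, y = "AP width change (%)",
                    title = "Soma vs AIS width change per cell") +
      ggplot2::theme_minimal() +
      ggplot2::theme(legend.position = "none")
  }

  changes <- run$changes
  if (is.null(changes) || nrow(changes) == 0) {
    missing <- c(missing, "changes")
  } else {
    panels$transient_changes <- ggplot2::ggplot(
      changes, ggplot2::aes(x = .data$metric, y = .data$change_pct)
    ) +
      ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
      ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.35,
                            colour = "red3") +
      ggplot2::labs(x = NULL, y = "change (%)",
                    title = "Per-cell transient and width changes") +
      ggplot2::theme_minimal()
    n_cells <- length(unique(changes$cell))
    if (n_cells < 2) {
      warns <- c(warns,
                 "single-cell bundle: paired statistics not available")
    }
  }

  if (!is.null(dose) && !is.null(dose$table)) {
    panels$dose_response <- ggplot2::ggplot(
      dose$table, ggplot2::aes(x = .data$conc_nm, y = .data$normalized,
                               group = .data$isoform,
                               colour = .data$isoform)
    ) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "concentration (nM)",
                    y = "normalised T50 increase",
                    title = "Dose-response of inactivation slowing") +
      ggplot2::theme_minimal()
  }

  summary_df <- run$summary
  if (is.null(summary_df)) missing <- c(missing, "summary")
  if (length(missing)) {
    warns <- c(warns, paste("missing tables:", paste(missing, collapse = ", ")))
  }
  for (w in warns) warning(w, call. = FALSE)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(panels)) {
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), panels[[nm]],
                      width = 6, height = 4, dpi = 150)
    }
    if (!is.null(summary_df)) {
      utils::write.csv(summary_df, file.path(out_dir, "report_summary.csv"),
                       row.names = FALSE)
    }
  }
  structure(list(panels = panels, summary = summary_df, missing = missing,
                 warnings = warns),
            class = "axf_report")
}
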