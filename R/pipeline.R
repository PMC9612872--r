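# End-to-end orchestration: tracks (read or simulated) -> per-line
# metrics -> ensemble MSD -> alpha fit -> regime -> group decision ->
# speed test -> machine-readable report.

#' Build a pipeline run configuration
#'
#' Each line entry is a list with `line_id`, `condition` (`"control"` or
#' `"patient"`), and either `path` (a track CSV readable by
#' [read_manual_tracking()]) or `sim` (arguments for [sim_config()]).
#' Simulated lines without an explicit seed get one derived from the run
#' seed and their position, so a run is deterministic end to end.
#'
#' @param lines List of line entries (>= 1 control; >= 0 patients).
#' @param pixel_size_um,frame_interval_min Calibration applied to lines
#'   read from plugin-style files.
#' @param max_lag_fraction Largest lag, as a fraction of each track's
#'   frame span, entering MSD curves (default 1: all lags).
#' @param min_points Tracks with fewer observed points are dropped
#'   (default 3, the minimum an MSD fit can use).
#' @param test_kind Speed test: `"unpaired_welch"` (default) or
#'   `"paired"`. Pairing unrelated cells requires equal group sizes and
#'   pairs them by rank, which is reported with a warning.
#' @param seed Run seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(lines, pixel_size_um = 1, frame_interval_min = 15,
                       max_lag_fraction = 1, min_points = 3L,
                       test_kind = c("unpaired_welch", "paired"),
                       seed = 1L) {
  test_kind <- match.arg(test_kind)
  if (!is.list(lines) || !length(lines))
    stop_tm("`lines` must be a non-empty list", "input_error")
  conds <- vapply(lines, function(l) l$condition %||% "", character(1L))
  if (!any(conds == "control"))
    stop_tm("at least one line with condition = 'control' is required",
            "input_error")
  if (!all(conds %in% c("control", "patient")))
    stop_tm("line conditions must be 'control' or 'patient'", "input_error")
  structure(list(lines = lines, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 max_lag_fraction = max_lag_fraction,
                 min_points = as.integer(min_points),
                 test_kind = test_kind, seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(stage, line_id, expr) {
  tryCatch(expr, error = function(e) {
    stop_tm(sprintf("[stage %s | line %s] %s", stage, line_id,
                    conditionMessage(e)), "pipeline_error")
  })
}

#' Run the full migration-analysis pipeline
#'
#' Stages per line: load or simulate tracks, drop short tracks, per-cell
#' metrics and line summary, ensemble MSD, alpha fit, regime
#' classification. Across lines: the CI-overlap group decision on alpha
#' and a two-tailed t-test on pooled per-cell speeds (control vs patient).
#' Any stage failure is re-raised with the stage name and line id.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: `lines` (per-line summaries,
#'   alpha estimates, regimes, MSD curves), `group_decision`,
#'   `speed_test`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop_tm("`config` must be a run_config", "input_error")
  line_out <- list()
  speeds <- list(control = numeric(), patient = numeric())
  ests <- list(control = list(), patient = list())

  for (k in seq_along(config$lines)) {
    spec <- config$lines[[k]]
    lid <- spec$line_id %||% sprintf("line%d", k)
    ts <- .stage("load", lid, {
      if (!is.null(spec$path)) {
        read_manual_tracking(spec$path,
                             pixel_size_um = config$pixel_size_um,
                             frame_interval_min = config$frame_interval_min,
                             line_id = lid, condition = spec$condition)
      } else if (!is.null(spec$sim)) {
        sim <- spec$sim
        if (is.null(sim$seed)) sim$seed <- config$seed + 1000L * k
        simulate_tracks(do.call(sim_config, sim), line_id = lid,
                        condition = "synthetic")
      } else {
        stop("line needs either `path` or `sim`")
      }
    })
    ts <- .stage("filter_min_length", lid,
                 filter_min_length(ts, config$min_points))
    summ <- .stage("metrics", lid, line_summary(ts))
    mets <- .stage("metrics", lid, trackset_metrics(ts))
    curve <- .stage("ensemble_msd", lid,
                    ensemble_msd(ts, config$max_lag_fraction))
    est <- .stage("fit_alpha", lid, fit_alpha(curve))
    regime <- classify_regime(est)
    line_out[[lid]] <- list(line_id = lid, condition = spec$condition,
                            n_cells = length(ts), summary = summ,
                            metrics = mets, msd = curve, alpha = est,
                            regime = regime)
    speeds[[spec$condition]] <- c(speeds[[spec$condition]],
                                  mets$mean_speed_um_per_min)
    ests[[spec$condition]] <- c(ests[[spec$condition]], list(est))
  }

  decision <- NULL
  sptest <- NULL
  if (length(ests$patient)) {
    decision <- compare_groups(ests$control, ests$patient)
    sptest <- .stage("speed_test", "all", {
      a <- speeds$control; b <- speeds$patient
      run_test <- function() {
        if (config$test_kind == "paired") {
          if (length(a) != length(b))
            stop("paired speed test needs equal pooled group sizes; use unpaired_welch")
          warn_tm("pairing unrelated cells by speed rank; interpret with care",
                  "rank_pairing")
          compare_speeds(sort(a), sort(b), kind = "paired")
        } else {
          compare_speeds(a, b, kind = "unpaired_welch")
        }
      }
      # degenerate (zero-variance) comparisons downgrade to a warning
      tryCatch(run_test(), trackmsd_degenerate_test_error = function(e) {
        warn_tm(paste("speed test skipped:", conditionMessage(e)),
                "degenerate_speed_test")
        NULL
      })
    })
  }

  structure(list(
    lines = line_out,
    group_decision = decision,
    speed_test = sptest,
    provenance = list(
      package_version = as.character(utils::packageVersion("trackmsd")),
      r_version = as.character(getRversion()),
      seed = config$seed,
      max_lag_fraction = config$max_lag_fraction,
      min_points = config$min_points,
      test_kind = config$test_kind,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "run_report")
}

#' Write a run report to disk
#'
#' Writes `report.json` (all numeric results and provenance) plus one
#' `msd_<line>.csv` and one `metrics_<line>.csv` per line.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  if (!inherits(report, "run_report"))
    stop_tm("`report` must be a run_report", "input_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(
    lines = lapply(report$lines, function(l) list(
      line_id = l$line_id,
      condition = l$condition,
      n_cells = l$n_cells,
      speed_mean = l$summary$speed_mean,
      speed_sd = l$summary$speed_sd,
      displacement_mean = l$summary$displacement_mean,
      displacement_sd = l$summary$displacement_sd,
      alpha = l$alpha$alpha,
      alpha_stderr = l$alpha$stderr,
      alpha_ci = c(l$alpha$ci_low, l$alpha$ci_high),
      r_squared = l$alpha$r_squared,
      n_lags_used = l$alpha$n_lags_used,
      regime = l$regime
    )),
    group_decision = if (is.null(report$group_decision)) NULL else list(
      control_mean_alpha = report$group_decision$control_mean_alpha,
      control_alphas = report$group_decision$control_alphas,
      patient_ci = apply(report$group_decision$patient_ci, 1L, as.list),
      different = report$group_decision$different,
      rule = report$group_decision$rule
    ),
    speed_test = if (is.null(report$speed_test)) NULL else
      unclass(report$speed_test),
    provenance = report$provenance
  )
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (l in report$lines) {
    utils::write.csv(as.data.frame(l$msd),
                     file.path(dir, sprintf("msd_%s.csv", l$line_id)),
                     row.names = FALSE)
    utils::write.csv(l$metrics,
                     file.path(dir, sprintf("metrics_%s.csv", l$line_id)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d line(s)\n", length(x$lines)))
  for (l in x$lines)
    cat(sprintf("  %s (%s): n=%d, alpha=%.3f (%.3f-%.3f), %s\n",
                l$line_id, l$condition, l$n_cells, l$alpha$alpha,
                l$alpha$ci_low, l$alpha$ci_high, l$regime))
  if (!is.null(x$group_decision))
    cat(sprintf("  decision: %s different\n",
                paste(ifelse(x$group_decision$different, "yes", "no"),
                      collapse = "/")))
  invisible(x)
}
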