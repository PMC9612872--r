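#' Per-cell motility metrics
#'
#' Computes the standard scratch-assay descriptors of one track: mean speed
#' (average over per-interval speeds, where the elapsed time of each
#' interval honours frame gaps), net displacement between the first and
#' last observed positions, total path length, and straightness
#' (net displacement / path length).
#'
#' @param tr A [trajectory()].
#' @return A list of class `cell_metrics` with fields `cell_id`,
#'   `mean_speed_um_per_min`, `net_displacement_um`, `path_length_um`,
#'   `straightness` (NA when the cell never moved) and `duration_min`.
#' @examples
#' tr <- trajectory("c", 1:61, x_um = 7.5 * (0:60), y_um = rep(0, 61),
#'                  frame_interval_min = 15)
#' cell_metrics(tr)$mean_speed_um_per_min # 0.5 um/min
#' @export
cell_metrics <- function(tr) {
  if (!inherits(tr, "trajectory"))
    stop_tm("`tr` must be a trajectory", "input_error")
  n <- tr$n_points
  dx <- diff(tr$x_um)
  dy <- diff(tr$y_um)
  step_len <- sqrt(dx^2 + dy^2)
  step_min <- diff(tr$frames) * tr$frame_interval_min
  net <- sqrt((tr$x_um[n] - tr$x_um[1L])^2 + (tr$y_um[n] - tr$y_um[1L])^2)
  path <- sum(step_len)
  structure(list(
    cell_id = tr$cell_id,
    mean_speed_um_per_min = mean(step_len / step_min),
    net_displacement_um = net,
    path_length_um = path,
    straightness = if (path > 0) net / path else NA_real_,
    duration_min = tr$times_min[n] - tr$times_min[1L]
  ), class = "cell_metrics")
}

#' Per-cell metrics for every trajectory in a track set
#'
#' @param ts A [trackset()].
#' @return A data.frame with one row per cell: `cell_id`,
#'   `mean_speed_um_per_min`, `net_displacement_um`, `path_length_um`,
#'   `straightness`, `duration_min`.
#' @export
trackset_metrics <- function(ts) {
  if (!inherits(ts, "trackset")) stop_tm("`ts` must be a trackset", "input_error")
  rows <- lapply(ts$trajectories, function(tr) {
    m <- cell_metrics(tr)
    data.frame(cell_id = m$cell_id,
               mean_speed_um_per_min = m$mean_speed_um_per_min,
               net_displacement_um = m$net_displacement_um,
               path_length_um = m$path_length_um,
               straightness = m$straightness,
               duration_min = m$duration_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(cell_id = character(), mean_speed_um_per_min = numeric(),
                      net_displacement_um = numeric(), path_length_um = numeric(),
                      straightness = numeric(), duration_min = numeric())
  out
}

#' Line-level mean +/- s.d. summary
#'
#' Sample mean and sample standard deviation (n-1 denominator) of per-cell
#' speed and net displacement, the quantities conventionally reported as
#' mean +/- s.d. per cell line. With a single cell the s.d. is 0 by
#' convention.
#'
#' @param ts A [trackset()] with at least one trajectory.
#' @return A list of class `line_summary`: `line_id`, `n_cells`,
#'   `speed_mean`, `speed_sd` (um/min), `displacement_mean`,
#'   `displacement_sd` (um).
#' @export
line_summary <- function(ts) {
  if (!inherits(ts, "trackset")) stop_tm("`ts` must be a trackset", "input_error")
  if (!length(ts$trajectories))
    stop_tm("empty track set: no trajectories to summarise", "input_error")
  m <- trackset_metrics(ts)
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  structure(list(
    line_id = ts$line_id,
    n_cells = nrow(m),
    speed_mean = mean(m$mean_speed_um_per_min),
    speed_sd = sd0(m$mean_speed_um_per_min),
    displacement_mean = mean(m$net_displacement_um),
    displacement_sd = sd0(m$net_displacement_um)
  ), class = "line_summary")
}

#' @export
print.line_summary <- function(x, ...) {
  cat(sprintf(
    "<line_summary> %s: n=%d, speed %.3f+/-%.3f um/min, displacement %.2f+/-%.2f um\n",
    x$line_id, x$n_cells, x$speed_mean, x$speed_sd,
    x$displacement_mean, x$displacement_sd))
  invisible(x)
}

#' Compare two groups of per-cell speeds
#'
#' Two-tailed t-test between per-cell speed vectors. `kind = "paired"`
#' reproduces the classical paired test, t = mean(d) / (sd(d)/sqrt(n)) with
#' d = a - b and df = n - 1. Because cells from two different lines have no
#' natural pairing, pairing two unrelated samples is statistically
#' questionable; `kind = "unpaired_welch"` is offered as the defensible
#' alternative. When pairing unrelated groups in the pipeline, cells are
#' paired by rank (sorted order) and a warning is emitted.
#'
#' @param a,b Numeric vectors of per-cell speeds.
#' @param kind `"paired"` or `"unpaired_welch"`.
#' @return A list of class `speed_test`: `statistic`, `df`, `p_value`,
#'   `test_kind`.
#' @examples
#' compare_speeds(c(1, 2, 3), c(2, 4, 3), kind = "paired")
#' @export
compare_speeds <- function(a, b, kind = c("paired", "unpaired_welch")) {
  kind <- match.arg(kind)
  a <- as.numeric(a); b <- as.numeric(b)
  if (anyNA(a) || anyNA(b))
    stop_tm("speed vectors must not contain NA", "input_error")
  if (kind == "paired") {
    if (length(a) != length(b))
      stop_tm("paired test requires equal-length groups", "input_error")
    n <- length(a)
    if (n < 2L) stop_tm("paired test requires n >= 2", "input_error")
    d <- a - b
    sdd <- stats::sd(d)
    if (sdd == 0)
      stop_tm("zero variance of paired differences: t statistic undefined",
              "degenerate_test_error")
    tval <- mean(d) / (sdd / sqrt(n))
    df <- n - 1
  } else {
    if (length(a) < 2L || length(b) < 2L)
      stop_tm("Welch test requires n >= 2 per group", "input_error")
    va <- stats::var(a) / length(a)
    vb <- stats::var(b) / length(b)
    if (va + vb == 0)
      stop_tm("zero variance in both groups: t statistic undefined",
              "degenerate_test_error")
    tval <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  }
  structure(list(
    statistic = tval,
    df = df,
    p_value = 2 * stats::pt(-abs(tval), df),
    test_kind = kind
  ), class = "speed_test")
}

#' @export
print.speed_test <- function(x, ...) {
  cat(sprintf("<speed_test> %s: t = %.4f, df = %.2f, p = %.4g\n",
              x$test_kind, x$statistic, x$df, x$p_value))
  invisible(x)
}
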