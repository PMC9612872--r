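#' Construct a single-cell trajectory
#'
#' A trajectory is one cell's time-ordered planar positions in micrometres,
#' in image convention (y increases downward), together with the frame
#' indices at which the cell was observed. Frames need not be contiguous:
#' cells lost for a few frames keep their gaps, and all downstream lag
#' computations use actual frame differences.
#'
#' @param cell_id Identifier for the cell (coerced to character).
#' @param frames Strictly increasing integer frame indices.
#' @param x_um,y_um Coordinates in micrometres, same length as `frames`.
#' @param frame_interval_min Time between consecutive frames, minutes.
#' @return An object of class `trajectory` with fields `cell_id`, `frames`,
#'   `times_min` (minutes from the first observed frame), `x_um`, `y_um`,
#'   `frame_interval_min` and `n_points`.
#' @examples
#' tr <- trajectory("c1", frames = 1:4, x_um = c(0, 1, 2, 3),
#'                  y_um = rep(0, 4), frame_interval_min = 15)
#' tr$times_min
#' @export
trajectory <- function(cell_id, frames, x_um, y_um, frame_interval_min) {
  check_positive_scalar(frame_interval_min, "frame_interval_min")
  frames <- as.integer(frames)
  x_um <- as.numeric(x_um)
  y_um <- as.numeric(y_um)
  n <- length(frames)
  if (n < 2L)
    stop_tm("a trajectory needs at least 2 observed points", "input_error")
  if (length(x_um) != n || length(y_um) != n)
    stop_tm("`frames`, `x_um` and `y_um` must have equal length", "input_error")
  if (anyNA(frames) || any(diff(frames) <= 0L))
    stop_tm("`frames` must be strictly increasing integers", "input_error")
  if (!all(is.finite(x_um)) || !all(is.finite(y_um)))
    stop_tm("coordinates must be finite", "input_error")
  structure(
    list(
      cell_id = as.character(cell_id)[1L],
      frames = frames,
      times_min = (frames - frames[1L]) * frame_interval_min,
      x_um = x_um,
      y_um = y_um,
      frame_interval_min = frame_interval_min,
      n_points = n
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> cell %s: %d points over %.0f min (frames %d..%d)\n",
              x$cell_id, x$n_points, x$times_min[x$n_points],
              x$frames[1L], x$frames[x$n_points]))
  invisible(x)
}

#' Construct a labelled collection of trajectories
#'
#' A track set bundles the trajectories of one cell line (or one simulated
#' condition) with its acquisition calibration: the pixel size used to
#' convert image coordinates to micrometres and the frame interval.
#'
#' @param trajectories List of [trajectory()] objects sharing one frame
#'   interval; cell ids must be unique.
#' @param line_id Label for the cell line (e.g. `"C1"`).
#' @param condition One of `"control"`, `"patient"`, `"synthetic"`.
#' @param replicate_id Replicate label.
#' @param frame_interval_min Minutes between frames; defaults to the
#'   trajectories' common value.
#' @param pixel_size_um Micrometres per pixel of the source images (1 for
#'   data already in micrometres, e.g. simulations).
#' @return An object of class `trackset`.
#' @export
trackset <- function(trajectories, line_id = "L1",
                     condition = c("synthetic", "control", "patient"),
                     replicate_id = "R1",
                     frame_interval_min = NULL, pixel_size_um = 1) {
  condition <- match.arg(condition)
  if (!is.list(trajectories) ||
      !all(vapply(trajectories, inherits, logical(1L), "trajectory")))
    stop_tm("`trajectories` must be a list of trajectory objects", "input_error")
  if (length(trajectories)) {
    ivals <- vapply(trajectories, `[[`, numeric(1L), "frame_interval_min")
    if (diff(range(ivals)) > 1e-9)
      stop_tm("all trajectories must share one frame_interval_min", "input_error")
    if (is.null(frame_interval_min)) frame_interval_min <- ivals[1L]
    ids <- vapply(trajectories, `[[`, character(1L), "cell_id")
    if (anyDuplicated(ids))
      stop_tm("cell_id values must be unique within a track set", "input_error")
    names(trajectories) <- ids
  } else if (is.null(frame_interval_min)) {
    frame_interval_min <- 15
  }
  check_positive_scalar(frame_interval_min, "frame_interval_min")
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  structure(
    list(
      line_id = as.character(line_id)[1L],
      condition = condition,
      replicate_id = as.character(replicate_id)[1L],
      frame_interval_min = frame_interval_min,
      pixel_size_um = pixel_size_um,
      trajectories = trajectories
    ),
    class = "trackset"
  )
}

#' @export
print.trackset <- function(x, ...) {
  cat(sprintf("<trackset> line %s (%s): %d cells, frame interval %g min\n",
              x$line_id, x$condition, length(x$trajectories),
              x$frame_interval_min))
  invisible(x)
}

#' @export
length.trackset <- function(x) length(x$trajectories)

#' Drop short trajectories from a track set
#'
#' @param ts A [trackset()].
#' @param min_points Minimum number of observed points a trajectory must
#'   have to be retained (at least 2).
#' @return A track set containing, in their original order, exactly the
#'   trajectories with `n_points >= min_points`.
#' @export
filter_min_length <- function(ts, min_points) {
  if (!inherits(ts, "trackset")) stop_tm("`ts` must be a trackset", "input_error")
  if (!is_scalar_num(min_points) || min_points < 2)
    stop_tm("`min_points` must be a single number >= 2", "input_error")
  keep <- vapply(ts$trajectories, function(tr) tr$n_points >= min_points,
                 logical(1L))
  ts$trajectories <- ts$trajectories[keep]
  ts
}
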