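# Track-table I/O.
#
# Two dialects are accepted:
#   (a) ImageJ "Manual Tracking" plugin exports: columns matched
#       case-insensitively to {Track n° | track | track_id}, {Slice n° |
#       slice | frame}, {X | x}, {Y | y}; extra columns ignored; positions
#       in pixels, converted to micrometres with the supplied pixel size.
#   (b) this package's own CSV (written by write_trackset): header
#       track_id,frame,time_min,x_um,y_um with "#key=value" metadata lines;
#       positions already calibrated, metadata carries the calibration.

# normalise a header token for matching: lower case, strip everything that
# is not a letter (handles "Track n°", "Track no.", "Slice n°", BOM, quotes)
.norm_header <- function(h) gsub("[^a-z]", "", tolower(h))

.match_column <- function(norm, candidates) {
  hit <- which(norm %in% candidates)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Read a track table
#'
#' Reads cell tracks either from an ImageJ Manual-Tracking-style CSV
#' (track id, slice, X, Y in pixels) or from a CSV previously written by
#' [write_trackset()] (already calibrated, with metadata comment lines).
#' Rows are grouped by track id and sorted by slice, so shuffled input
#' yields the same track set.
#'
#' @param path Path to a CSV file.
#' @param pixel_size_um Micrometres per pixel; required for plugin exports,
#'   ignored (taken from metadata) for files written by [write_trackset()].
#' @param frame_interval_min Minutes between frames; same rule as
#'   `pixel_size_um`.
#' @param line_id,condition,replicate_id Labels attached to the result;
#'   for [write_trackset()] files the stored metadata wins unless
#'   overridden explicitly.
#' @return A [trackset()].
#' @export
read_manual_tracking <- function(path, pixel_size_um = NULL,
                                 frame_interval_min = NULL,
                                 line_id = NULL, condition = NULL,
                                 replicate_id = NULL) {
  if (!file.exists(path))
    stop_tm(sprintf("file not found: %s", path), "io_error")

  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    stop_tm("file has no header line", "format_error")

  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  norm <- .norm_header(names(df))

  native <- all(c("trackid", "frame", "xum", "yum") %in% norm)
  if (native) {
    if (is.null(pixel_size_um))
      pixel_size_um <- as.numeric(meta$pixel_size_um %||% 1)
    if (is.null(frame_interval_min))
      frame_interval_min <- as.numeric(meta$frame_interval_min %||% NA)
    if (is.na(frame_interval_min))
      stop_tm("frame_interval_min neither supplied nor in file metadata",
              "format_error")
    i_track <- .match_column(norm, "trackid")
    i_slice <- .match_column(norm, "frame")
    i_x <- .match_column(norm, "xum")
    i_y <- .match_column(norm, "yum")
    scale <- 1 # already micrometres
  } else {
    if (is.null(pixel_size_um) || is.null(frame_interval_min))
      stop_tm("pixel_size_um and frame_interval_min are required for plugin exports",
              "input_error")
    i_track <- .match_column(norm, c("trackn", "trackno", "track", "trackid"))
    i_slice <- .match_column(norm, c("slicen", "sliceno", "slice", "frame"))
    i_x <- .match_column(norm, "x")
    i_y <- .match_column(norm, "y")
    missing <-c("track id", "slice/frame", "X", "Y")[is.na(c(i_track, i_slice, i_x, i_y))]
    if (length(missing))
      stop_tm(sprintf("cannot map required column(s): %s",
                      paste(missing, collapse = ", ")), "format_error")
    scale <- pixel_size_um
  }
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_positive_scalar(frame_interval_min, "frame_interval_min")

  if (nrow(df)) {
    xs <- suppressWarnings(as.numeric(df[[i_x]]))
    ys <- suppressWarnings(as.numeric(df[[i_y]]))
    bad <- which(is.na(xs) | is.na(ys))
    if (length(bad))
      stop_tm(sprintf("non-numeric coordinate at data row %d", bad[1L]),
              "parse_error")
    slices <- suppressWarnings(as.integer(as.numeric(df[[i_slice]])))
    if (anyNA(slices))
      stop_tm(sprintf("non-numeric slice/frame at data row %d",
                      which(is.na(slices))[1L]), "parse_error")
    tracks <- df[[i_track]]
    key <- paste(tracks, slices, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      parts <- strsplit(dup, "\r", fixed = TRUE)[[1L]]
      stop_tm(sprintf("duplicate (track, slice) row: track %s, slice %s",
                      parts[1L], parts[2L]), "integrity_error")
    }
    trajs <- lapply(split(seq_len(nrow(df)), factor(tracks, levels = unique(tracks))),
                    function(idx) {
      o <- idx[order(slices[idx])]
      trajectory(cell_id = tracks[o[1L]], frames = slices[o],
                 x_um = xs[o] * scale, y_um = ys[o] * scale,
                 frame_interval_min = frame_interval_min)
    })
    names(trajs) <- NULL
  } else {
    trajs <- list()
  }

  trackset(
    trajs,
    line_id = line_id %||% meta$line_id %||% "L1",
    condition = condition %||% meta$condition %||% "synthetic",
    replicate_id = replicate_id %||% meta$replicate_id %||% "R1",
    frame_interval_min = frame_interval_min,
    pixel_size_um = pixel_size_um
  )
}

#' Write a track set to CSV
#'
#' Writes calibrated positions with a `#key=value` metadata block, so the
#' file is self-describing and [read_manual_tracking()] round-trips it.
#'
#' @param ts A [trackset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trackset <- function(ts, path) {
  if (!inherits(ts, "trackset")) stop_tm("`ts` must be a trackset", "input_error")
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e)
                    stop_tm(sprintf("cannot open '%s' for writing", path),
                            "io_error"))
  on.exit(close(con))
  writeLines(c(
    sprintf("#line_id=%s", ts$line_id),
    sprintf("#condition=%s", ts$condition),
    sprintf("#replicate_id=%s", ts$replicate_id),
    sprintf("#pixel_size_um=%s", format(ts$pixel_size_um, digits = 17)),
    sprintf("#frame_interval_min=%s", format(ts$frame_interval_min, digits = 17)),
    "track_id,frame,time_min,x_um,y_um"
  ), con)
  for (tr in ts$trajectories) {
    writeLines(sprintf("%s,%d,%s,%s,%s", tr$cell_id, tr$frames,
                       format(tr$times_min, digits = 17, trim = TRUE),
                       format(tr$x_um, digits = 17, trim = TRUE),
                       format(tr$y_um, digits = 17, trim = TRUE)), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
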