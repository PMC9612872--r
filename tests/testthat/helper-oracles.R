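# Shared fixtures and independent oracles. Oracles deliberately use the
# naive O(n^2) / element-by-element formulation, not the package's code
# paths.

# straight-line walker: speed um/min along +x
straight_traj <- function(n_frames = 61L, speed = 0.5, interval = 15,
                          id = "s1") {
  t <- (0:(n_frames - 1L)) * interval
  trajectory(id, frames = 1:n_frames, x_um = speed * t,
             y_um = rep(0, n_frames), frame_interval_min = interval)
}

# random trajectory, optionally with frame gaps
random_traj <- function(n = 10L, id = "r1", interval = 15, gapped = FALSE) {
  frames <- if (gapped) sort(sample.int(3L * n, n)) else 1:n
  trajectory(id, frames = frames, x_um = stats::rnorm(n, sd = 5),
             y_um = stats::rnorm(n, sd = 5), frame_interval_min = interval)
}

# O(n^2) double-loop MSD oracle: visit every ordered index pair (i, j),
# bin its squared displacement by the frame separation k = frames_j -
# frames_i, then average per bin. Independent of the package's matching
# strategy.
msd_oracle <- function(tr, max_lag_fraction = 1) {
  span <- tr$frames[tr$n_points] - tr$frames[1L]
  kmax <- floor(max_lag_fraction * span)
  sums <- numeric(span); cnts <- integer(span)
  for (i in seq_len(tr$n_points)) for (j in seq_len(tr$n_points)) {
    k <- tr$frames[j] - tr$frames[i]
    if (k >= 1L && k <= kmax) {
      sums[k] <- sums[k] +
        (tr$x_um[j] - tr$x_um[i])^2 + (tr$y_um[j] - tr$y_um[i])^2
      cnts[k] <- cnts[k] + 1L
    }
  }
  keep <- which(cnts > 0L & seq_len(span) <= kmax)
  list(lag = keep * tr$frame_interval_min, msd = sums[keep] / cnts[keep],
       n = cnts[keep])
}

# element-by-element path length
path_oracle <- function(tr) {
  s <- 0
  for (i in 2:tr$n_points)
    s <- s + sqrt((tr$x_um[i] - tr$x_um[i - 1L])^2 +
                  (tr$y_um[i] - tr$y_um[i - 1L])^2)
  s
}

# normal-equations OLS slope/stderr oracle for log-log fits
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  list(slope = b, intercept = a, stderr = se)
}

# write a plugin-style Manual Tracking CSV
write_plugin_csv <- function(path, track, slice, x, y,
                             header = c("Track n°", "Slice n°", "X", "Y")) {
  df <- data.frame(track, slice, x, y)
  names(df) <- header
  utils::write.csv(df, path, row.names = FALSE)
}

two_cell_set <- function(interval = 15) {
  trackset(list(
    straight_traj(10, 0.4, interval, id = "a"),
    straight_traj(10, 0.6, interval, id = "b")
  ), line_id = "demo")
}
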