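# Seed-reproducible 2-D motion models.
#
# All models emit positions in micrometres on a frame grid 1..n_frames with
# a fixed frame interval, starting at the origin. One independent process
# per axis where the model is stochastic (isotropy); MSD is additive over
# axes, so per-axis theory carries over by a factor 2.

.sim_models <- c("brownian", "ballistic", "prw", "fbm", "circular",
                 "back_and_forth", "mixture")

#' Simulation configuration
#'
#' Describes one motion model and its parameters. Model-specific `params`:
#' \describe{
#'   \item{brownian}{`diffusion_um2_per_min` (D): per-axis increment
#'     variance over a step of dt minutes is `2 * D * dt`, so the 2-D MSD
#'     is `4 D tau` (alpha = 1).}
#'   \item{ballistic}{`speed_um_per_min` (v): constant velocity along a
#'     per-cell uniform random heading; MSD = `v^2 tau^2` (alpha = 2).}
#'   \item{prw}{`speed_um_per_min` (mean scalar speed),
#'     `persistence_time_min` (P): velocity is a per-axis
#'     Ornstein-Uhlenbeck process with relaxation time P, advanced with the
#'     exact joint velocity/position transition (no Euler bias). Ballistic
#'     at lags << P, diffusive at lags >> P.}
#'   \item{fbm}{`hurst` (H in (0,1)), `sigma_um` (per-axis scale):
#'     exact fractional Brownian motion per axis via Cholesky factorisation
#'     of cov(t, s) = sigma^2/2 (t^2H + s^2H - |t-s|^2H); 2-D MSD =
#'     `2 sigma^2 tau^2H` (alpha = 2H).}
#'   \item{circular}{`radius_um` (r), `angular_speed_rad_per_min` (omega):
#'     uniform rotation on a circle through the origin, random initial
#'     phase and direction; squared displacement never exceeds `(2r)^2`.}
#'   \item{back_and_forth}{`amplitude_um` (A), `period_min` (T): sinusoidal
#'     reciprocation along a per-cell random axis with random phase.}
#'   \item{mixture}{`components`: list of `list(weight =, config =)` where
#'     each `config` is itself a `sim_config` (its `n_cells`/`seed` are
#'     ignored); weights must sum to 1. Each cell is drawn from one
#'     component.}
#' }
#'
#' @param model One of `"brownian"`, `"ballistic"`, `"prw"`, `"fbm"`,
#'   `"circular"`, `"back_and_forth"`, `"mixture"`.
#' @param n_cells Number of cells to simulate.
#' @param n_frames Frames per cell (default 61, i.e. 15 h at 15-min
#'   sampling).
#' @param frame_interval_min Minutes between frames (default 15).
#' @param seed Integer RNG seed; identical configs give bitwise-identical
#'   track sets.
#' @param geometry Start-position geometry: `"origin"` (default; every
#'   cell starts at (0, 0)) or `"gap500"` (cells start at uniform random
#'   positions inside two 500-um-deep strips flanking a 500-um cell-free
#'   gap, echoing a two-well insert). MSD, speed and displacement are
#'   translation-invariant, so this only matters for visual comparison of
#'   raw tracks.
#' @param ... Model parameters, see Details.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model, n_cells = 100L, n_frames = 61L,
                       frame_interval_min = 15, seed = 1L,
                       geometry = c("origin", "gap500"), ...) {
  geometry <- match.arg(geometry)
  if (!is.character(model) || length(model) != 1L || !model %in% .sim_models)
    stop_tm(sprintf("unknown model '%s' (expected one of: %s)",
                    paste(model, collapse = ","),
                    paste(.sim_models, collapse = ", ")), "config_error")
  if (!is_scalar_num(n_cells) || n_cells < 1)
    stop_tm("`n_cells` must be >= 1", "config_error")
  if (!is_scalar_num(n_frames) || n_frames < 2)
    stop_tm("`n_frames` must be >= 2", "config_error")
  check_positive_scalar(frame_interval_min, "frame_interval_min")
  params <- list(...)
  defaults <- switch(model,
    brownian = list(diffusion_um2_per_min = 1),
    ballistic = list(speed_um_per_min = 0.5),
    prw = list(speed_um_per_min = 0.5, persistence_time_min = 150),
    fbm = list(hurst = 0.5, sigma_um = 1),
    circular = list(radius_um = 30, angular_speed_rad_per_min = 2 * pi / 450),
    back_and_forth = list(amplitude_um = 40, period_min = 300),
    mixture = list(components = list())
  )
  for (nm in names(params)) {
    if (!nm %in% names(defaults))
      stop_tm(sprintf("unknown parameter '%s' for model '%s'", nm, model),
              "config_error")
    defaults[[nm]] <- params[[nm]]
  }
  params <- defaults
  if (model == "fbm" &&
      (!is_scalar_num(params$hurst) || params$hurst <= 0 || params$hurst >= 1))
    stop_tm("fbm requires hurst in (0, 1)", "config_error")
  if (model == "mixture") {
    comps <- params$components
    if (!length(comps))
      stop_tm("mixture requires a non-empty `components` list", "config_error")
    w <- vapply(comps, function(co) co$weight, numeric(1L))
    if (any(w <= 0) || abs(sum(w) - 1) > 1e-9)
      stop_tm("mixture weights must be positive and sum to 1", "config_error")
    for (co in comps)
      if (!inherits(co$config, "sim_config") || co$config$model == "mixture")
        stop_tm("each mixture component needs a non-mixture sim_config",
                "config_error")
  } else {
    rates <- params[vapply(params, is.numeric, logical(1L))]
    if (any(unlist(rates) <= 0))
      stop_tm("all rate/scale parameters must be > 0", "config_error")
  }
  structure(list(model = model, n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames),
                 frame_interval_min = frame_interval_min,
                 seed = as.integer(seed), geometry = geometry,
                 params = params),
            class = "sim_config")
}

# run expr under a given seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- single-cell position generators (n x 2 matrices, start at origin) ----

.sim_cell <- function(model, params, n, dt, times) {
  switch(model,
    brownian = {
      sd_step <- sqrt(2 * params$diffusion_um2_per_min * dt)
      apply(matrix(stats::rnorm(2L * (n - 1L), 0, sd_step), ncol = 2L),
            2L, function(inc) c(0, cumsum(inc)))
    },
    ballistic = {
      theta <- stats::runif(1L, 0, 2 * pi)
      v <- params$speed_um_per_min
      cbind(v * times * cos(theta), v * times * sin(theta))
    },
    prw = .sim_cell_prw(params, n, dt),
    fbm = {
      L <- .fbm_chol(params$hurst, params$sigma_um, times[-1L])
      x <- c(0, crossprod(L, stats::rnorm(n - 1L)))
      y <- c(0, crossprod(L, stats::rnorm(n - 1L)))
      cbind(x, y)
    },
    circular = {
      phi0 <- stats::runif(1L, 0, 2 * pi)
      s <- sample(c(-1, 1), 1L)
      r <- params$radius_um
      ang <- phi0 + s * params$angular_speed_rad_per_min * times
      cbind(r * (cos(ang) - cos(phi0)), r * (sin(ang) - sin(phi0)))
    },
    back_and_forth = {
      theta <- stats::runif(1L, 0, 2 * pi)
      phi <- stats::runif(1L, 0, 2 * pi)
      disp <- params$amplitude_um *
        (sin(2 * pi * times / params$period_min + phi) - sin(phi))
      cbind(disp * cos(theta), disp * sin(theta))
    },
    stop_tm(sprintf("unknown model '%s'", model), "config_error")
  )
}

# exact OU velocity + integrated-position transition (Gillespie update):
# over a step dt with relaxation time P and stationary per-axis variance
# sv2, with mu = exp(-dt/P),
#   v' = v mu + xi_v,          Var xi_v = sv2 (1 - mu^2)
#   x' = x + v P (1 - mu) + xi_x,
#       Var xi_x = sv2 P^2 (2 dt / P - 3 + 4 mu - mu^2)
#   Cov(xi_v, xi_x) = sv2 P (1 - mu)^2
.sim_cell_prw <- function(params, n, dt) {
  P <- params$persistence_time_min
  # mean scalar speed of a 2-D Rayleigh velocity is sv * sqrt(pi/2)
  sv2 <- (params$speed_um_per_min / sqrt(pi / 2))^2
  mu <- exp(-dt / P)
  var_v <- sv2 * (1 - mu^2)
  var_x <- sv2 * P^2 * (2 * dt / P - 3 + 4 * mu - mu^2)
  cov_vx <- sv2 * P * (1 - mu)^2
  # Cholesky of the 2x2 (xi_x, xi_v) covariance
  a11 <- sqrt(var_x)
  a21 <- cov_vx / a11
  a22 <- sqrt(max(var_v - a21^2, 0))
  out <- matrix(0, n, 2L)
  for (axis in 1:2) {
    v <- stats::rnorm(1L, 0, sqrt(sv2)) # stationary start
    x <- 0
    z <- matrix(stats::rnorm(2L * (n - 1L)), ncol = 2L)
    for (k in 2:n) {
      xi_x <- a11 * z[k - 1L, 1L]
      xi_v <- a21 * z[k - 1L, 1L] + a22 * z[k - 1L, 2L]
      x <- x + v * P * (1 - mu) + xi_x
      v <- v * mu + xi_v
      out[k, axis] <- x
    }
  }
  out
}

# lower-triangular-like factor (here: upper chol, used via crossprod) of the
# fBm covariance over the positive observation times
.fbm_chol <- function(H, sigma, times) {
  t2h <- times^(2 * H)
  G <- outer(t2h, t2h, function(a, b) a + b) -
    abs(outer(times, times, "-"))^(2 * H)
  G <- sigma^2 / 2 * G
  tryCatch(chol(G), error = function(e)
    stop_tm(paste0("fBm covariance not positive definite (degenerate or ",
                   "duplicated times); jitter the time grid"),
            "numerical_error"))
}

#' Simulate a track set from a motion model
#'
#' Deterministic given the config's seed: the same `sim_config` always
#' yields a bitwise-identical track set.
#'
#' @param config A [sim_config()].
#' @param line_id,condition,replicate_id Labels for the resulting
#'   [trackset()].
#' @return A [trackset()] of `n_cells` trajectories with `n_frames` points
#'   each, positions in micrometres, frames 1..n_frames.
#' @examples
#' ts <- simulate_tracks(sim_config("brownian", n_cells = 5, seed = 1,
#'                                  diffusion_um2_per_min = 1))
#' length(ts)
#' @export
simulate_tracks <- function(config, line_id = config$model,
                            condition = "synthetic", replicate_id = "R1") {
  if (!inherits(config, "sim_config"))
    stop_tm("`config` must be a sim_config", "config_error")
  n <- config$n_frames
  dt <- config$frame_interval_min
  times <- (0:(n - 1L)) * dt
  .with_seed(config$seed, {
    if (config$model == "mixture") {
      comps <- config$params$components
      w <- vapply(comps, function(co) co$weight, numeric(1L))
      assign_idx <- sample.int(length(comps), config$n_cells,
                               replace = TRUE, prob = w)
    }
    trajs <- vector("list", config$n_cells)
    for (i in seq_len(config$n_cells)) {
      if (config$model == "mixture") {
        sub <- comps[[assign_idx[i]]]$config
        pos <- .sim_cell(sub$model, sub$params, n, dt, times)
      } else {
        pos <- .sim_cell(config$model, config$params, n, dt, times)
      }
      if (identical(config$geometry, "gap500")) {
        # two 1000 x 500 um strips flanking a 500-um cell-free gap along y
        side <- sample(c(-1, 1), 1L)
        pos[, 1L] <- pos[, 1L] + stats::runif(1L, 0, 1000)
        pos[, 2L] <- pos[, 2L] + side * stats::runif(1L, 250, 750)
      }
      trajs[[i]] <- trajectory(sprintf("cell_%03d", i), frames = 1:n,
                               x_um = pos[, 1L], y_um = pos[, 2L],
                               frame_interval_min = dt)
    }
    trackset(trajs, line_id = line_id, condition = condition,
             replicate_id = replicate_id, frame_interval_min = dt,
             pixel_size_um = 1)
  })
}

#' Five-line study-like trajectory panel
#'
#' A fixture that mirrors a typical scratch-assay comparison: three
#' "control-like" lines of persistently migrating cells (persistent random
#' walks with long persistence times, ensemble alpha around 1.5-1.7) and
#' two "patient-like" lines whose cells mix near-Brownian wanderers,
#' circular movers, back-and-forth movers and a minority of directed cells
#' (ensemble alpha around 1.1-1.3). All lines: 100 cells, 61 frames,
#' 15-min interval. Mixture weights are fixture choices, not estimates of
#' any real population.
#'
#' @param seed Integer seed; line-specific seeds are derived from it.
#' @param n_cells Cells per line (default 100).
#' @return Named list of five [trackset()]s: controls `C1`-`C3`
#'   (condition `"control"`), patients `B1`-`B2` (condition `"patient"`).
#' @export
make_study_like_panel <- function(seed = 1L, n_cells = 100L) {
  seed <- as.integer(seed)
  patient_mix <- function(sd) {
    comps <- list(
      list(weight = 0.45, config = sim_config("brownian", seed = 0,
                                              diffusion_um2_per_min = 2)),
      list(weight = 0.20, config = sim_config("circular", seed = 0,
                                              radius_um = 25,
                                              angular_speed_rad_per_min = 2 * pi / 400)),
      list(weight = 0.20, config = sim_config("back_and_forth", seed = 0,
                                              amplitude_um = 35,
                                              period_min = 360)),
      list(weight = 0.15, config = sim_config("ballistic", seed = 0,
                                              speed_um_per_min = 0.3))
    )
    sim_config("mixture", n_cells = n_cells, seed = sd, components = comps)
  }
  ctrl <- function(sd, speed, persist)
    sim_config("prw", n_cells = n_cells, seed = sd,
               speed_um_per_min = speed, persistence_time_min = persist)
  list(
    C1 = simulate_tracks(ctrl(seed + 11L, 0.55, 140), "C1", "control"),
    C2 = simulate_tracks(ctrl(seed + 12L, 0.30, 160), "C2", "control"),
    C3 = simulate_tracks(ctrl(seed + 13L, 0.25, 200), "C3", "control"),
    B1 = simulate_tracks(patient_mix(seed + 21L), "B1", "patient"),
    B2 = simulate_tracks(patient_mix(seed + 22L), "B2", "patient")
  )
}
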