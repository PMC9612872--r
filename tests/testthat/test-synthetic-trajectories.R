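test_that("simulation is seed-deterministic and shape-correct", {
  cfg <- sim_config("brownian", n_cells = 5L, n_frames = 21L, seed = 9L,
                    diffusion_um2_per_min = 1)
  a <- simulate_tracks(cfg)
  b <- simulate_tracks(cfg)
  expect_identical(a, b)
  expect_length(a$trajectories, 5L)
  expect_true(all(vapply(a$trajectories, function(tr) tr$n_points,
                         integer(1L)) == 21L))
  # different seed -> different tracks
  c2 <- simulate_tracks(sim_config("brownian", n_cells = 5L, n_frames = 21L,
                                   seed = 10L, diffusion_um2_per_min = 1))
  expect_false(identical(a$trajectories[[1L]]$x_um,
                         c2$trajectories[[1L]]$x_um))
  # simulation must not disturb the caller's RNG stream
  set.seed(123); before <- stats::rnorm(1)
  set.seed(123); invisible(simulate_tracks(cfg)); after <- stats::rnorm(1)
  expect_identical(before, after)
})

test_that("config validation rejects bad models and parameters", {
  expect_error(sim_config("levy"), class = "trackmsd_config_error")
  expect_error(sim_config("brownian", diffusion_um2_per_min = -1),
               class = "trackmsd_config_error")
  expect_error(sim_config("brownian", bogus = 1),
               class = "trackmsd_config_error")
  expect_error(sim_config("fbm", hurst = 1.2), class = "trackmsd_config_error")
  expect_error(sim_config("mixture", components = list(
    list(weight = 0.5, config = sim_config("brownian")),
    list(weight = 0.6, config = sim_config("ballistic"))
  )), class = "trackmsd_config_error")
})

test_that("brownian increments have the configured variance and MSD", {
  D <- 1.5; dt <- 15
  ts <- simulate_tracks(sim_config("brownian", n_cells = 200L, n_frames = 61L,
                                   seed = 4L, diffusion_um2_per_min = D))
  incs <- unlist(lapply(ts$trajectories, function(tr)
    c(diff(tr$x_um), diff(tr$y_um))))
  # chi-square bound: 24000 increments, sample var within 5% of 2 D dt
  expect_equal(stats::var(incs), 2 * D * dt, tolerance = 0.05)
  # ensemble MSD within 3 s.e. of 4 D tau at the first lags
  ens <- ensemble_msd(ts)
  for (li in 1:4) {
    se <- stats::sd(vapply(ts$trajectories, function(tr)
      time_averaged_msd(tr)$msd_um2[li], numeric(1L))) / sqrt(200)
    expect_lt(abs(ens$msd_um2[li] - 4 * D * ens$lags_min[li]), 3 * se)
  }
})

test_that("ballistic cells are exactly ballistic", {
  ts <- simulate_tracks(sim_config("ballistic", n_cells = 10L, seed = 2L,
                                   speed_um_per_min = 0.5))
  for (tr in ts$trajectories) {
    m <- cell_metrics(tr)
    expect_equal(m$net_displacement_um, 450, tolerance = 1e-9)
    expect_equal(m$straightness, 1, tolerance = 1e-12)
  }
  est <- suppressWarnings(fit_alpha(ensemble_msd(ts)))
  expect_equal(est$alpha, 2, tolerance = 1e-9)
})

test_that("fBm has the exact target covariance structure", {
  H <- 0.75; sigma <- 1.3
  ts <- simulate_tracks(sim_config("fbm", n_cells = 400L, n_frames = 8L,
                                   seed = 6L, hurst = H, sigma_um = sigma))
  X <- t(vapply(ts$trajectories, function(tr) tr$x_um, numeric(8L)))
  times <- (0:7) * 15
  # empirical covariance vs sigma^2/2 (t^2H + s^2H - |t-s|^2H)
  emp <- stats::cov(X)
  theo <- sigma^2 / 2 * (outer(times^(2 * H), times^(2 * H), "+") -
                           abs(outer(times, times, "-"))^(2 * H))
  expect_lt(max(abs(emp[-1, -1] - theo[-1, -1]) / max(theo)), 0.15)
})

test_that("fBm ensembles recover alpha = 2H; H = 0.5 looks Brownian", {
  for (H in c(0.3, 0.75)) {
    ts <- simulate_tracks(sim_config("fbm", n_cells = 100L, seed = 60L,
                                     hurst = H, sigma_um = 1))
    est <- fit_alpha(ensemble_msd(ts))
    expect_lt(abs(est$alpha - 2 * H), 0.1)
  }
  ts5 <- simulate_tracks(sim_config("fbm", n_cells = 100L, seed = 61L,
                                    hurst = 0.5, sigma_um = sqrt(2 * 1)))
  expect_equal(classify_regime(ensemble_alpha(ts5, seed = 62L)), "brownian")
})

test_that("circular tracks close and their MSD is bounded by (2r)^2", {
  r <- 30
  # period 450 min -> integer periods at t = 450, 900
  ts <- simulate_tracks(sim_config("circular", n_cells = 20L, seed = 13L,
                                   radius_um = r,
                                   angular_speed_rad_per_min = 2 * pi / 450))
  for (tr in ts$trajectories) {
    cu <- time_averaged_msd(tr)
    expect_true(all(cu$msd_um2 <= (2 * r)^2 + 1e-9))
    i450 <- which(abs(tr$times_min - 450) < 1e-9)
    expect_lt(sqrt(tr$x_um[i450]^2 + tr$y_um[i450]^2), 1e-6)
  }
})

test_that("back-and-forth cells stay on one axis and reciprocate", {
  ts <- simulate_tracks(sim_config("back_and_forth", n_cells = 10L,
                                   seed = 14L, amplitude_um = 40,
                                   period_min = 300))
  for (tr in ts$trajectories) {
    P <- cbind(tr$x_um, tr$y_um)
    # rank-1: all positions on a line through the origin
    expect_lt(svd(P)$d[2L], 1e-9)
    # returns to start after an integer number of periods
    i300 <- which(abs(tr$times_min - 300) < 1e-9)
    expect_lt(abs(tr$x_um[i300]) + abs(tr$y_um[i300]), 1e-9)
  }
})

test_that("PRW shows the ballistic-to-diffusive crossover in lag windows", {
  ts <- simulate_tracks(sim_config("prw", n_cells = 150L, seed = 15L,
                                   speed_um_per_min = 0.5,
                                   persistence_time_min = 75))
  ens <- ensemble_msd(ts)
  short <- fit_alpha(ens, lag_range = c(15, 60))    # lags < P
  long <- fit_alpha(ens, lag_range = c(450, 900))   # lags >> P
  expect_gt(short$alpha, long$alpha)
  expect_gt(short$alpha, 1.5)
  expect_lt(long$alpha, 1.5)
})

test_that("mixtures draw each cell from one component, reproducibly", {
  cfg <- sim_config("mixture", n_cells = 30L, seed = 16L, components = list(
    list(weight = 0.5, config = sim_config("ballistic", speed_um_per_min = 0.5)),
    list(weight = 0.5, config = sim_config("circular", radius_um = 10,
                                           angular_speed_rad_per_min = 0.01))
  ))
  ts <- simulate_tracks(cfg)
  expect_identical(ts, simulate_tracks(cfg))
  straightness <- vapply(ts$trajectories,
                         function(tr) cell_metrics(tr)$straightness,
                         numeric(1L))
  # ballistic cells have straightness exactly 1, circular ones well below
  expect_true(any(abs(straightness - 1) < 1e-9))
  expect_true(any(straightness < 0.9))
})

test_that("gap500 geometry shifts starts into two strips without touching MSD", {
  base <- sim_config("ballistic", n_cells = 30L, seed = 22L,
                     speed_um_per_min = 0.5)
  gap <- sim_config("ballistic", n_cells = 30L, seed = 22L,
                    speed_um_per_min = 0.5, geometry = "gap500")
  ts <- simulate_tracks(gap)
  y0 <- vapply(ts$trajectories, function(tr) tr$y_um[1L], numeric(1L))
  expect_true(all(abs(y0) >= 250 & abs(y0) <= 750))
  expect_true(any(y0 > 0) && any(y0 < 0))
  # displacement statistics are translation-invariant
  s1 <- line_summary(simulate_tracks(base))
  s2 <- line_summary(ts)
  expect_equal(s2$displacement_mean, s1$displacement_mean, tolerance = 1e-9)
})

test_that("study-like panel has the advertised shape and phenotypes", {
  panel <- make_study_like_panel(seed = 1L, n_cells = 40L)
  expect_named(panel, c("C1", "C2", "C3", "B1", "B2"))
  expect_true(all(vapply(panel, length, integer(1L)) == 40L))
  conds <- vapply(panel, function(ts) ts$condition, character(1L))
  expect_equal(unname(conds), c(rep("control", 3), rep("patient", 2)))
  ests <- lapply(panel, function(ts) fit_alpha(ensemble_msd(ts)))
  # controls clearly more persistent than patients
  actrl <- vapply(ests[1:3], `[[`, numeric(1L), "alpha")
  apat <- vapply(ests[4:5], `[[`, numeric(1L), "alpha")
  expect_gt(min(actrl), max(apat))
  gd <- compare_groups(ests[1:3], ests[4:5])
  expect_true(all(gd$different))
  for (e in ests[4:5])
    expect_false(classify_regime(e) == "ballistic_like")
})
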