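test_that("time-averaged MSD matches closed forms", {
  # 4 collinear points 1 um apart: MSD = (1, 4, 9) with pair counts (3, 2, 1)
  tr <- trajectory("c", 1:4, x_um = c(0, 1, 2, 3), y_um = rep(0, 4),
                   frame_interval_min = 15)
  cu <- time_averaged_msd(tr)
  expect_equal(cu$lags_min, c(15, 30, 45))
  expect_equal(cu$msd_um2, c(1, 4, 9))
  expect_equal(cu$n_pairs, c(3L, 2L, 1L))

  # stationary cell
  st <- trajectory("st", 1:5, rep(2, 5), rep(-1, 5), 15)
  expect_true(all(time_averaged_msd(st)$msd_um2 == 0))

  # max_lag_fraction truncates the lag grid
  expect_equal(time_averaged_msd(tr, 1 / 3)$lags_min, 15)

  expect_error(time_averaged_msd(trajectory("x", 1:2, 0:1, 0:1, 15)),
               class = "trackmsd_input_error")
})

test_that("time-averaged MSD equals the double-loop oracle on random tracks", {
  set.seed(5)
  for (rep in 1:30) {
    tr <- random_traj(sample(5:30, 1L), gapped = rep %% 2 == 0)
    frac <- sample(c(0.3, 0.5, 1), 1L)
    cu <- time_averaged_msd(tr, frac)
    or <- msd_oracle(tr, frac)
    expect_equal(cu$lags_min, or$lag)
    expect_equal(cu$msd_um2, or$msd, tolerance = 1e-12)
    expect_equal(cu$n_pairs, or$n)
  }
})

test_that("MSD is rigid-motion invariant and scales quadratically", {
  set.seed(21)
  tr <- random_traj(20L)
  cu0 <- time_averaged_msd(tr)
  th <- 1.2
  x2 <- cos(th) * tr$x_um - sin(th) * tr$y_um + 5
  y2 <- sin(th) * tr$x_um + cos(th) * tr$y_um - 3
  cu1 <- time_averaged_msd(trajectory("r", tr$frames, x2, y2, 15))
  expect_equal(cu1$msd_um2, cu0$msd_um2, tolerance = 1e-9)
  cu2 <- time_averaged_msd(trajectory("s", tr$frames, 3 * tr$x_um,
                                      3 * tr$y_um, 15))
  expect_equal(cu2$msd_um2, 9 * cu0$msd_um2, tolerance = 1e-9)
})

test_that("ensemble MSD averages per-cell curves unweighted", {
  # two identical cells -> ensemble equals single-cell curve
  a <- straight_traj(10, 0.5, id = "a")
  b <- straight_traj(10, 0.5, id = "b")
  ts <- trackset(list(a, b))
  ens <- ensemble_msd(ts)
  expect_equal(ens$msd_um2, time_averaged_msd(a)$msd_um2)
  expect_equal(ens$n_cells, rep(2L, length(ens$lags_min)))

  # unequal spans: long lags carried by the long cell only
  long <- straight_traj(61, 0.5, id = "long")
  short <- straight_traj(31, 0.5, id = "short")
  ens2 <- ensemble_msd(trackset(list(long, short)))
  expect_equal(ens2$n_cells[ens2$lags_min <= 450], rep(2L, 30))
  expect_equal(ens2$n_cells[ens2$lags_min > 450], rep(1L, 30))
  # min_cells_per_lag drops the singleton lags
  ens3 <- ensemble_msd(trackset(list(long, short)), min_cells_per_lag = 2L)
  expect_equal(max(ens3$lags_min), 450)

  # unweighted mean oracle on random cells
  set.seed(31)
  trs <- lapply(1:5, function(i) random_traj(12L, id = paste0("c", i)))
  ens4 <- ensemble_msd(trackset(trs))
  per <- lapply(trs, time_averaged_msd)
  for (li in seq_along(ens4$lags_min)) {
    vals <- unlist(lapply(per, function(cu) {
      cu$msd_um2[cu$lags_min == ens4$lags_min[li]]
    }))
    expect_equal(ens4$msd_um2[li], mean(vals), tolerance = 1e-12)
  }

  expect_error(ensemble_msd(trackset(list())), class = "trackmsd_input_error")
})

test_that("fit_alpha recovers exact power laws and matches the OLS oracle", {
  lags <- seq(15, 300, by = 15)
  # exact power law MSD = 3.7 tau^1.4
  cu <- structure(list(lags_min = lags, msd_um2 = 3.7 * lags^1.4,
                       n_pairs = rep(10L, length(lags)), source = "ensemble"),
                  class = "msd_curve")
  est <- suppressWarnings(fit_alpha(cu))
  expect_equal(est$alpha, 1.4, tolerance = 1e-9)
  expect_lt(est$stderr, 1e-9)
  expect_equal(est$intercept, log(3.7), tolerance = 1e-9)

  # arbitrary (C, a) grid
  for (a in c(0.2, 0.7, 1, 1.8, 2.5)) for (C in c(0.01, 5)) {
    cu$msd_um2 <- C * lags^a
    expect_equal(suppressWarnings(fit_alpha(cu))$alpha, a, tolerance = 1e-9)
  }

  # ballistic closed form through the real pipeline
  est2 <- suppressWarnings(fit_alpha(time_averaged_msd(straight_traj(61, 0.5))))
  expect_equal(est2$alpha, 2, tolerance = 1e-9)

  # noisy curve vs normal-equations oracle
  set.seed(8)
  cu$msd_um2 <- 2 * lags^1.3 * exp(stats::rnorm(length(lags), sd = 0.2))
  est3 <- fit_alpha(cu)
  o <- ols_oracle(log(lags), log(cu$msd_um2))
  expect_equal(est3$alpha, o$slope, tolerance = 1e-9)
  expect_equal(est3$stderr, o$stderr, tolerance = 1e-9)
  tq <- stats::qt(0.975, length(lags) - 2)
  expect_equal(est3$ci_low, o$slope - tq * o$stderr, tolerance = 1e-9)
  expect_equal(est3$ci_high, o$slope + tq * o$stderr, tolerance = 1e-9)
})

test_that("fit_alpha guards its inputs", {
  lags <- c(15, 30, 45, 60)
  cu <- structure(list(lags_min = lags, msd_um2 = c(0, 4, 9, 16),
                       n_pairs = rep(3L, 4), source = "single_cell"),
                  class = "msd_curve")
  expect_warning(fit_alpha(cu), class = "trackmsd_zero_msd_dropped")
  cu$msd_um2 <- c(0, 0, 9, 16)
  expect_error(suppressWarnings(fit_alpha(cu)),
               class = "trackmsd_input_error")
  # lag_range restriction
  cu$msd_um2 <- lags^2
  est <- fit_alpha(cu, lag_range = c(15, 45))
  expect_equal(est$n_lags_used, 3L)
  expect_error(fit_alpha(cu, lag_range = c(40, 60)),
               class = "trackmsd_input_error")
})

test_that("regime classification follows the CI rules", {
  est <- function(a, lo, hi) alpha_estimate(a, lo, hi)
  expect_equal(classify_regime(est(1.0, 0.95, 1.05)), "brownian")
  expect_equal(classify_regime(est(0.6, 0.5, 0.7)), "sub_diffusive")
  expect_equal(classify_regime(est(2.0, 1.98, 2.02)), "ballistic_like")
  expect_equal(classify_regime(est(1.61, 1.59, 1.62)), "super_diffusive")
  expect_equal(classify_regime(est(1.2, 1.18, 1.22)), "super_diffusive")
  # boundaries are inclusive
  expect_equal(classify_regime(est(1.05, 1.0, 1.1)), "brownian")
  expect_equal(classify_regime(est(1.9, 1.5, 2.0)), "ballistic_like")
})

test_that("group decision: control mean vs patient CIs, closed intervals", {
  pats <- list(alpha_estimate(1.20, 1.18, 1.22),
               alpha_estimate(1.26, 1.24, 1.28))
  gd <- compare_groups(c(1.56, 1.61, 1.70), pats)
  expect_equal(gd$control_mean_alpha, mean(c(1.56, 1.61, 1.70)))
  expect_true(all(gd$different))

  gd2 <- compare_groups(c(1.0), list(alpha_estimate(1.0, 0.9, 1.1)))
  expect_false(gd2$different)

  # exact boundary counts as overlap
  gd3 <- compare_groups(c(1.1), list(alpha_estimate(1.0, 0.9, 1.1)))
  expect_false(gd3$different)
  gd4 <- compare_groups(c(1.1 + 1e-9), list(alpha_estimate(1.0, 0.9, 1.1)))
  expect_true(gd4$different)

  expect_error(compare_groups(numeric(), pats),
               class = "trackmsd_input_error")
})

test_that("bootstrap ensemble CI has near-nominal coverage for Brownian motion", {
  # binomial check of the claim "coverage >= 90%": 20 independent 200-cell
  # replicates at fixed seeds; reject only if <= 14 cover (P(X <= 14 |
  # p = 0.9) ~ 1.1%). The regression CI of fit_alpha covers in ~10-20% of
  # such runs (see the methods vignette) and would fail this test.
  cover <- vapply(1:20, function(s) {
    ts <- simulate_tracks(sim_config("brownian", n_cells = 200L,
                                     n_frames = 61L, seed = 300L + s,
                                     diffusion_um2_per_min = 1))
    e <- ensemble_alpha(ts, seed = 400L + s)
    e$ci_low <= 1 && 1 <= e$ci_high
  }, logical(1L))
  expect_gte(sum(cover), 15L)
})

test_that("ensemble_alpha agrees with the regression point estimate", {
  ts <- simulate_tracks(sim_config("brownian", n_cells = 40L, n_frames = 31L,
                                   seed = 12L))
  reg <- fit_alpha(ensemble_msd(ts))
  boot <- ensemble_alpha(ts, n_boot = 99L, seed = 1L)
  expect_equal(boot$alpha, reg$alpha, tolerance = 1e-12)
  expect_gt(boot$ci_high - boot$ci_low, reg$ci_high - reg$ci_low)
  expect_true(boot$ci_low <= boot$alpha && boot$alpha <= boot$ci_high)
})
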