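no_noise <- function(n = 1, seed = 1, ...)
  sim_config(n_tracks = n, seed = seed, localization_sigma = 0, ...)

free <- function(...) regime_params(confinement = c(Inf, Inf, Inf),
                                    drift_amp = 0, sigma_z = 0, ...)

test_that("degenerate limits: stationary and ballistic", {
  still <- simulate_track(free(p_AP = 0, p_PA = 0.5, sigma_arrest = 0),
                          no_noise(seed = 4))
  expect_equal(diff(range(still$points$x)), 0)
  expect_equal(diff(range(still$points$y)), 0)

  run <- simulate_track(free(p_AP = 0.5, p_PA = 0, v_run = 7, sigma_turn = 0),
                        no_noise(seed = 5))
  run2d <- project_2d(track_set(list(run)))$tracks[[1]]
  expect_equal(mean_speed(run2d), 7, tolerance = 1e-9)
  expect_equal(straightness_ratio(run2d), 1, tolerance = 1e-9)
  expect_equal(arrest_coefficient(run2d), 0)
  m <- msd(run2d)
  expect_equal(m$msd, (7 * m$lag)^2, tolerance = 1e-9)
})

test_that("pure-run regime at coarse fine_step measures v_run within 1%", {
  cfg <- sim_config(n_tracks = 50, seed = 8, fine_step = 1, localization_sigma = 0)
  ts <- simulate_cohort(free(p_AP = 0.5, p_PA = 0, v_run = 10, sigma_turn = 0.4), cfg)
  mt <- metrics_table(project_2d(ts))
  expect_equal(mean(mt$mean_speed), 10, tolerance = 0.01)
})

test_that("state occupancy follows the Markov stationary distribution", {
  r <- free(p_AP = 0.05, p_PA = 0.15, v_run = 5)
  cfg <- sim_config(n_tracks = 300, seed = 12)
  ts <- simulate_cohort(r, cfg)
  occ <- attr(ts, "arrested_fraction")
  target <- r$p_PA / (r$p_AP + r$p_PA)
  # cohort mean within 2 s.d. of the stationary arrested fraction
  expect_lt(abs(mean(occ) - target), 2 * sd(occ) / sqrt(length(occ)) + 0.01)
})

test_that("localization noise inflates arrested-cohort speed as predicted", {
  sig <- 0.3
  r <- regime_params(p_AP = 0, p_PA = 0.5, sigma_arrest = 0, sigma_z = 0,
                     drift_amp = 0)
  cfg <- sim_config(n_tracks = 500, seed = 14, localization_sigma = sig)
  mt <- metrics_table(project_2d(simulate_cohort(r, cfg)))
  # steps are |N2(0, 2 sig^2 I)|: Rayleigh with mean sig*sqrt(pi)/dt
  expect_equal(mean(mt$mean_speed), sig * sqrt(pi), tolerance = 0.1)
})

test_that("confinement keeps every position inside the box", {
  r <- regime_params(p_AP = 0.5, p_PA = 0.02, v_run = 15, drift_amp = 0,
                     confinement = c(20, 10, 10))
  cfg <- sim_config(n_tracks = 50, seed = 15, localization_sigma = 0)
  ts <- simulate_cohort(r, cfg)
  for (tr in ts$tracks) {
    expect_true(all(abs(tr$points$x) <= 20 + 1e-9))
    expect_true(all(abs(tr$points$y) <= 10 + 1e-9))
    expect_true(all(abs(tr$points$z) <= 10 + 1e-9))
  }
})

test_that("MSD shape separates confined and ballistic regimes", {
  cfg <- sim_config(n_tracks = 500, seed = 16, localization_sigma = 0)
  arrest <- simulate_cohort(regime_params(p_AP = 0, p_PA = 0.5,
                                          sigma_arrest = 1, drift_amp = 0,
                                          confinement = c(3, 3, 25)), cfg)
  m_arr <- cohort_msd(project_2d(arrest), 0.5, 10)
  ratio_arr <- m_arr$msd[m_arr$lag == 10] / m_arr$msd[m_arr$lag == 2]
  expect_lt(ratio_arr, 3)

  ball <- simulate_cohort(free(p_AP = 0.5, p_PA = 0, v_run = 5, sigma_turn = 0),
                          cfg)
  m_b <- cohort_msd(project_2d(ball), 0.5, 10)
  ratio_b <- m_b$msd[m_b$lag == 10] / m_b$msd[m_b$lag == 2]
  expect_equal(ratio_b, 25, tolerance = 1e-6)
})

test_that("cohort simulation is deterministic and labelled", {
  a <- simulate_cohort("wt_villus_steady", fast_cfg(n = 5, seed = 99))
  b <- simulate_cohort("wt_villus_steady", fast_cfg(n = 5, seed = 99))
  expect_identical(a$tracks, b$tracks)
  expect_equal(a$condition, "wt_villus_steady")
  expect_equal(n_tracks(simulate_cohort("wt_villus_steady", fast_cfg(n = 0))), 0L)
  expect_error(simulate_cohort("no_such_regime", fast_cfg(5)),
               class = "villustrack_error_unknown_regime")
})

test_that("time course with identical regimes matches a plain cohort", {
  cfg <- fast_cfg(n = 500, seed = 23)
  tc <- simulate_timecourse("t_reconstituted", "t_reconstituted", 15, cfg)
  plain <- simulate_cohort("t_reconstituted", fast_cfg(n = 500, seed = 24))
  sp_tc <- unlist(lapply(project_2d(tc)$tracks,
                         function(tr) instantaneous_speeds(tr)$speed))
  sp_pl <- unlist(lapply(project_2d(plain)$tracks,
                         function(tr) instantaneous_speeds(tr)$speed))
  ks <- suppressWarnings(ks.test(sp_tc, sp_pl))
  expect_gt(ks$p.value, 0.01)

  # switch at t = 0 equals the pure post regime statistically
  tc0 <- simulate_timecourse("rag2_steady", "ccl25_blockade_post", 0,
                             fast_cfg(n = 300, seed = 25))
  post <- simulate_cohort("ccl25_blockade_post", fast_cfg(n = 300, seed = 26))
  m_tc <- summarize_metrics(metrics_table(project_2d(tc0)))
  m_po <- summarize_metrics(metrics_table(project_2d(post)))
  expect_lt(abs(m_tc$mean_speed - m_po$mean_speed),
            4 * sqrt(m_tc$mean_speed_sem^2 + m_po$mean_speed_sem^2))

  expect_error(simulate_timecourse("rag2_steady", "ccl25_blockade_post", 99,
                                   fast_cfg(5)),
               class = "villustrack_error_bad_switch_time")
})

test_that("invalid regime parameters are rejected", {
  expect_error(regime_params(p_AP = 1.5), class = "villustrack_error_bad_regime")
  expect_error(regime_params(v_run = -1), class = "villustrack_error_bad_regime")
  expect_error(sim_config(fine_step = 0.3), class = "villustrack_error_bad_sim_config")
  expect_error(sim_config(duration = 5), class = "villustrack_error_bad_sim_config")
})

test_that("calibration selects the ballistic corner for ballistic targets", {
  grid <- expand.grid(p_AP = c(0.02, 0.5), p_PA = c(0, 0.3),
                      v_run = 8, sigma_arrest = 0.05, sigma_turn = c(0, 1))
  win <- calibrate_regime(
    c(mean_speed = 8, arrest_coefficient = 1e-6, straightness = 1),
    grid, cfg = sim_config(n_tracks = 60, seed = 30, localization_sigma = 0),
    base = regime_params(drift_amp = 0, sigma_z = 0,
                         confinement = c(Inf, Inf, Inf)),
    max_rel_err = 1e6)
  expect_equal(win$p_PA, 0)
  expect_equal(win$sigma_turn, 0)

  # deterministic: the same seed reproduces the same winner and statistics
  win2 <- calibrate_regime(
    c(mean_speed = 8, arrest_coefficient = 1e-6, straightness = 1),
    grid, cfg = sim_config(n_tracks = 60, seed = 30, localization_sigma = 0),
    base = regime_params(drift_amp = 0, sigma_z = 0,
                         confinement = c(Inf, Inf, Inf)),
    max_rel_err = 1e6)
  expect_identical(attr(win, "grid_results"), attr(win2, "grid_results"))

  expect_error(
    calibrate_regime(c(mean_speed = 1000, arrest_coefficient = 50,
                       straightness = 0.5),
                     grid[1:2, ],
                     cfg = sim_config(n_tracks = 40, seed = 31)),
    class = "villustrack_error_calibration_failure")
})
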