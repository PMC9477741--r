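test_that("instantaneous speeds match hand-computed step geometry", {
  tr <- track("a", data.frame(t = 0:2, x = c(0, 1, 2), y = 0))
  expect_equal(instantaneous_speeds(tr)$speed, c(1, 1))
  expect_equal(instantaneous_speeds(tr)$t_mid, c(0.5, 1.5))

  expect_equal(instantaneous_speeds(stationary_track())$speed, rep(0, 4))

  tri <- track("b", data.frame(t = 0:1, x = c(0, 3), y = c(0, 4)))
  expect_equal(instantaneous_speeds(tri)$speed, 5)

  expect_error(instantaneous_speeds(track("x", data.frame(t = 0, x = 0, y = 0))),
               class = "villustrack_error_too_short")
})

test_that("arrest coefficient counts strict sub-threshold steps as percent", {
  # 10-step track: 7 slow steps at 1 um/min, 3 fast at 6 um/min
  steps <- c(rep(1, 7), rep(6, 3))
  tr <- track("m", data.frame(t = 0:10, x = cumsum(c(0, steps)), y = 0))
  expect_equal(arrest_coefficient(tr), 70)

  expect_equal(arrest_coefficient(stationary_track()), 100)
  fast <- straight_track(6, v = 6)
  expect_equal(arrest_coefficient(fast), 0)

  # strict inequality: steps exactly at the threshold count as motile
  at_thr <- straight_track(6, v = 3)
  expect_equal(arrest_coefficient(at_thr, threshold = 3), 0)

  # antitone in the threshold
  spd <- with_seed(2, rw_track(30, sigma = 2))
  expect_gte(arrest_coefficient(spd, 5), arrest_coefficient(spd, 2))
})

test_that("straightness ratio is displacement over path length in [0, 1]", {
  expect_equal(straightness_ratio(straight_track(10)), 1)

  loop <- track("loop", data.frame(t = 0:4, x = c(0, 1, 1, 0, 0),
                                   y = c(0, 0, 1, 1, 0)))
  expect_equal(straightness_ratio(loop), 0)

  ell <- track("L", data.frame(t = 0:2, x = c(0, 1, 1), y = c(0, 0, 1)))
  expect_equal(straightness_ratio(ell), sqrt(2) / 2)

  # zero path length is undefined, not 0 or 1
  expect_true(is.na(straightness_ratio(stationary_track())))

  with_seed(3, for (i in 1:20) {
    s <- straightness_ratio(rw_track(15, sigma = 1))
    expect_gte(s, 0); expect_lte(s, 1)
  })
})

test_that("mean speed averages instantaneous speeds", {
  expect_equal(mean_speed(straight_track(5, v = 2)), 2)
  expect_equal(mean_speed(stationary_track()), 0)
  steps <- c(1, 1, 6, 6)
  tr <- track("m", data.frame(t = 0:4, x = cumsum(c(0, steps)), y = 0))
  expect_equal(mean_speed(tr), 3.5)
})

test_that("overlapping-interval MSD equals the brute-force oracle exactly", {
  # irregular 5-point toy track
  toy <- track("toy", data.frame(t = 0:4, x = c(0, 1, 3, 2, 5),
                                 y = c(0, 2, 1, 4, 4)))
  got_toy <- msd(toy, 1)
  exp_toy <- brute_force_msd(toy, 1)
  expect_identical(got_toy$lag, exp_toy$lag)
  expect_identical(got_toy$msd, exp_toy$msd)
  expect_identical(got_toy$n_intervals, exp_toy$n_intervals)

  with_seed(9, for (i in 1:25) {
    n <- sample(5:50, 1)
    tr <- rw_track(n, sigma = runif(1, 0.1, 5))
    got <- msd(tr)
    exp <- brute_force_msd(tr)
    expect_identical(got$msd, exp$msd)
    expect_identical(got$n_intervals, exp$n_intervals)
  })
})

test_that("MSD closed forms: stationary and ballistic limits", {
  m0 <- msd(stationary_track(11))
  expect_equal(m0$msd, rep(0, nrow(m0)))

  v <- 2.5; dt <- 1
  mb <- msd(straight_track(21, v = v, dt = dt))
  expect_equal(mb$msd, (v * mb$lag)^2, tolerance = 1e-12)
})

test_that("MSD skips gap-crossing intervals", {
  # hole between t=5 and t=8; lag-1 pairs must not bridge it
  pts <- data.frame(t = c(0:5, 8:13), x = c(0:5, 100 + 0:5), y = 0)
  tr <- track("g", pts)
  m <- msd(tr, 0.5)
  expect_equal(m$msd[1], 1)        # all within-segment lag-1 steps are 1 um
  expect_equal(m$n_intervals[1], 10)
})

test_that("cohort MSD averages tracks and truncates low support", {
  a <- straight_track(11, v = 1, id = "a")
  b <- straight_track(11, v = 3, id = "b")
  ts <- track_set(list(a, b))
  cm <- cohort_msd(ts, 0.5, min_tracks = 2)
  ma <- msd(a); mb <- msd(b)
  expect_equal(cm$msd, (ma$msd + mb$msd) / 2)

  # identical tracks reduce to the single-track curve
  ts1 <- track_set(list(a, track("a2", a$points)))
  expect_equal(cohort_msd(ts1, 0.5, min_tracks = 2)$msd, ma$msd)

  # lag support below min_tracks is truncated
  short <- straight_track(6, id = "s")
  mixed <- track_set(list(a, short))
  cmx <- cohort_msd(mixed, 0.5, min_tracks = 2)
  expect_lte(max(cmx$lag), 2)  # short track only supports lags 1..2
})

test_that("diffusive cohort MSD slope recovers 4D", {
  sigma <- 0.8  # per-axis step s.d. sqrt(2)*sigma => slope 4D, D = sigma^2/dt
  ts <- with_seed(21, track_set(lapply(1:500, function(i)
    rw_track(31, sigma = sqrt(2) * sigma, id = paste0("rw", i)))))
  cm <- cohort_msd(ts, 0.3, min_tracks = 100)
  fit <- lm(msd ~ 0 + lag, data = cm)
  expect_equal(unname(coef(fit)[1]), 4 * sigma^2, tolerance = 0.1)
})

test_that("speed over time pools by bin and omits empty bins", {
  tr <- straight_track(31, v = 2)
  ts <- track_set(list(tr))
  sot <- speed_over_time(ts, event_time = 0, bin = 5)
  expect_true(all(abs(sot$mean_speed - 2) < 1e-12))

  # event time shifts the bin origin; bins before the start are absent
  sot2 <- speed_over_time(ts, event_time = 10, bin = 5)
  expect_equal(min(sot2$t_start), -10)
  expect_false(any(sot2$n == 0))

  # regime switch shows as a speed drop after the event
  tc <- simulate_timecourse("rag2_steady", "ccl25_blockade_post", 15,
                            fast_cfg(n = 120, seed = 31))
  res <- speed_over_time(project_2d(tc), event_time = 15, bin = 5)
  pre <- res$mean_speed[res$t_start < 0]
  post <- res$mean_speed[res$t_start >= 5]  # leave the switch bin out
  expect_gt(min(pre), max(post))
})

test_that("metrics are invariant under rigid motions and time shifts", {
  ts <- with_seed(13, simulate_cohort("t_reconstituted", fast_cfg(n = 20, seed = 13)))
  ts <- project_2d(ts)
  mt <- metrics_table(ts)
  moved <- rigid_transform(ts, angle = 1.1, shift = c(42, -17))
  mt2 <- metrics_table(moved)
  expect_equal(mt2$mean_speed, mt$mean_speed, tolerance = 1e-9)
  expect_equal(mt2$arrest_coefficient, mt$arrest_coefficient, tolerance = 1e-9)
  expect_equal(mt2$straightness, mt$straightness, tolerance = 1e-9)

  shifted <- ts
  shifted$tracks <- lapply(ts$tracks, function(tr) {
    tr$points$t <- tr$points$t + 7
    tr
  })
  mt3 <- metrics_table(shifted)
  expect_equal(mt3$mean_speed, mt$mean_speed, tolerance = 1e-12)

  m1 <- cohort_msd(ts, 0.5, 5)
  m2 <- cohort_msd(moved, 0.5, 5)
  expect_equal(m2$msd, m1$msd, tolerance = 1e-9)
})

test_that("metrics table flags short tracks instead of dropping them", {
  good <- straight_track(15, id = "good")
  bad <- track("tiny", data.frame(t = 0, x = 0, y = 0))
  mt <- metrics_table(track_set(list(good, bad)))
  expect_equal(nrow(mt), 2L)
  expect_true(is.na(mt$mean_speed[mt$track_id == "tiny"]))
  expect_equal(mt$reason[mt$track_id == "tiny"], "too_short")
  expect_true(is.na(mt$reason[mt$track_id == "good"]))
  # straightness consistency on the complete record
  ok <- mt[mt$track_id == "good", ]
  expect_equal(ok$straightness, ok$net_displacement / ok$path_length)
  expect_gte(ok$path_length, ok$net_displacement)
})

test_that("gap-split segments pool into one per-cell record", {
  pts <- data.frame(t = c(0:12, 18:30), x = c(0:12, 18:30), y = 0)
  holed <- track("cell7", pts)
  split <- split_and_filter(track_set(list(holed)), 10, 1)
  expect_equal(n_tracks(split), 2L)
  mt <- metrics_table(split)
  expect_equal(nrow(mt), 1L)            # one record for the original cell
  expect_equal(mt$track_id, "cell7")
  expect_equal(mt$n_segments, 2L)
  expect_equal(mt$n_steps, 24L)         # 12 uniform steps per segment
  expect_equal(mt$net_displacement, 30)
  expect_equal(mt$straightness, 1)      # straight line, hop included in path
})
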