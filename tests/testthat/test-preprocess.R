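make_set <- function(tracks) track_set(tracks, condition = "test")

test_that("2D projection drops z and shrinks (or preserves) speeds", {
  flat <- track("flat", data.frame(t = 0:4, x = 0:4, y = 0, z = 0))
  ts <- project_2d(make_set(list(flat)))
  expect_false("z" %in% names(ts$tracks[[1]]$points))
  expect_equal(mean_speed(ts$tracks[[1]]), 1)

  # helix: constant xy speed 1, rising z -> projected speed below 3D speed
  helix <- track("h", data.frame(t = 0:9, x = cos(0:9), y = sin(0:9), z = 2 * (0:9)))
  v3d <- mean_speed(helix)
  v2d <- mean_speed(project_2d(make_set(list(helix)))$tracks[[1]])
  expect_lt(v2d, v3d)

  # purely axial mover projects to a stationary cell
  axial <- track("ax", data.frame(t = 0:5, x = 1, y = 2, z = 0:5))
  expect_equal(mean_speed(project_2d(make_set(list(axial)))$tracks[[1]]), 0)
})

test_that("rigid translation drift is estimated exactly and removed", {
  # 5 static cells translated by (1, -0.5) um per frame
  base <- lapply(1:5, function(i)
    track(paste0("c", i), data.frame(t = 0:9, x = i + (0:9) * 1, y = i - (0:9) * 0.5)))
  ts <- make_set(base)
  d <- estimate_drift(ts)
  expect_equal(d$cum_dx[1], 0)
  expect_equal(d$cum_dy[1], 0)
  expect_equal(d$step_dx[-1], rep(1, 9))
  expect_equal(d$step_dy[-1], rep(-0.5, 9))

  corrected <- correct_drift(ts, d)
  for (tr in corrected$tracks) {
    expect_lt(diff(range(tr$points$x)), 1e-12)
    expect_lt(diff(range(tr$points$y)), 1e-12)
  }
  # idempotence: re-estimated drift on corrected data is numerically zero
  d2 <- estimate_drift(corrected)
  expect_lt(max(abs(c(d2$step_dx, d2$step_dy))), 1e-9)

  # static cells give zero drift
  still <- make_set(lapply(1:3, function(i) stationary_track(10, paste0("s", i))))
  d0 <- estimate_drift(still)
  expect_equal(max(abs(c(d0$step_dx, d0$step_dy))), 0)

  expect_error(estimate_drift(make_set(list())),
               class = "villustrack_error_empty_cohort")
})

test_that("drift recovery under per-cell noise is accurate to < 0.05 um/step", {
  with_seed(11, {
    n <- 50; nf <- 30
    drift_x <- cumsum(c(0, runif(nf, -1, 1)))
    drift_y <- cumsum(c(0, runif(nf, -1, 1)))
    cells <- lapply(seq_len(n), function(i)
      track(paste0("c", i),
            data.frame(t = 0:nf,
                       x = drift_x + rnorm(nf + 1, 0, 0.1),
                       y = drift_y + rnorm(nf + 1, 0, 0.1))))
    d <- estimate_drift(make_set(cells))
    err_x <- d$step_dx[-1] - diff(drift_x)
    err_y <- d$step_dy[-1] - diff(drift_y)
    expect_lt(mean(abs(c(err_x, err_y))), 0.05)
  })
})

test_that("frame-grid mismatch between drift and tracks is an error", {
  ts <- make_set(list(straight_track(5)))
  d <- estimate_drift(ts)
  short <- d[1:3, ]
  class(short) <- class(d)
  expect_error(correct_drift(ts, short),
               class = "villustrack_error_frame_grid_mismatch")
})

test_that("gap splitting and duration filtering behave as specified", {
  # contiguous track longer than min_duration is untouched
  long <- straight_track(16)  # 15 min span
  res <- split_and_filter(make_set(list(long)), min_duration = 10, max_gap = 1)
  expect_equal(n_tracks(res), 1L)
  expect_equal(attr(res, "report")[["kept"]], 1L)

  # a 3-frame hole with max_gap = 1 splits the track in two segments
  pts <- data.frame(t = c(0:12, 16:28), x = 0, y = 0)
  holed <- track("h", pts)
  res2 <- split_and_filter(make_set(list(holed)), min_duration = 10, max_gap = 1)
  expect_equal(n_tracks(res2), 2L)
  expect_equal(attr(res2, "report")[["split"]], 1L)
  expect_setequal(vapply(res2$tracks, function(tr) tr$parent_track, character(1)),
                  "h")

  # the same hole with max_gap = 3 is tolerated: one track, gap step excluded
  res3 <- split_and_filter(make_set(list(holed)), min_duration = 10, max_gap = 3)
  expect_equal(n_tracks(res3), 1L)
  expect_equal(nrow(instantaneous_speeds(res3$tracks[[1]])), 24L)  # 25 steps - 1 gap

  # short segments are discarded and counted
  shorty <- straight_track(5)  # 4 min
  res4 <- split_and_filter(make_set(list(shorty)), min_duration = 10, max_gap = 1)
  expect_equal(n_tracks(res4), 0L)
  expect_equal(attr(res4, "report")[["discarded"]], 1L)
})

test_that("frame dropout changes cohort metrics by < 5% relative", {
  ts <- with_seed(5, simulate_cohort("rag2_steady", fast_cfg(n = 100, seed = 5)))
  ts <- project_2d(ts)
  full <- summarize_metrics(metrics_table(split_and_filter(ts, 10, 1)))
  dropped <- with_seed(6, {
    ts2 <- ts
    ts2$tracks <- lapply(ts$tracks, function(tr) {
      keep <- runif(nrow(tr$points)) > 0.05
      keep[c(1, nrow(tr$points))] <- TRUE
      tr$points <- tr$points[keep, , drop = FALSE]
      tr
    })
    ts2
  })
  part <- summarize_metrics(metrics_table(split_and_filter(dropped, 10, 1)))
  expect_lt(abs(part$mean_speed - full$mean_speed) / full$mean_speed, 0.05)
  expect_lt(abs(part$arrest_coefficient - full$arrest_coefficient) /
              full$arrest_coefficient, 0.05)
})
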