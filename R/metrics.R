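#' Per-track motility metrics
#'
#' The motility statistics used to characterize lymphocyte behavior in
#' intravital movies: instantaneous speed, mean speed, arrest coefficient
#' (fraction of time below 3 um/min), straightness ratio
#' (net displacement / path length) and mean squared displacement computed
#' over all overlapping intervals of each lag.
#'
#' @name motility_metrics
NULL

# Per-step geometry of a track. Steps whose time difference exceeds the
# nominal frame interval (a tolerated gap) are marked non-uniform and are
# excluded from speed-based statistics, but still contribute to path length.
.track_steps <- function(tr) {
  p <- tr$points
  n <- nrow(p)
  if (n < 2L) vt_stop("too_short", "track '%s' has fewer than 2 points", tr$track_id)
  dt <- diff(p$t)
  d2 <- diff(p$x)^2 + diff(p$y)^2
  if ("z" %in% names(p)) d2 <- d2 + diff(p$z)^2
  dist <- sqrt(d2)
  list(dt = dt, dist = dist,
       t_mid = (p$t[-1] + p$t[-n]) / 2,
       uniform = abs(dt - tr$frame_interval) <= 1e-6)
}

#' Instantaneous speeds of a track
#'
#' Speed of each step between consecutive observed positions, in um/min,
#' with the mid-interval timestamp. Steps spanning tolerated gaps (actual
#' time difference larger than the frame interval) are excluded.
#'
#' @param tr a `track` with at least 2 points.
#' @return data.frame of class `speed_series` with columns `t_mid`, `speed`.
#' @examples
#' tr <- track("a", data.frame(t = 0:2, x = c(0, 1, 2), y = 0))
#' instantaneous_speeds(tr)$speed  # 1, 1
#' @export
instantaneous_speeds <- function(tr) {
  s <- .track_steps(tr)
  structure(data.frame(t_mid = s$t_mid[s$uniform],
                       speed = (s$dist / s$dt)[s$uniform]),
            class = c("speed_series", "data.frame"))
}

#' Arrest coefficient
#'
#' Percentage of steps whose instantaneous speed is strictly below
#' `threshold` (default 3 um/min); a step at exactly the threshold counts as
#' motile. With uniform frame intervals the step count is an exact
#' "percentage of time".
#'
#' @param tr a `track`.
#' @param threshold speed threshold in um/min.
#' @return percentage in \[0, 100\].
#' @export
arrest_coefficient <- function(tr, threshold = 3.0) {
  v <- instantaneous_speeds(tr)$speed
  if (!length(v)) vt_stop("too_short", "track '%s' has no uniform steps", tr$track_id)
  100 * mean(v < threshold)
}

#' Straightness ratio
#'
#' Net displacement (last minus first position) divided by path length (sum
#' of consecutive step lengths), a directionality index in \[0, 1\]: 1 for a
#' perfectly straight run, near 0 for confined wandering. Undefined (NA) for
#' a zero-length path.
#'
#' @param tr a `track`.
#' @return unitless ratio, or `NA` if the path length is zero.
#' @export
straightness_ratio <- function(tr) {
  s <- .track_steps(tr)
  p <- tr$points
  n <- nrow(p)
  net2 <- (p$x[n] - p$x[1])^2 + (p$y[n] - p$y[1])^2
  if ("z" %in% names(p)) net2 <- net2 + (p$z[n] - p$z[1])^2
  path <- sum(s$dist)
  if (path == 0) return(NA_real_)
  sqrt(net2) / path
}

#' Mean speed of a track
#'
#' Arithmetic mean of the instantaneous speeds (equal to path length over
#' duration for gap-free uniform sampling), in um/min.
#'
#' @param tr a `track`.
#' @return mean speed in um/min.
#' @export
mean_speed <- function(tr) {
  mean(instantaneous_speeds(tr)$speed)
}

# pooled step displacements (squared) at integer lag n within uniformly
# sampled runs of consecutive points; returned in (segment, start-index) order
.msd_sq_disp <- function(p, uniform, n) {
  # uniform runs: maximal stretches of consecutive uniform steps
  out <- numeric(0)
  r <- rle(c(uniform, FALSE))
  start <- 1L
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]
    if (r$values[k] && len >= n) {
      i <- start:(start + len - n)      # point indices of interval starts
      dx <- p$x[i + n] - p$x[i]
      dy <- p$y[i + n] - p$y[i]
      d2 <- dx * dx + dy * dy
      if ("z" %in% names(p)) {
        dz <- p$z[i + n] - p$z[i]
        d2 <- d2 + dz * dz
      }
      out <- c(out, d2)
    }
    start <- start + len
  }
  out
}

#' Mean squared displacement of a track (overlapping intervals)
#'
#' MSD(n dt) is the mean of the squared displacement over *all* overlapping
#' index pairs (i, i+n) within uniformly sampled stretches of the track, for
#' n = 1 ... floor(`max_lag_fraction` * (N-1)). Long lags are supported by few
#' intervals, so the number of intervals per lag is reported and the default
#' maximum lag is half the track length.
#'
#' @param tr a `track` with at least 3 points.
#' @param max_lag_fraction largest lag as a fraction of the track length.
#' @return data.frame of class `msd_curve` with columns `lag` (minutes),
#'   `msd` (um^2) and `n_intervals`.
#' @export
msd <- function(tr, max_lag_fraction = 0.5) {
  p <- tr$points
  if (nrow(p) < 3L) vt_stop("too_short", "track '%s' has fewer than 3 points", tr$track_id)
  s <- .track_steps(tr)
  nmax <- floor(max_lag_fraction * (nrow(p) - 1L))
  if (nmax < 1L) vt_stop("too_short", "track '%s' too short for any MSD lag", tr$track_id)
  lags <- msds <- numeric(nmax)
  counts <- integer(nmax)
  for (n in seq_len(nmax)) {
    d2 <- .msd_sq_disp(p, s$uniform, n)
    lags[n] <- n * tr$frame_interval
    counts[n] <- length(d2)
    msds[n] <- if (length(d2)) mean(d2) else NA_real_
  }
  keep <- counts > 0
  structure(data.frame(lag = lags[keep], msd = msds[keep],
                       n_intervals = counts[keep]),
            class = c("msd_curve", "data.frame"))
}

#' Cohort-averaged MSD
#'
#' Unweighted mean across tracks of the per-track MSD at each lag, matching
#' per-cell averaging (every cell counts once, regardless of track length).
#' Lags supported by fewer than `min_tracks` tracks (capped at the cohort
#' size) are truncated.
#'
#' @param ts a [track_set()].
#' @param max_lag_fraction passed to [msd()].
#' @param min_tracks minimum number of contributing tracks per retained lag.
#' @return data.frame of class `msd_curve` with columns `lag`, `msd`,
#'   `n_tracks`.
#' @export
cohort_msd <- function(ts, max_lag_fraction = 0.5, min_tracks = 10) {
  stopifnot(is_track_set(ts))
  if (n_tracks(ts) == 0L) vt_stop("empty_cohort", "empty track set")
  curves <- list()
  for (tr in ts$tracks) {
    c0 <- tryCatch(msd(tr, max_lag_fraction), villustrack_error_too_short = function(e) NULL)
    if (!is.null(c0)) curves[[length(curves) + 1L]] <- c0
  }
  if (!length(curves)) vt_stop("empty_cohort", "no track long enough for MSD")
  all_lags <- sort(unique(unlist(lapply(curves, `[[`, "lag"))))
  vals <- counts <- numeric(length(all_lags))
  for (k in seq_along(all_lags)) {
    per <- unlist(lapply(curves, function(cv) cv$msd[match(all_lags[k], cv$lag)]))
    per <- per[!is.na(per)]
    counts[k] <- length(per)
    vals[k] <- mean(per)
  }
  keep <- counts >= min(min_tracks, length(curves))
  structure(data.frame(lag = all_lags[keep], msd = vals[keep],
                       n_tracks = counts[keep]),
            class = c("msd_curve", "data.frame"))
}

#' Cohort speed over time
#'
#' Pools all instantaneous speeds of a cohort into wall-clock time bins
#' relative to a treatment event (e.g. an antibody injection at `event_time`)
#' and reports mean, s.e.m. and the number of pooled steps per bin. Empty
#' bins are omitted, not zero-filled.
#'
#' @param ts a [track_set()] on a common clock.
#' @param event_time event origin in minutes; bin times are relative to it.
#' @param bin bin width in minutes.
#' @return data.frame of class `speed_over_time` with columns `t_start`,
#'   `t_mid`, `mean_speed`, `sem`, `n`.
#' @export
speed_over_time <- function(ts, event_time = 0, bin = 5) {
  stopifnot(is_track_set(ts), bin > 0)
  t_rel <- speeds <- numeric(0)
  for (tr in ts$tracks) {
    ss <- tryCatch(instantaneous_speeds(tr),
                   villustrack_error_too_short = function(e) NULL)
    if (is.null(ss) || !nrow(ss)) next
    t_rel <- c(t_rel, ss$t_mid - event_time)
    speeds <- c(speeds, ss$speed)
  }
  if (!length(speeds)) vt_stop("empty_cohort", "no speed data in the cohort")
  b <- floor(t_rel / bin)
  agg <- lapply(split(speeds, b), function(v)
    c(mean = mean(v), sem = sem(v), n = length(v)))
  bl <- as.numeric(names(agg))
  ord <- order(bl)
  structure(data.frame(t_start = bl[ord] * bin,
                       t_mid = (bl[ord] + 0.5) * bin,
                       mean_speed = vapply(agg, `[[`, numeric(1), "mean")[ord],
                       sem = vapply(agg, `[[`, numeric(1), "sem")[ord],
                       n = vapply(agg, `[[`, numeric(1), "n")[ord],
                       row.names = NULL),
            class = c("speed_over_time", "data.frame"))
}

#' Per-track metrics table for a cohort
#'
#' One record per cell: segments produced by [split_and_filter()] from the
#' same original track are pooled (their id is the `parent_track`), with
#' speed-based metrics computed on the pooled steps and displacement metrics
#' on the full time-ordered sequence of retained positions. Tracks that are
#' too short for a metric are flagged with a reason instead of being silently
#' dropped.
#'
#' @param ts a preprocessed [track_set()].
#' @param config a [default_config()]-style configuration.
#' @return data.frame with one row per cell: identity and labels, `n_points`,
#'   `n_steps`, `duration`, `mean_speed`, `arrest_coefficient`,
#'   `straightness`, `net_displacement`, `path_length`, `reason` (NA when the
#'   record is complete).
#' @export
metrics_table <- function(ts, config = default_config()) {
  stopifnot(is_track_set(ts))
  thr <- config$metrics$arrest_threshold
  parents <- vapply(ts$tracks, function(tr) tr$parent_track, character(1))
  groups <- split(seq_along(ts$tracks), parents)
  rows <- lapply(names(groups), function(pid) {
    trs <- ts$tracks[groups[[pid]]]
    # merge retained points of all segments, time-ordered
    pts <- do.call(rbind, lapply(trs, function(tr) tr$points))
    pts <- pts[order(pts$t), , drop = FALSE]
    merged <- trs[[1]]
    merged$track_id <- pid
    merged$points <- pts
    base <- data.frame(track_id = pid, cell_class = trs[[1]]$cell_class,
                       condition = trs[[1]]$condition,
                       n_points = nrow(pts), n_segments = length(trs),
                       duration = diff(range(pts$t)),
                       stringsAsFactors = FALSE)
    res <- tryCatch({
      sp <- instantaneous_speeds(merged)$speed
      if (!length(sp)) vt_stop("too_short", "no uniform steps")
      st <- .track_steps(merged)
      n <- nrow(pts)
      net2 <- (pts$x[n] - pts$x[1])^2 + (pts$y[n] - pts$y[1])^2
      if ("z" %in% names(pts)) net2 <- net2 + (pts$z[n] - pts$z[1])^2
      path <- sum(st$dist)
      cbind(base, data.frame(
        n_steps = length(sp),
        mean_speed = mean(sp),
        arrest_coefficient = 100 * mean(sp < thr),
        net_displacement = sqrt(net2),
        path_length = path,
        straightness = if (path > 0) sqrt(net2) / path else NA_real_,
        reason = NA_character_, stringsAsFactors = FALSE))
    }, villustrack_error = function(e) {
      cbind(base, data.frame(
        n_steps = 0L, mean_speed = NA_real_, arrest_coefficient = NA_real_,
        net_displacement = NA_real_, path_length = NA_real_,
        straightness = NA_real_,
        reason = sub("^villustrack_error_", "", class(e)[1]),
        stringsAsFactors = FALSE))
    })
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$track_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohort summary of a metrics table
#'
#' Mean and s.e.m. per condition for the headline metrics, on complete
#' records only; incomplete records are counted, not dropped silently.
#'
#' @param mt output of [metrics_table()].
#' @return data.frame with one row per condition.
#' @export
summarize_metrics <- function(mt) {
  do.call(rbind, lapply(split(mt, mt$condition), function(d) {
    ok <- d[is.na(d$reason), , drop = FALSE]
    data.frame(
      condition = d$condition[1],
      n_tracks = nrow(d), n_complete = nrow(ok),
      mean_speed = mean(ok$mean_speed), mean_speed_sem = sem(ok$mean_speed),
      arrest_coefficient = mean(ok$arrest_coefficient),
      arrest_coefficient_sem = sem(ok$arrest_coefficient),
      straightness = mean(ok$straightness, na.rm = TRUE),
      straightness_sem = sem(ok$straightness),
      net_displacement = mean(ok$net_displacement),
      path_length = mean(ok$path_length),
      row.names = NULL, stringsAsFactors = FALSE)
  }))
}
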