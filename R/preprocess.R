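#' Preprocessing of intravital track cohorts
#'
#' Intravital movies of the gut are analyzed as 2D projections of the 3D
#' volume (axial motion of the villus makes z unreliable), after removal of
#' bulk XY tissue drift (peristalsis, breathing) and splitting/filtering of
#' fragmented tracks. These stages reproduce that pipeline on coordinates.
#'
#' @name preprocess
NULL

.frame_index <- function(tr) as.integer(round(tr$points$t / tr$frame_interval))

#' Project a cohort to 2D
#'
#' Drops the z coordinate of every track and flags the set as projected.
#' x and y are untouched, so in-plane displacements are preserved while any
#' axial motion no longer contributes to speeds (projected speeds are
#' therefore a slight underestimate for cells moving in z).
#'
#' @param ts a [track_set()].
#' @return the projected `track_set`.
#' @export
project_2d <- function(ts) {
  stopifnot(is_track_set(ts))
  ts$tracks <- lapply(ts$tracks, function(tr) {
    tr$points$z <- NULL
    tr
  })
  ts$projected <- TRUE
  ts
}

#' Estimate per-frame XY tissue drift
#'
#' The drift at each frame transition is the componentwise median, over all
#' cells present at both frames, of their frame-to-frame displacement. The
#' median makes the estimate robust to a minority of genuinely motile cells,
#' mimicking reference-frame stabilization without image registration.
#' Transitions with no spanning cell get zero drift.
#'
#' @param ts a 2D-projected [track_set()].
#' @return a `drift_series` data.frame with one row per frame: `frame`,
#'   per-step displacement `step_dx`, `step_dy` (zero at the first frame) and
#'   cumulative `cum_dx`, `cum_dy` (zero at the first frame).
#' @export
estimate_drift <- function(ts) {
  stopifnot(is_track_set(ts))
  if (n_tracks(ts) == 0L) vt_stop("empty_cohort", "cannot estimate drift from an empty track set")
  frames <- lapply(ts$tracks, .frame_index)
  fmax <- max(unlist(frames))
  fmin <- min(unlist(frames))
  grid <- fmin:fmax
  # position-per-frame matrices (tracks x frames), NA where a cell is absent
  X <- Y <- matrix(NA_real_, nrow = n_tracks(ts), ncol = length(grid))
  for (i in seq_along(ts$tracks)) {
    col <- frames[[i]] - fmin + 1L
    X[i, col] <- ts$tracks[[i]]$points$x
    Y[i, col] <- ts$tracks[[i]]$points$y
  }
  med_step <- function(M) {
    D <- M[, -1L, drop = FALSE] - M[, -ncol(M), drop = FALSE]
    v <- apply(D, 2L, stats::median, na.rm = TRUE)
    v[is.na(v)] <- 0  # no spanning cell at this transition
    v
  }
  step_dx <- c(0, med_step(X))
  step_dy <- c(0, med_step(Y))
  structure(data.frame(frame = grid, step_dx = step_dx, step_dy = step_dy,
                       cum_dx = cumsum(step_dx), cum_dy = cumsum(step_dy)),
            class = c("drift_series", "data.frame"))
}

#' Subtract estimated drift from every position
#'
#' @param ts a [track_set()].
#' @param drift a `drift_series` from [estimate_drift()] on the same frame grid.
#' @return the corrected `track_set`.
#' @export
correct_drift <- function(ts, drift) {
  stopifnot(is_track_set(ts), inherits(drift, "drift_series"))
  ts$tracks <- lapply(ts$tracks, function(tr) {
    fi <- .frame_index(tr)
    idx <- match(fi, drift$frame)
    if (anyNA(idx))
      vt_stop("frame_grid_mismatch",
              "track '%s' has frames outside the drift series grid", tr$track_id)
    tr$points$x <- tr$points$x - drift$cum_dx[idx]
    tr$points$y <- tr$points$y - drift$cum_dy[idx]
    tr
  })
  ts
}

#' Write a drift series as a two-column-per-axis CSV for audit
#'
#' @param drift a `drift_series`.
#' @param path output file.
#' @export
write_drift <- function(drift, path) {
  utils::write.csv(data.frame(frame = drift$frame, dx = drift$step_dx,
                              dy = drift$step_dy), path, row.names = FALSE)
  invisible(path)
}

#' Split tracks at large gaps and filter short segments
#'
#' Tracks with missing frames are split wherever more than `max_gap`
#' consecutive frames are absent; within tolerated gaps the track stays whole
#' and the gap-spanning step is simply excluded from speed-based metrics
#' downstream (no interpolation, which would fabricate low instantaneous
#' speeds and inflate the arrest coefficient). Segments spanning less than
#' `min_duration` are discarded. Split segments keep their original id in
#' `parent_track` so per-cell metrics can pool them.
#'
#' @param ts a [track_set()].
#' @param min_duration minimum segment time span in minutes.
#' @param max_gap largest number of missing frames tolerated within a track.
#' @return the filtered `track_set`, with an attribute `"report"` giving
#'   counts of tracks kept intact, split, and segments discarded.
#' @export
split_and_filter <- function(ts, min_duration = 10, max_gap = 1) {
  stopifnot(is_track_set(ts))
  n_kept <- n_split <- n_discarded <- 0L
  out <- list()
  for (tr in ts$tracks) {
    fi <- .frame_index(tr)
    gaps <- diff(fi) - 1L
    cut_after <- which(gaps > max_gap)
    bounds <- c(0L, cut_after, nrow(tr$points))
    nseg <- length(bounds) - 1L
    if (nseg > 1L) n_split <- n_split + 1L
    kept_any <- FALSE
    for (s in seq_len(nseg)) {
      idx <- (bounds[s] + 1L):bounds[s + 1L]
      if (length(idx) < 2L || diff(range(tr$points$t[idx])) < min_duration) {
        n_discarded <- n_discarded + 1L
        next
      }
      seg <- tr
      seg$points <- tr$points[idx, , drop = FALSE]
      rownames(seg$points) <- NULL
      seg$parent_track <- tr$track_id
      if (nseg > 1L) seg$track_id <- sprintf("%s.%d", tr$track_id, s)
      out[[length(out) + 1L]] <- seg
      kept_any <- TRUE
    }
    if (kept_any && nseg == 1L) n_kept <- n_kept + 1L
  }
  res <- track_set(out, condition = ts$condition, acquisition = ts$acquisition,
                   projected = ts$projected)
  attr(res, "report") <- c(kept = n_kept, split = n_split,
                           discarded = n_discarded)
  res
}
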