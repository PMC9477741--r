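#' Track and cohort containers
#'
#' The unit of all metric computation is a `track`: one cell's ordered
#' positions (t in minutes, x/y and optionally z in micrometres) with an
#' identity, a cell-class label and a condition (regime) label. Cohorts of
#' tracks sharing acquisition parameters are held in a `track_set`.
#'
#' Units are fixed package-wide: micrometres and minutes, so every speed is
#' in um/min and every MSD in um^2.
#'
#' @param track_id scalar identifier (coerced to character).
#' @param points data.frame with columns `t`, `x`, `y` and optionally `z`.
#' @param frame_interval nominal frame spacing in minutes.
#' @param cell_class free-text label of the tracked population.
#' @param condition regime/condition label.
#' @param parent_track identifier of the original track when this track is a
#'   gap-split segment; defaults to `track_id`.
#' @return An object of class `track`.
#' @examples
#' tr <- track("a", data.frame(t = 0:2, x = c(0, 1, 2), y = 0))
#' mean_speed(tr)
#' @export
track <- function(track_id, points, frame_interval = 1.0,
                  cell_class = "unspecified", condition = "unspecified",
                  parent_track = track_id) {
  stopifnot(is.data.frame(points), all(c("t", "x", "y") %in% names(points)))
  keep <- intersect(c("t", "x", "y", "z"), names(points))
  points <- points[, keep, drop = FALSE]
  structure(
    list(track_id = as.character(track_id),
         cell_class = as.character(cell_class),
         condition = as.character(condition),
         parent_track = as.character(parent_track),
         points = points,
         frame_interval = as.numeric(frame_interval)),
    class = "track")
}

#' @rdname track
#' @param x object to test.
#' @export
is_track <- function(x) inherits(x, "track")

#' Acquisition parameters of an imaging run
#'
#' Defaults mirror a typical intravital two-photon protocol on the small
#' intestine: a 40-60 um volume scanned at 7-um Z-steps every 60 s.
#'
#' @param frame_interval minutes between frames.
#' @param volume_depth imaged depth in um.
#' @param z_step axial step in um.
#' @param localization_sigma per-coordinate localization noise s.d. in um.
#' @return list of class `acquisition_params`.
#' @export
acquisition_params <- function(frame_interval = 1.0, volume_depth = 50,
                               z_step = 7, localization_sigma = 0.3) {
  p <- list(frame_interval = frame_interval, volume_depth = volume_depth,
            z_step = z_step, localization_sigma = localization_sigma)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1))))
    vt_stop("bad_acquisition", "all acquisition parameters must be positive scalars")
  structure(p, class = "acquisition_params")
}

#' @rdname track
#' @param tracks list of `track` objects with unique ids and a common
#'   `frame_interval`.
#' @param acquisition an [acquisition_params()] object.
#' @param projected logical: have positions been 2D-projected?
#' @export
track_set <- function(tracks, condition = "unspecified",
                      acquisition = acquisition_params(), projected = FALSE) {
  stopifnot(is.list(tracks))
  if (length(tracks)) {
    if (!all(vapply(tracks, is_track, logical(1))))
      vt_stop("bad_trackset", "all elements must be track objects")
    ids <- vapply(tracks, function(t) t$track_id, character(1))
    if (anyDuplicated(ids))
      vt_stop("duplicate_track_id", "duplicated track_id: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
    fi <- vapply(tracks, function(t) t$frame_interval, numeric(1))
    if (diff(range(fi)) > 1e-9)
      vt_stop("mixed_frame_interval", "tracks do not share a frame_interval")
    names(tracks) <- ids
  }
  structure(list(tracks = tracks, condition = as.character(condition),
                 acquisition = acquisition, projected = isTRUE(projected)),
            class = "track_set")
}

#' @rdname track
#' @export
is_track_set <- function(x) inherits(x, "track_set")

#' Number of tracks in a set
#' @param ts a `track_set`.
#' @export
n_tracks <- function(ts) length(ts$tracks)

#' Validate a track against its structural invariants
#'
#' Checks that the track has at least two points, strictly increasing finite
#' times, and finite coordinates. Each failure mode raises a classed error
#' (`villustrack_error_too_short`, `villustrack_error_non_monotone_time`,
#' `villustrack_error_nonfinite`, `villustrack_error_negative_time`).
#'
#' @param tr a `track`.
#' @return the track, unchanged, if valid.
#' @export
validate_track <- function(tr) {
  if (!is_track(tr)) vt_stop("not_a_track", "not a track object")
  p <- tr$points
  if (nrow(p) < 2L)
    vt_stop("too_short", "track '%s' has %d point(s); at least 2 required",
            tr$track_id, nrow(p))
  coords <- as.matrix(p[, intersect(c("x", "y", "z"), names(p)), drop = FALSE])
  if (!all(is.finite(p$t)) || !all(is.finite(coords)))
    vt_stop("nonfinite", "track '%s' contains non-finite time or coordinates",
            tr$track_id)
  if (any(p$t < 0))
    vt_stop("negative_time", "track '%s' has negative timestamps", tr$track_id)
  if (any(diff(p$t) <= 0))
    vt_stop("non_monotone_time", "track '%s' has non-increasing timestamps",
            tr$track_id)
  tr
}

#' @export
print.track <- function(x, ...) {
  zlab <- if ("z" %in% names(x$points)) "3D" else "2D"
  cat(sprintf("<track '%s'> %s, %d points, dt=%g min, %.1f min span [%s | %s]\n",
              x$track_id, zlab, nrow(x$points), x$frame_interval,
              diff(range(x$points$t)), x$cell_class, x$condition))
  invisible(x)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set '%s'> %d tracks, dt=%g min%s\n", x$condition,
              n_tracks(x), x$acquisition$frame_interval,
              if (x$projected) ", 2D-projected" else ""))
  invisible(x)
}
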