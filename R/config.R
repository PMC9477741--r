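#' Default run configuration
#'
#' The defaults encode the analysis conventions used throughout:
#' 1-min frames, arrest threshold 3 um/min (strict `<`), 10-min minimum track
#' duration, gaps of at most 1 missing frame tolerated within a track, MSD
#' lags up to half the track length, and the spot/wavy thresholds
#' (net displacement 10 um, per-cell arrest cutoff 80%).
#'
#' @return nested list of class `run_config` with sections `acquisition`,
#'   `preprocess`, `metrics`, `classification` and `simulation`.
#' @export
default_config <- function() {
  structure(list(
    acquisition = list(
      frame_interval = 1.0,      # minutes
      volume_depth = 50,         # um
      z_step = 7,                # um
      localization_sigma = 0.3   # um per coordinate
    ),
    preprocess = list(
      drift_correction = TRUE,
      min_track_duration = 10,   # minutes
      max_gap = 1                # tolerated missing frames within a track
    ),
    metrics = list(
      arrest_threshold = 3.0,        # um/min, strict <
      msd_max_lag_fraction = 0.5,    # max lag as fraction of track length
      msd_min_tracks = 10            # truncate cohort MSD below this support
    ),
    classification = list(
      d_min = 10,                # um net displacement separating spot/wavy
      cell_arrest_cutoff = 80    # % arrest above which a cell is "arrested"
    ),
    simulation = list(
      n_tracks = 500,
      duration = 30,             # minutes
      fine_step = 0.1,           # minutes
      seed = 20220823
    )
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Unknown sections or keys are rejected (with the valid keys listed) rather
#' than silently ignored; values must have the same type as the default they
#' override. An empty or absent body yields the full default configuration.
#'
#' @param path path to a YAML config file, or `NULL` for pure defaults.
#' @return a `run_config` list with defaults filled in.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) vt_stop("missing_file", "config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  if (!is.list(user)) vt_stop("bad_config", "config must be a mapping of sections")
  for (sec in names(user)) {
    if (!sec %in% names(cfg))
      vt_stop("unknown_key", "unknown config section '%s'; valid sections: %s",
              sec, paste(names(cfg), collapse = ", "))
    entries <- user[[sec]]
    if (is.null(entries)) next
    if (!is.list(entries))
      vt_stop("bad_config", "section '%s' must be a mapping", sec)
    for (key in names(entries)) {
      if (!key %in% names(cfg[[sec]]))
        vt_stop("unknown_key", "unknown key '%s' in section '%s'; valid keys: %s",
                key, sec, paste(names(cfg[[sec]]), collapse = ", "))
      val <- entries[[key]]
      def <- cfg[[sec]][[key]]
      if (is.logical(def)) {
        if (!is.logical(val) || length(val) != 1L)
          vt_stop("type_mismatch", "'%s.%s' must be a logical scalar", sec, key)
      } else {
        if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
          vt_stop("type_mismatch", "'%s.%s' must be a finite numeric scalar", sec, key)
      }
      cfg[[sec]][[key]] <- val
    }
  }
  cfg
}
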