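#' End-to-end analysis of a track cohort
#'
#' The standard pipeline applied to every cohort, simulated or imported:
#' 2D projection, optional tissue-drift correction, gap splitting and
#' minimum-duration filtering, per-track metrics with behavioral labels,
#' cohort summary and cohort MSD.
#'
#' @param ts a [track_set()].
#' @param config a [default_config()]-style configuration.
#' @param compute_msd compute the cohort MSD curve (the slowest stage).
#' @return list with elements `metrics` (per-track table with `pattern` and
#'   `arrested` columns), `summary` (per-condition means with s.e.m.,
#'   percentage of arrested cells and pattern fractions), `msd`
#'   (cohort [msd()] curve or NULL), `drift` (estimated drift series or
#'   NULL), `filter_report` (kept/split/discarded counts).
#' @export
analyze_tracks <- function(ts, config = default_config(), compute_msd = TRUE) {
  stopifnot(is_track_set(ts))
  ts <- project_2d(ts)
  drift <- NULL
  if (isTRUE(config$preprocess$drift_correction)) {
    drift <- estimate_drift(ts)
    ts <- correct_drift(ts, drift)
  }
  ts <- split_and_filter(ts, config$preprocess$min_track_duration,
                         config$preprocess$max_gap)
  if (n_tracks(ts) == 0L)
    vt_stop("empty_cohort", "no track passed duration filtering")
  mt <- metrics_table(ts, config)
  mt$arrested <- is_arrested_cell(mt, config$classification$cell_arrest_cutoff)
  mt$pattern <- classify_pattern(mt, config$classification$d_min,
                                 config$classification$cell_arrest_cutoff)
  smy <- summarize_metrics(mt)
  extra <- do.call(rbind, lapply(split(mt, mt$condition), function(d) {
    ok <- d[!is.na(d$arrested), , drop = FALSE]
    data.frame(condition = d$condition[1],
               pct_arrested_cells = 100 * mean(ok$arrested),
               frac_spot = mean(ok$pattern == "spot"),
               frac_wavy = mean(ok$pattern == "wavy"),
               stringsAsFactors = FALSE)
  }))
  smy <- merge(smy, extra, by = "condition")
  msd_curve <- NULL
  if (compute_msd)
    msd_curve <- cohort_msd(ts, config$metrics$msd_max_lag_fraction,
                            config$metrics$msd_min_tracks)
  list(metrics = mt, summary = smy, msd = msd_curve, drift = drift,
       filter_report = attr(ts, "report"))
}

.provenance <- function(config, seed = NULL, extra = list()) {
  c(list(package = "villustrack",
         version = as.character(utils::packageVersion("villustrack")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = seed,
         config = unclass(config)), extra)
}

#' Simulate a cohort and write it to disk
#'
#' Writes the canonical track CSV, a JSON sidecar with the exact regime
#' parameters and seed, and a run log; outputs are byte-identical when rerun
#' with the same arguments.
#'
#' @param regime preset name (see [list_regimes()]) or [regime_params()].
#' @param n number of tracks.
#' @param seed RNG seed.
#' @param out_dir output directory (created if absent).
#' @param cfg a [sim_config()] for the remaining acquisition settings.
#' @return invisible list of written paths (`tracks`, `params`, `log`).
#' @export
cmd_simulate <- function(regime, n = 500, seed = 20220823, out_dir,
                         cfg = sim_config()) {
  regime <- .resolve_regime(regime)
  cfg$n_tracks <- as.integer(n)
  cfg$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ts <- simulate_cohort(regime, cfg)
  paths <- list(tracks = file.path(out_dir, paste0(regime$name, "_tracks.csv")),
                params = file.path(out_dir, paste0(regime$name, "_params.json")),
                log = file.path(out_dir, paste0(regime$name, "_run.json")))
  write_tracks(ts, paths$tracks)
  jsonlite::write_json(list(regime = unclass(regime), sim_config = unclass(cfg)),
                       paths$params, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(.provenance(cfg, seed = seed,
                                   extra = list(command = "simulate",
                                                regime = regime$name,
                                                n_tracks = cfg$n_tracks)),
                       paths$log, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Analyze a track file and write metrics, summary and MSD
#'
#' Pipeline: read, 2D-project, (optionally) drift-correct, split/filter,
#' per-track metrics and classification, cohort summary and MSD.
#'
#' @param tracks_file canonical track CSV (see [read_tracks()]).
#' @param out_dir output directory.
#' @param config a `run_config` (object or YAML path).
#' @param dialect forwarded to [read_tracks()].
#' @return invisible list with the analysis result (`result`) and written
#'   paths (`metrics`, `summary`, `msd`, `log`).
#' @export
cmd_analyze <- function(tracks_file, out_dir, config = default_config(),
                        dialect = "canonical") {
  if (is.character(config)) config <- load_config(config)
  ts <- read_tracks(tracks_file, dialect = dialect,
                    frame_interval = config$acquisition$frame_interval)
  res <- analyze_tracks(ts, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(metrics = file.path(out_dir, "metrics.csv"),
                summary = file.path(out_dir, "summary.json"),
                msd = file.path(out_dir, "msd.csv"),
                log = file.path(out_dir, "run.json"))
  utils::write.csv(res$metrics, paths$metrics, row.names = FALSE)
  jsonlite::write_json(list(conditions = res$summary,
                            filter_report = as.list(res$filter_report),
                            thresholds = config$classification,
                            arrest_threshold = config$metrics$arrest_threshold),
                       paths$summary, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(res$msd)) utils::write.csv(res$msd, paths$msd, row.names = FALSE)
  jsonlite::write_json(.provenance(config,
                                   extra = list(command = "analyze",
                                                input = basename(tracks_file))),
                       paths$log, auto_unbox = TRUE, digits = NA)
  invisible(c(list(result = res), paths))
}

#' Compare two metrics files
#'
#' @param metrics_a,metrics_b per-track metrics CSVs written by
#'   [cmd_analyze()].
#' @param metric metric column to compare.
#' @param test `"mw"` or `"anova"`.
#' @param out_file optional JSON report path.
#' @return the [compare_conditions()] report (printed).
#' @export
cmd_compare <- function(metrics_a, metrics_b, metric = "mean_speed",
                        test = "mw", out_file = NULL) {
  read_mt <- function(p) {
    d <- utils::read.csv(p, stringsAsFactors = FALSE)
    need <- c("condition", metric)
    missing <- setdiff(need, names(d))
    if (length(missing))
      vt_stop("missing_column", "'%s' lacks column(s): %s", p,
              paste(missing, collapse = ", "))
    d
  }
  a <- read_mt(metrics_a); b <- read_mt(metrics_b)
  shared <- intersect(names(a), names(b))
  rep <- compare_conditions(rbind(a[shared], b[shared]), metric = metric,
                            test = test)
  if (!is.null(out_file))
    jsonlite::write_json(unclass(rep), out_file, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", force = TRUE)
  print(rep)
  invisible(rep)
}
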