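#' Read a cohort of tracks from a delimited text file
#'
#' Two dialects are supported. The `"canonical"` dialect is the package's own
#' long/tidy table, one row per tracked position, comma- or tab-delimited
#' (autodetected), with header columns `track_id, frame, t_min, x_um, y_um`
#' plus optional `z_um`, `cell_class`, `condition`. The `"imaris_position"`
#' dialect is the position-per-row spot export of common tracking software:
#' three preamble lines, then a comma-separated header containing
#' `Position X`, `Position Y`, `Position Z`, `Time` (1-based frame index) and
#' `TrackID`; frame indices are converted to minutes via `frame_interval`.
#'
#' @param path file to read.
#' @param dialect `"canonical"` or `"imaris_position"`.
#' @param frame_interval minutes per frame (used to reconstruct time for the
#'   imaris dialect and as the nominal spacing of all tracks).
#' @param condition,cell_class labels applied where the file carries none.
#' @return a [track_set()] with one track per distinct id, points time-sorted.
#' @export
read_tracks <- function(path, dialect = c("canonical", "imaris_position"),
                        frame_interval = 1.0, condition = "unspecified",
                        cell_class = "unspecified") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) vt_stop("missing_file", "track file not found: %s", path)
  if (dialect == "canonical")
    .read_canonical(path, frame_interval, condition, cell_class)
  else
    .read_imaris(path, frame_interval, condition, cell_class)
}

.detect_sep <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
}

.num_col <- function(raw, col, rows) {
  suppressWarnings(v <- as.numeric(raw))
  bad <- which(is.na(v) & !(trimws(raw) %in% c("", "NA")))
  if (length(bad))
    vt_stop("bad_numeric", "column '%s': unparseable numeric value '%s' at data row %d",
            col, raw[bad[1]], rows[bad[1]])
  v
}

.read_canonical <- function(path, frame_interval, condition, cell_class) {
  first <- readLines(path, n = 1L)
  if (!length(first)) vt_stop("empty_file", "file '%s' is empty", path)
  sep <- .detect_sep(first)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  required <- c("track_id", "frame", "t_min", "x_um", "y_um")
  missing <- setdiff(required, names(df))
  if (length(missing))
    vt_stop("missing_column", "missing required column(s): %s",
            paste(missing, collapse = ", "))
  rows <- seq_len(nrow(df))
  if (nrow(df) == 0L)
    return(track_set(list(), condition = condition,
                     acquisition = acquisition_params(frame_interval = frame_interval)))
  frame <- .num_col(df$frame, "frame", rows)
  dup <- duplicated(paste(df$track_id, frame))
  if (any(dup))
    vt_stop("duplicate_point", "duplicate (track_id, frame) at data row %d (track '%s', frame %g)",
            which(dup)[1], df$track_id[which(dup)[1]], frame[which(dup)[1]])
  tab <- data.frame(
    track_id = df$track_id,
    frame = frame,
    t = .num_col(df$t_min, "t_min", rows),
    x = .num_col(df$x_um, "x_um", rows),
    y = .num_col(df$y_um, "y_um", rows),
    stringsAsFactors = FALSE)
  if ("z_um" %in% names(df)) {
    z <- .num_col(df$z_um, "z_um", rows)
    if (!all(is.na(z))) tab$z <- z
  }
  tab$cell_class <- if ("cell_class" %in% names(df)) df$cell_class else cell_class
  tab$condition <- if ("condition" %in% names(df)) df$condition else condition
  .assemble_tracks(tab, frame_interval, condition)
}

.read_imaris <- function(path, frame_interval, condition, cell_class) {
  df <- utils::read.table(path, header = TRUE, sep = ",", skip = 3,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  pick <- function(pattern) {
    hit <- grep(pattern, names(df), ignore.case = TRUE)
    if (!length(hit))
      vt_stop("missing_column", "imaris export lacks a column matching '%s'", pattern)
    names(df)[hit[1]]
  }
  rows <- seq_len(nrow(df))
  frame <- .num_col(df[[pick("^Time$")]], "Time", rows)
  tab <- data.frame(
    track_id = df[[pick("^TrackID$")]],
    frame = frame - 1,  # 1-based export, 0-based internal time origin
    t = (frame - 1) * frame_interval,
    x = .num_col(df[[pick("^Position X")]], "Position X", rows),
    y = .num_col(df[[pick("^Position Y")]], "Position Y", rows),
    z = .num_col(df[[pick("^Position Z")]], "Position Z", rows),
    cell_class = cell_class, condition = condition,
    stringsAsFactors = FALSE)
  dup <- duplicated(paste(tab$track_id, tab$frame))
  if (any(dup))
    vt_stop("duplicate_point", "duplicate (TrackID, Time) at data row %d", which(dup)[1])
  .assemble_tracks(tab, frame_interval, condition)
}

.assemble_tracks <- function(tab, frame_interval, condition) {
  tracks <- lapply(split(tab, tab$track_id), function(d) {
    d <- d[order(d$t), , drop = FALSE]
    cols <- intersect(c("t", "x", "y", "z"), names(d))
    track(d$track_id[1], d[, cols, drop = FALSE],
          frame_interval = frame_interval,
          cell_class = d$cell_class[1], condition = d$condition[1])
  })
  tracks <- tracks[order(names(tracks))]
  track_set(unname(tracks), condition = condition,
            acquisition = acquisition_params(frame_interval = frame_interval))
}

#' Write a track set in the canonical dialect
#'
#' Rows are emitted in deterministic order (track_id, then time), comma
#' separated, with enough digits to round-trip doubles to better than 1e-9.
#'
#' @param ts a [track_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(is_track_set(ts))
  has_z <- any(vapply(ts$tracks, function(tr) "z" %in% names(tr$points), logical(1)))
  rows <- lapply(ts$tracks, function(tr) {
    p <- tr$points[order(tr$points$t), , drop = FALSE]
    d <- data.frame(track_id = tr$track_id,
                    frame = round(p$t / tr$frame_interval),
                    t_min = p$t, x_um = p$x, y_um = p$y,
                    stringsAsFactors = FALSE)
    if (has_z) d$z_um <- if ("z" %in% names(p)) p$z else NA_real_
    d$cell_class <- tr$cell_class
    d$condition <- tr$condition
    d
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    cols <- c("track_id", "frame", "t_min", "x_um", "y_um",
              if (has_z) "z_um", "cell_class", "condition")
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    df <- df[order(df$track_id, df$t_min), , drop = FALSE]
    for (col in intersect(c("t_min", "x_um", "y_um", "z_um"), names(df)))
      df[[col]] <- sprintf("%.15g", df[[col]])
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
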