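#' Behavioral classification of tracked cells
#'
#' Two per-cell calls used in cohort reports: whether a cell is "arrested"
#' over its track duration, and the dichotomy between "spot" migration
#' (restricted, in-place tracks) and "wavy" migration (extended, meandering
#' patrolling tracks). The published dichotomy is visual; the quantitative
#' surrogate here uses net displacement and arrest coefficient, with both
#' thresholds configuration-exposed and reported alongside every output.
#'
#' @name behavior_classify
NULL

#' Is a cell arrested over its track duration?
#'
#' @param m one row of a [metrics_table()] (or any list with an
#'   `arrest_coefficient` element in percent).
#' @param cell_arrest_cutoff arrest-coefficient cutoff in percent.
#' @return `TRUE` iff the cell's arrest coefficient is at least the cutoff;
#'   `NA` for incomplete records.
#' @export
is_arrested_cell <- function(m, cell_arrest_cutoff = 80) {
  ac <- m$arrest_coefficient
  ifelse(is.na(ac), NA, ac >= cell_arrest_cutoff)
}

#' Classify a track as "spot" or "wavy"
#'
#' A cell is a "spot" if it translocates less than `d_min` um net over the
#' track, or is arrested by [is_arrested_cell()]; otherwise it is "wavy".
#' Both thresholds come from the `classification` config section.
#'
#' @param m one row (or several rows) of a [metrics_table()].
#' @param d_min net-displacement threshold in um.
#' @param cell_arrest_cutoff arrest cutoff in percent.
#' @return character vector of labels `"spot"`/`"wavy"` (`NA` when the
#'   underlying metrics are missing).
#' @export
classify_pattern <- function(m, d_min = 10, cell_arrest_cutoff = 80) {
  spot <- m$net_displacement < d_min |
    is_arrested_cell(m, cell_arrest_cutoff)
  ifelse(is.na(spot), NA_character_, ifelse(spot, "spot", "wavy"))
}

#' Estimate arrested-state occupancy from cohort arrest coefficients
#'
#' For stop-and-go motility with run speeds well above the arrest threshold
#' and bouts long relative to the frame interval, the cohort mean arrest
#' coefficient estimates the fraction of time cells spend in the arrested
#' state (the stationary occupancy `p_PA / (p_AP + p_PA)` of the two-state
#' model).
#'
#' @param mt a [metrics_table()].
#' @return estimated arrested-state occupancy in \[0, 1\].
#' @export
estimate_arrest_occupancy <- function(mt) {
  mean(mt$arrest_coefficient, na.rm = TRUE) / 100
}

#' Distribution of migration patterns per condition
#'
#' @param mt a [metrics_table()] with a `pattern` column (see
#'   [classify_pattern()]), or without one, in which case labels are computed
#'   with the thresholds given.
#' @param d_min,cell_arrest_cutoff thresholds forwarded to
#'   [classify_pattern()] when labels are absent.
#' @return data.frame with one row per condition and pattern: `condition`,
#'   `pattern`, `count`, `fraction` (fractions sum to 1 per condition).
#' @export
pattern_distribution <- function(mt, d_min = 10, cell_arrest_cutoff = 80) {
  if (!nrow(mt)) vt_stop("empty_cohort", "empty metrics table")
  if (!"pattern" %in% names(mt))
    mt$pattern <- classify_pattern(mt, d_min, cell_arrest_cutoff)
  mt <- mt[!is.na(mt$pattern), , drop = FALSE]
  if (!nrow(mt)) vt_stop("empty_cohort", "no classifiable tracks")
  out <- do.call(rbind, lapply(split(mt, mt$condition), function(d) {
    counts <- table(factor(d$pattern, levels = c("spot", "wavy")))
    data.frame(condition = d$condition[1],
               pattern = names(counts),
               count = as.integer(counts),
               fraction = as.numeric(counts) / nrow(d),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
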