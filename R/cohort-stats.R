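#' Cohort comparisons of per-track metrics
#'
#' The statistical unit is the track (cell), matching how cohort figures in
#' intravital studies plot individual cells. Two tests cover the published
#' usage: the two-tailed Mann-Whitney U for pairwise comparisons and one-way
#' ANOVA for multi-group panels.
#'
#' @name cohort_stats
NULL

#' Two-tailed Mann-Whitney U test
#'
#' Exact p value (full null distribution of U) when the smaller sample has at
#' most 8 observations and there are no ties; otherwise the normal
#' approximation with tie and continuity correction. The method actually used
#' is reported.
#'
#' @param a,b numeric samples (each non-empty).
#' @return list with elements `U` (statistic for sample `a`), `p`
#'   (two-sided), `method` (`"exact"` or `"normal_approx"`), `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) vt_stop("empty_sample", "both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) vt_stop("empty_sample", "samples must not contain NA")
  ties <- anyDuplicated(c(a, b)) > 0L
  if (length(unique(c(a, b))) == 1L) {
    # fully degenerate: every pairwise comparison is a tie
    return(list(U = length(a) * length(b) / 2, p = 1,
                method = "normal_approx", n_a = length(a), n_b = length(b)))
  }
  exact <- min(length(a), length(b)) <= 8L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(U = unname(res$statistic), p = min(1, res$p.value),
       method = if (exact) "exact" else "normal_approx",
       n_a = length(a), n_b = length(b))
}

#' One-way analysis of variance
#'
#' Classic between/within sum-of-squares decomposition with equal-variance
#' assumption. If the within-group variance is zero while group means are
#' equal, F is undefined and reported as `NA` with a note.
#'
#' @param groups list of at least 2 numeric samples, each with n >= 2.
#' @return list with `F`, `p`, `df_between`, `df_within`, `note` (NULL unless
#'   F is undefined).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    vt_stop("bad_groups", "need at least 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) vt_stop("bad_groups", "every group needs n >= 2")
  v <- unlist(groups)
  g <- factor(rep(seq_along(groups), n))
  df1 <- length(groups) - 1L
  df2 <- length(v) - length(groups)
  ssw <- sum((v - stats::ave(v, g))^2)
  ssb <- sum(tapply(v, g, length) * (tapply(v, g, mean) - mean(v))^2)
  if (ssw == 0) {
    if (ssb == 0)
      return(list(F = NA_real_, p = NA_real_, df_between = df1,
                  df_within = df2, note = "undefined: zero variance everywhere"))
    return(list(F = Inf, p = 0, df_between = df1, df_within = df2,
                note = "zero within-group variance"))
  }
  a <- stats::anova(stats::lm(v ~ g))
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       df_between = a$Df[1], df_within = a$Df[2], note = NULL)
}

#' Compare a metric across conditions
#'
#' Summarizes (n, mean, s.e.m.) per condition and tests the group difference:
#' pairwise Mann-Whitney U for `test = "mw"` or an omnibus one-way ANOVA for
#' `test = "anova"`. Tracks with a missing value of the metric are excluded,
#' with the exclusion count reported. No multiple-testing adjustment is
#' applied by default (matching per-panel reporting of unadjusted pairwise
#' tests); set `p_adjust = "holm"` to adjust the pairwise p values.
#'
#' @param mt a [metrics_table()] covering >= 1 condition (rbind several to
#'   compare cohorts).
#' @param metric column to compare, e.g. `"mean_speed"`,
#'   `"arrest_coefficient"`, `"straightness"`.
#' @param test `"mw"` or `"anova"`.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return list of class `condition_report` with `summary` (per-condition
#'   data.frame), `test`, and `comparisons` (pairwise data.frame) or `anova`
#'   (omnibus list); with a single condition only the summary, with a warning.
#' @export
compare_conditions <- function(mt, metric = "mean_speed",
                               test = c("mw", "anova"),
                               p_adjust = c("none", "holm")) {
  test <- match.arg(test)
  p_adjust <- match.arg(p_adjust)
  if (!metric %in% names(mt))
    vt_stop("unknown_metric", "unknown metric '%s'; columns: %s", metric,
            paste(names(mt), collapse = ", "))
  by_cond <- split(mt[[metric]], mt$condition)
  summary <- do.call(rbind, lapply(names(by_cond), function(cn) {
    v <- by_cond[[cn]]
    data.frame(condition = cn, n = sum(!is.na(v)), n_missing = sum(is.na(v)),
               mean = mean(v, na.rm = TRUE), sem = sem(v),
               stringsAsFactors = FALSE)
  }))
  vals <- lapply(by_cond, function(v) v[!is.na(v)])
  out <- list(metric = metric, test = test, summary = summary,
              p_adjust = p_adjust)
  if (length(vals) < 2L) {
    warning("single condition: summary only, no test performed")
    class(out) <- "condition_report"
    return(out)
  }
  if (test == "mw") {
    pairs <- utils::combn(names(vals), 2L)
    cmp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      r <- mann_whitney_u(vals[[pairs[1, k]]], vals[[pairs[2, k]]])
      data.frame(condition_a = pairs[1, k], condition_b = pairs[2, k],
                 U = r$U, p = r$p, method = r$method, stringsAsFactors = FALSE)
    }))
    if (p_adjust == "holm") cmp$p_adj <- stats::p.adjust(cmp$p, "holm")
    out$comparisons <- cmp
  } else {
    out$anova <- one_way_anova(vals)
  }
  class(out) <- "condition_report"
  out
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("Comparison of %s (%s test)\n", x$metric,
              if (x$test == "mw") "Mann-Whitney U" else "one-way ANOVA"))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE)
  if (!is.null(x$anova))
    cat(sprintf("F(%d, %d) = %.4g, p = %.3g %s\n", x$anova$df_between,
                x$anova$df_within, x$anova$F, x$anova$p,
                if (is.null(x$anova$note)) "" else paste0("(", x$anova$note, ")")))
  invisible(x)
}
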