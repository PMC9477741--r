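#' Classed error helper
#'
#' All package errors carry a subclass `villustrack_error_<id>` so callers can
#' dispatch on the failure mode rather than parse messages.
#' @noRd
vt_stop <- function(id, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("villustrack_error_", id),
                                "villustrack_error", "error", "condition")))
}

#' Standard error of the mean
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return sample s.d. divided by sqrt(n); `NA` if fewer than 2 values.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded simulations do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# near-equality on a time grid
.approx_equal <- function(a, b, tol = 1e-6) abs(a - b) <= tol
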