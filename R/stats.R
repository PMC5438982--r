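#' Percent change between two values
#'
#' \code{100 * (v1 - v0) / v0}, sign preserved: a reduction comes out
#' negative (report its magnitude when speaking of "a reduction of x\%").
#'
#' @param v0 Baseline value (non-zero).
#' @param v1 Later value.
#' @return Percent change.
#' @examples
#' percent_change(20, 9.5)   # -52.5: a 52.5% reduction
#' percent_change(3.8, 5.2)  # +36.8: a ~37% increase
#' @export
percent_change <- function(v0, v1) {
  if (any(v0 == 0)) stop("percent change undefined for a zero baseline")
  100 * (v1 - v0) / v0
}

.group_comparison <- function(group_a, group_b, a, b, t, df, p, kind,
                              degenerate = FALSE) {
  sem <- function(v) if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  data.frame(
    group_a = group_a, group_b = group_b,
    n_a = length(a), n_b = if (is.null(b)) NA_integer_ else length(b),
    mean_a = mean(a), mean_b = if (is.null(b)) NA_real_ else mean(b),
    sem_a = sem(a), sem_b = if (is.null(b)) NA_real_ else sem(b),
    t_statistic = t, df = df, p_value = p,
    test_kind = kind, degenerate = degenerate,
    stringsAsFactors = FALSE)
}

#' One-sample t-test against a reference value
#'
#' Two-sided t-test of the group mean against \code{mu0} (the "preference
#' index against zero" test of the assay). A zero-variance sample is
#' returned flagged degenerate rather than erroring.
#'
#' @param values Numeric sample, n >= 2.
#' @param mu0 Null value.
#' @param group Label for the output row.
#' @return A one-row data.frame (group comparison record) with the
#'   statistic, df, p-value and group summaries.
#' @export
one_sample_t <- function(values, mu0 = 0, group = "group") {
  if (length(values) < 2) stop("one_sample_t needs n >= 2")
  if (stats::sd(values) < .Machine$double.eps^0.5)
    return(.group_comparison(group, sprintf("mu=%g", mu0), values, NULL,
                             NA_real_, NA_real_, NA_real_, "one_sample",
                             degenerate = TRUE))
  tt <- stats::t.test(values, mu = mu0)
  .group_comparison(group, sprintf("mu=%g", mu0), values, NULL,
                    unname(tt$statistic), unname(tt$parameter),
                    tt$p.value, "one_sample")
}

#' Welch two-sample t-test
#'
#' Two-sided unpaired comparison of two groups with the Welch-Satterthwaite
#' degrees-of-freedom correction (no equal-variance assumption).
#'
#' @param values_a,values_b Numeric samples, each n >= 2.
#' @param group_a,group_b Labels for the output row.
#' @return A one-row group-comparison data.frame.
#' @export
two_sample_t <- function(values_a, values_b,
                         group_a = "A", group_b = "B") {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("two_sample_t needs n >= 2 in each group")
  if (stats::sd(values_a) < .Machine$double.eps^0.5 &&
      stats::sd(values_b) < .Machine$double.eps^0.5) {
    eq <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(.group_comparison(group_a, group_b, values_a, values_b,
                             if (eq) 0 else NA_real_, NA_real_,
                             if (eq) 1 else NA_real_, "two_sample",
                             degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  .group_comparison(group_a, group_b, values_a, values_b,
                    unname(tt$statistic), unname(tt$parameter),
                    tt$p.value, "two_sample")
}
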