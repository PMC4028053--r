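# Class-comparison statistics and the derived report arithmetic.

#' Pearson chi-square comparison of two proportions (1 df)
#'
#' Uncorrected Pearson chi-square on the 2x2 table of successes/failures —
#' the test used for every frequency contrast between gene classes except
#' the protein-domain contrasts (see [chisq_yates_2x2()]).
#'
#' @param a_success,a_total successes and total in group A.
#' @param b_success,b_total successes and total in group B.
#' @return list with `statistic`, `p`, `df`, and `undefined`/`reason` when a
#'   table margin is zero.
#' @export
chisq_prop <- function(a_success, a_total, b_success, b_total) {
  stopifnot(a_total > 0, b_total > 0,
            a_success <= a_total, b_success <= b_total,
            a_success >= 0, b_success >= 0)
  tab <- matrix(c(a_success, a_total - a_success,
                  b_success, b_total - b_success), nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0)) {
    return(list(statistic = NA_real_, p = NA_real_, df = 1L,
                undefined = TRUE, reason = "zero table margin"))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value), df = 1L,
       undefined = FALSE)
}

#' Yates-corrected chi-square on a 2x2 table (1 df)
#'
#' Used for protein-domain frequency contrasts between annotation versions.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `statistic`, `p`, `df`, and `undefined`/`reason`.
#' @export
chisq_yates_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    return(list(statistic = NA_real_, p = NA_real_, df = 1L,
                undefined = TRUE, reason = "zero table margin"))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value), df = 1L,
       undefined = FALSE)
}

#' Compare two sample means by Kolmogorov-Smirnov and Welch t tests
#'
#' Both two-sided tests are run and the least significant (largest) P-value
#' is reported, avoiding any normality or equal-variance assumption.
#' Constant, equal samples yield `p_reported = 1` by convention.
#'
#' @param sample_a,sample_b numeric samples, each of size >= 2.
#' @return list with `ks_p`, `welch_p`, `p_reported`, `mean_a`, `mean_b`.
#' @export
mean_comparison <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("mean_comparison: both samples must have at least 2 values")
  }
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0 &&
      sample_a[1] == sample_b[1]) {
    return(list(ks_p = 1, welch_p = 1, p_reported = 1,
                mean_a = mean(sample_a), mean_b = mean(sample_b)))
  }
  ks <- suppressWarnings(stats::ks.test(sample_a, sample_b))
  we <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(ks_p = unname(ks$p.value), welch_p = unname(we$p.value),
       p_reported = max(ks$p.value, we$p.value),
       mean_a = mean(sample_a), mean_b = mean(sample_b))
}

#' Derived report arithmetic
#'
#' Count deltas and percent changes between annotation versions: the delta is
#' exact integer arithmetic; the percent increase is reported to one decimal.
#'
#' @param old_value,new_value non-negative counts.
#' @return list with `delta` and `percent_increase` (`NA` when
#'   `old_value` is 0).
#' @export
derived_metrics <- function(old_value, new_value) {
  stopifnot(old_value >= 0, new_value >= 0)
  delta <- new_value - old_value
  list(delta = delta,
       percent_increase = if (old_value > 0) round(delta / old_value * 100, 1)
                          else NA_real_)
}

#' Percent reduction, rounded to an integer
#' @param old_value,new_value non-negative counts (`new_value <= old_value`
#'   gives a positive reduction).
#' @return integer percent.
#' @export
percent_reduction <- function(old_value, new_value) {
  if (old_value <= 0) return(NA_real_)
  round((old_value - new_value) / old_value * 100)
}

#' Coverage percentage to one decimal
#' @param hits,total non-negative counts.
#' @return percent to one decimal (`NA` when `total` is 0).
#' @export
coverage_percent <- function(hits, total) {
  if (total <= 0) return(NA_real_)
  round(hits / total * 100, 1)
}
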