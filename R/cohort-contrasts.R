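# Worked-example arithmetic on the published cohort characteristics table.

#' Published cohort characteristics (group medians and mother counts)
#'
#' Reads the shipped copy of the cohort summary: per growth group, the
#' median weight-Z-score change (SD), the median birth weight (kg), and
#' mother counts incl. non-secretors.
#'
#' @param path optional alternative CSV path.
#' @return data frame with columns `characteristic`, `faster`, `slower`.
#' @export
printed_cohort_summary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "printed_cohort_summary.csv",
                        package = "lactomics", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Integer-rounded percentage of a count
#' @param k numerator count.
#' @param n denominator count.
#' @return `round(100 k / n)`.
#' @export
proportion_pct <- function(k, n) {
  assert_that(n > 0, "denominator must be positive")
  round(100 * k / n)
}

#' Integer-rounded relative difference of two group medians
#'
#' `round(100 |a - b| / |b|)`: the difference between the groups expressed
#' as a percentage of the reference group's median.
#'
#' @param a median of the contrasted group.
#' @param b median of the reference group.
#' @return integer percentage.
#' @export
median_relative_difference_pct <- function(a, b) {
  assert_that(b != 0, "reference median must be nonzero")
  round(100 * abs(a - b) / abs(b))
}

#' Headline cohort contrasts from the published characteristics
#'
#' Computes, from the printed group medians and counts: the non-secretor
#' percentage among slower-group mothers, the relative gain in weight
#' Z-score change of the faster group over the slower group, and the
#' relative birth-weight deficit of the faster group.
#'
#' @param summary data frame from [printed_cohort_summary()].
#' @return named list of integer percentages:
#'   `nonsecretor_slower_pct`, `delta_zscore_gain_pct`,
#'   `birthweight_diff_pct`.
#' @export
cohort_contrasts <- function(summary = printed_cohort_summary()) {
  g <- function(ch, col) summary[summary$characteristic == ch, col]
  list(
    nonsecretor_slower_pct =
      proportion_pct(g("n_nonsecretor_mothers", "slower"),
                     g("n_mothers", "slower")),
    delta_zscore_gain_pct =
      median_relative_difference_pct(g("delta_weight_zscore_median", "faster"),
                                     g("delta_weight_zscore_median", "slower")),
    birthweight_diff_pct =
      median_relative_difference_pct(g("birth_weight_median_kg", "faster"),
                                     g("birth_weight_median_kg", "slower")))
}
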