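# Univariate screening: Mann-Whitney U with BH-FDR and median (P25-P75)
# group summaries, mirroring the study's result-table conventions.

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution (full rank-assignment enumeration, as provided by
#' [stats::wilcox.test()]) when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie-corrected
#' variance and continuity correction. Ties are handled by midranks. When
#' every value in both groups is identical the test is degenerate and p = 1.
#'
#' @param x values of group A.
#' @param y values of group B.
#' @return list with `U` (the U statistic of `x`) and `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  assert_that(length(x) > 0 && length(y) > 0, "both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1))
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} m p_(j) / j` on the sorted p-values, mapped back to
#' input order (as computed by `stats::p.adjust(method = "BH")`). `NaN`/`NA`
#' p-values propagate with a warning.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  bad <- is.na(p_values)
  if (any(bad)) warning(sprintf("%d NA/NaN p-value(s) propagated", sum(bad)))
  ok <- p_values[!bad]
  assert_that(all(ok >= 0 & ok <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Median and quartile summary per group
#'
#' Medians with 25% and 75% percentiles (linear, type-7 interpolation),
#' formatted `"median (P25-P75)"`.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param digits decimals in the formatted string (default 2).
#' @return data frame with one row per group: `group`, `median`, `p25`,
#'   `p75`, `formatted`.
#' @export
group_summary <- function(values, groups, digits = 2) {
  f <- droplevels(base::factor(groups))
  out <- do.call(rbind, lapply(levels(f), function(lev) {
    v <- values[f == lev]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = lev, median = q[2], p25 = q[1], p75 = q[3],
               formatted = sprintf("%.*f (%.*f–%.*f)", digits, q[2],
                                   digits, q[1], digits, q[3]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

significance_tier <- function(q) {
  ifelse(is.na(q), "ns",
         ifelse(q < 0.01, "**",
                ifelse(q < 0.05, "*",
                       ifelse(q < 0.1, "#", "ns"))))
}

#' Mann-Whitney + FDR screen of a feature table
#'
#' Per feature: two-sided Mann-Whitney U between the growth groups across
#' all pooled weekly samples, BH-FDR across the block, per-group
#' median (P25-P75) summaries, and a significance tier (`**` q<0.01, `*`
#' q<0.05, `#` q<0.1 trend, `ns`). An alternative collapse averages weekly
#' samples per mother first, acknowledging the within-mother correlation the
#' pooled mode ignores.
#'
#' @param table a [feature_table()] (raw or relative abundances).
#' @param metadata cohort metadata.
#' @param collapse `"pooled"` (all infant-week samples as independent, the
#'   study's table convention) or `"mother_mean"`.
#' @return data frame: feature_id, group summaries, U, p, q, tier.
#' @export
univariate_screen <- function(table, metadata,
                              collapse = c("pooled", "mother_mean")) {
  collapse <- match.arg(collapse)
  bio <- metadata[!metadata$is_qc & metadata$sample_id %in% sample_ids(table), ]
  X <- table$values[bio$sample_id, , drop = FALSE]
  grp <- bio$growth_group
  if (collapse == "mother_mean") {
    key <- paste(bio$mother_id, bio$growth_group)
    X <- apply(X, 2, function(col) tapply(col, key, mean))
    grp <- sub("^\\S+ ", "", rownames(X))
  }
  res <- do.call(rbind, lapply(colnames(X), function(fid) {
    v <- X[, fid]
    a <- v[grp == "faster"]; b <- v[grp == "slower"]
    mw <- mann_whitney(a, b)
    gs <- group_summary(v, grp)
    data.frame(feature_id = fid,
               faster = gs$formatted[gs$group == "faster"],
               slower = gs$formatted[gs$group == "slower"],
               U = mw$U, p = mw$p,
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_fdr(res$p)
  res$tier <- significance_tier(res$q)
  rownames(res) <- NULL
  res
}
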