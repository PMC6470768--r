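# Confounder-adjusted biomarker regression: per candidate feature, ordinary
# least squares of the infant weight-Z-score change on the feature plus the
# clinical confounders, with BH-FDR over the screened candidate set.

#' Single-feature confounder-adjusted regression
#'
#' Ordinary least squares of the response on
#' `[intercept, feature, confounders]` with a two-sided t-test for the
#' feature coefficient. Rows with missing values are dropped listwise (and
#' reported); a rank-deficient design is rejected naming the collinear
#' columns.
#'
#' @param feature_values numeric vector (one value per infant).
#' @param response infant weight-Z-score change (same length).
#' @param confounders numeric matrix or data frame of clinical covariates
#'   (may be NULL for an unadjusted model).
#' @return list with `coef`, `se`, `p` for the feature term, and `n` used.
#' @export
fit_feature_mlr <- function(feature_values, response, confounders = NULL) {
  assert_that(stats::sd(feature_values, na.rm = TRUE) > 0,
              "feature is constant; cannot regress")
  df <- data.frame(.response = response, .feature = feature_values)
  if (!is.null(confounders)) df <- cbind(df, as.data.frame(confounders))
  keep <- stats::complete.cases(df)
  if (any(!keep))
    message(sprintf("fit_feature_mlr: %d row(s) dropped listwise", sum(!keep)))
  df <- df[keep, , drop = FALSE]
  n_conf <- ncol(df) - 2L
  assert_that(nrow(df) > n_conf + 2,
              "too few complete observations for the model")
  mm <- stats::model.matrix(~ ., data = df[, -1, drop = FALSE])
  qrx <- qr(mm)
  if (qrx$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
    stop2(paste("rank-deficient design; collinear column(s):",
                paste(dropped, collapse = ", ")))
  }
  fit <- stats::lm(.response ~ ., data = df)
  sm <- summary(fit)$coefficients
  list(coef = sm[".feature", "Estimate"],
       se = sm[".feature", "Std. Error"],
       p = sm[".feature", "Pr(>|t|)"],
       n = nrow(df))
}

# collapse mother-week feature values to one value per infant
collapse_to_infants <- function(table, metadata,
                                collapse = c("mother_mean", "week3")) {
  collapse <- match.arg(collapse)
  bio <- metadata[!metadata$is_qc & metadata$sample_id %in% sample_ids(table), ]
  if (collapse == "week3") bio <- bio[bio$week == 3, ]
  X <- table$values[bio$sample_id, , drop = FALSE]
  inf <- unique(bio$infant_id)
  out <- matrix(NA_real_, length(inf), ncol(X),
                dimnames = list(inf, colnames(X)))
  for (id in inf) {
    rows <- bio$infant_id == id
    out[id, ] <- colMeans(X[rows, , drop = FALSE])
  }
  out
}

#' Confounder-adjusted MLR screen of candidate biomarkers
#'
#' One regression per candidate feature of the infant's weight-Z-score
#' change on the feature (weekly milk values averaged per mother and carried
#' to her infant(s), or week-3 only) plus the nine clinical confounders,
#' then BH-FDR over the screen; a candidate is flagged reliable when its
#' q-value is below `q_threshold` (default 0.1). A confounder whose missing
#' values would drop more than 20% of infants is median-imputed instead
#' (reported).
#'
#' @param candidates a [feature_table()] restricted to the screened features
#'   (e.g. the VIP selection).
#' @param metadata cohort metadata.
#' @param confounders character vector of confounder columns (default the
#'   nine clinical variables of [confounder_names()]).
#' @param collapse `"mother_mean"` (default) or `"week3"`.
#' @param q_threshold reliability threshold on the q-value.
#' @return data frame: feature_id, coef, se, p, q, reliable, n; the number
#'   of regressions run equals the number of candidates (`n_models`
#'   attribute).
#' @export
run_mlr_screen <- function(candidates, metadata,
                           confounders = confounder_names(),
                           collapse = "mother_mean",
                           q_threshold = 0.1) {
  if (ncol(candidates$values) == 0) {
    warning("empty candidate set; no models run")
    out <- data.frame(feature_id = character(0), coef = numeric(0),
                      se = numeric(0), p = numeric(0), q = numeric(0),
                      reliable = logical(0), n = integer(0))
    attr(out, "n_models") <- 0L
    return(out)
  }
  X <- collapse_to_infants(candidates, metadata, collapse)
  bio <- metadata[!metadata$is_qc, ]
  inf <- bio[!duplicated(bio$infant_id),
             c("infant_id", "delta_weight_zscore", confounders)]
  inf <- inf[match(rownames(X), inf$infant_id), ]
  conf <- inf[, confounders, drop = FALSE]
  for (cn in names(conf)) {
    miss <- is.na(conf[[cn]])
    if (mean(miss) > 0 && mean(miss) > 0.2) {
      message(sprintf("confounder '%s': %d missing value(s) median-imputed",
                      cn, sum(miss)))
      conf[[cn]][miss] <- stats::median(conf[[cn]], na.rm = TRUE)
    }
  }
  res <- do.call(rbind, lapply(colnames(X), function(fid) {
    fit <- fit_feature_mlr(X[, fid], inf$delta_weight_zscore, conf)
    data.frame(feature_id = fid, coef = fit$coef, se = fit$se, p = fit$p,
               n = fit$n, stringsAsFactors = FALSE)
  }))
  res$q <- bh_fdr(res$p)
  res$reliable <- res$q < q_threshold
  res <- res[, c("feature_id", "coef", "se", "p", "q", "reliable", "n")]
  rownames(res) <- NULL
  attr(res, "n_models") <- nrow(res)
  res
}
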