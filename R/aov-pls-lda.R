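# ANOVA-PLS discriminant workflow: one-way ANOVA decomposition of the scaled
# feature matrix on the growth factor, PLS of the factor-associated part
# against a centered dummy response, Fisher LDA on the latent scores,
# leave-one-out validation of the whole chain, and VIP-based selection.

#' One-way ANOVA decomposition of a feature matrix
#'
#' Per feature, `x = grand mean + (group mean - grand mean) + residual`.
#' The effect matrix is constant within groups and the reconstruction is
#' exact; per feature, total, effect and residual sums of squares add up.
#'
#' @param X scaled matrix (samples x features).
#' @param factor group labels (>= 2 groups, each with >= 2 samples).
#' @param nuisance optional secondary factor whose group-mean deviations are
#'   swept out of the residual (e.g. lactation week), generalizing the
#'   decomposition to designs with nuisance factors.
#' @return list with `grand_mean`, `effect`, `residual` (and `nuisance_effect`
#'   when a nuisance factor is given).
#' @export
anova_decompose <- function(X, factor, nuisance = NULL) {
  X <- as.matrix(X)
  f <- droplevels(base::factor(factor))
  assert_that(nlevels(f) >= 2, "need at least 2 groups")
  if (any(table(f) < 2))
    stop2("every group must contain at least 2 samples")
  grand <- colMeans(X)
  Xc <- sweep(X, 2, grand, "-")
  gm <- apply(Xc, 2, function(col) tapply(col, f, mean))
  effect <- gm[as.character(f), , drop = FALSE]
  dimnames(effect) <- dimnames(X)
  residual <- Xc - effect
  out <- list(grand_mean = grand, effect = effect, residual = residual)
  if (!is.null(nuisance)) {
    g <- droplevels(base::factor(nuisance))
    nm <- apply(residual, 2, function(col) tapply(col, g, mean))
    nuis <- nm[as.character(g), , drop = FALSE]
    dimnames(nuis) <- dimnames(X)
    out$nuisance_effect <- nuis
    out$residual <- residual - nuis
  }
  out
}

#' Fisher linear discriminant on latent scores
#'
#' Two-class Fisher LDA: direction `S_within^-1 (mu1 - mu2)` in score space,
#' threshold at the midpoint of the projected class means (equal priors).
#' A singular within-class scatter is regularized by a ridge of 1e-8 times
#' the mean diagonal, with a message.
#'
#' @param scores matrix of selected PLS components (samples x components).
#' @param labels two-class labels.
#' @return an `lda_axis` with `direction`, `threshold`, `canonical`
#'   (per-sample canonical values), and the class levels.
#' @export
fit_lda_on_scores <- function(scores, labels) {
  scores <- as.matrix(scores)
  f <- droplevels(base::factor(labels))
  assert_that(nlevels(f) == 2, "Fisher LDA here is two-class")
  mu <- apply(scores, 2, function(col) tapply(col, f, mean))
  mu <- matrix(mu, nrow = 2, dimnames = list(levels(f), NULL))
  sw <- matrix(0, ncol(scores), ncol(scores))
  for (lev in levels(f)) {
    s <- scores[f == lev, , drop = FALSE]
    sw <- sw + crossprod(sweep(s, 2, colMeans(s), "-"))
  }
  dmu <- mu[1, ] - mu[2, ]
  dir <- tryCatch(solve(sw, dmu), error = function(e) {
    message("within-class scatter singular; ridge 1e-8 added")
    solve(sw + diag(1e-8 * mean(diag(sw)) + 1e-12, ncol(sw)), dmu)
  })
  canon <- drop(scores %*% dir)
  pm <- tapply(canon, f, mean)
  structure(list(direction = dir,
                 threshold = unname((pm[1] + pm[2]) / 2),
                 canonical = canon,
                 levels = levels(f),
                 level_means = pm),
            class = "lda_axis")
}

#' Predict classes from a fitted LDA axis
#' @param object an `lda_axis`.
#' @param scores matrix of latent scores.
#' @param ... unused.
#' @return character vector of class labels.
#' @export
predict.lda_axis <- function(object, scores, ...) {
  v <- drop(as.matrix(scores) %*% object$direction)
  above <- object$level_means[1] >= object$threshold
  ifelse((v >= object$threshold) == above, object$levels[1], object$levels[2])
}

#' Fit the AoV-PLS + LDA discriminant chain
#'
#' Decomposes the scaled matrix on the growth factor, fits PLS on
#' `effect + residual` against the centered group dummy (in a one-way design
#' this equals PLS-DA on the centered matrix; with a nuisance factor its
#' group-mean deviations are swept out first), computes VIP on that model,
#' and fits a Fisher LDA on the first `n_components` latent scores.
#'
#' @param X scaled matrix (samples x features).
#' @param factor two-class growth labels.
#' @param n_components number of PLS components fed to the LDA.
#' @param nuisance optional nuisance factor (see [anova_decompose()]).
#' @return an `aovpls_lda` object: the decomposition, the `pls_model`, the
#'   `lda_axis`, and the training misclassification fraction.
#' @export
fit_aov_pls <- function(X, factor, n_components, nuisance = NULL) {
  X <- as.matrix(X)
  f <- droplevels(base::factor(factor))
  dec <- anova_decompose(X, f, nuisance = nuisance)
  M <- dec$effect + dec$residual
  Yd <- stats::model.matrix(~ f - 1)
  Yc <- scale(Yd, center = TRUE, scale = FALSE)
  pls <- fit_pls(M, Yc, n_components)
  lda <- fit_lda_on_scores(pls$T, f)
  train_pred <- predict(lda, pls$T)
  structure(list(grand_mean = dec$grand_mean,
                 effect = dec$effect,
                 residual = dec$residual,
                 pls = pls,
                 lda = lda,
                 factor = f,
                 n_components = pls$n_components,
                 train_error = mean(train_pred != as.character(f))),
            class = "aovpls_lda")
}

#' Predict growth group for new samples from an AoV-PLS + LDA fit
#' @param object an `aovpls_lda`.
#' @param newdata matrix on the same (scaled) feature scale as the training X.
#' @param ... unused.
#' @return character vector of class labels.
#' @export
predict.aovpls_lda <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = length(object$grand_mean))
  scores <- sweep(newdata, 2, object$grand_mean, "-") %*% object$pls$R
  predict(object$lda, scores)
}

#' Leave-one-out error of the full discriminant chain
#'
#' Per fold the entire chain is refit: scaling statistics, ANOVA
#' decomposition, PLS, LDA; the held-out sample is pushed through the
#' fold's scaling and projection. Optionally reports an infant-level error
#' by majority vote over each infant's weekly samples.
#'
#' @param X raw (or pre-scaled) matrix, samples x features.
#' @param factor two-class labels.
#' @param n_components PLS components fed to the LDA.
#' @param scaling per-fold scaling: "none", "autoscale" or "log_pareto".
#' @param infant_ids optional per-sample infant identifiers for the
#'   majority-vote error.
#' @param milk_ids optional per-sample milk identifiers; all samples of the
#'   held-out milk are excluded from each fold's training set (twins share
#'   milk samples, see [loo_cv()]).
#' @return list with `error` (sample-level fraction), `predicted`,
#'   `observed`, and `infant_error` when `infant_ids` is given.
#' @export
cv_error_chain <- function(X, factor, n_components,
                           scaling = c("none", "autoscale", "log_pareto"),
                           infant_ids = NULL, milk_ids = NULL) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  f <- droplevels(base::factor(factor))
  scale_fn <- switch(scaling,
                     none = function(x) list(x = x, spec = NULL),
                     autoscale = function(x) suppressWarnings(autoscale(x)),
                     log_pareto = function(x) suppressWarnings(log_pareto_scale(x)))
  fit_fn <- function(Xtr, ytr) {
    sc <- scale_fn(Xtr)
    list(spec = sc$spec,
         model = fit_aov_pls(sc$x, ytr, n_components))
  }
  predict_fn <- function(fit, xte) {
    if (!is.null(fit$spec)) xte <- apply_scaling(fit$spec, xte)
    predict(fit$model, xte)
  }
  cv <- loo_cv(X, f, fit_fn, predict_fn, groups = milk_ids)
  if (!is.null(infant_ids)) {
    ok <- !is.na(cv$predicted)
    vote <- tapply(cv$predicted[ok], infant_ids[ok], function(v) {
      tb <- sort(table(v), decreasing = TRUE)
      names(tb)[1]
    })
    truth <- tapply(as.character(f)[ok], infant_ids[ok], function(v) v[1])
    cv$infant_error <- mean(vote[names(truth)] != truth)
  }
  cv
}

#' Choose the number of LDA-fed PLS components by leave-one-out error
#'
#' Scans `1..max_components` and returns the smallest component count
#' achieving the minimal LOO error of the full chain.
#'
#' @inheritParams cv_error_chain
#' @param max_components largest component count scanned (default 5).
#' @param milk_ids optional per-sample milk identifiers (see [loo_cv()]).
#' @return list with `n_components`, `errors` (per candidate), and the
#'   winning `cv` result.
#' @export
select_n_components <- function(X, factor, max_components = 5,
                                scaling = "none", milk_ids = NULL) {
  a_max <- min(max_components, nrow(as.matrix(X)) - 2L, ncol(as.matrix(X)))
  errs <- numeric(a_max)
  cvs <- vector("list", a_max)
  for (a in seq_len(a_max)) {
    cvs[[a]] <- cv_error_chain(X, factor, a, scaling = scaling,
                               milk_ids = milk_ids)
    errs[a] <- cvs[[a]]$error
  }
  best <- which.min(errs)
  list(n_components = best, errors = errs, cv = cvs[[best]])
}

#' Select features by VIP threshold
#'
#' @param result an `aovpls_lda` (or a `pls_model`).
#' @param threshold VIP cutoff (default 1.5).
#' @return feature ids with VIP >= threshold, sorted by VIP descending,
#'   ties broken by feature id; the VIP values are attached as names.
#' @export
select_vip_features <- function(result, threshold = 1.5) {
  v <- if (inherits(result, "aovpls_lda")) result$pls$vip else result$vip
  assert_that(!is.null(v), "no VIP values in the supplied model")
  keep <- v[v >= threshold]
  ord <- order(-keep, names(keep))
  ids <- names(keep)[ord]
  names(ids) <- NULL
  structure(ids, vip = unname(keep[ord]))
}
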