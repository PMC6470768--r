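# Multi-omics fusion: block weighting and concatenation, unfold PCA, and
# multi-block PLS with super scores and per-component block importances.

#' Assemble a weighted super-block from scaled omics blocks
#'
#' Blocks must be sample-aligned (identical row names in identical order).
#' Each block is multiplied by its weight, default `1/sqrt(p_b)` so that an
#' autoscaled block contributes total variance independent of its width;
#' column provenance is retained.
#'
#' @param blocks named list of scaled matrices (samples x features).
#' @param weights optional named numeric vector of block weights.
#' @return a `superblock`: `x` (n x sum p_b), `ranges` (named list of column
#'   index vectors partitioning the matrix), `weights`, `block_of` (per
#'   column block name).
#' @export
assemble_superblock <- function(blocks, weights = NULL) {
  assert_that(length(blocks) >= 1, "need at least one block")
  rn <- lapply(blocks, rownames)
  assert_that(all(vapply(rn, identical, logical(1), rn[[1]])),
              "blocks are not sample-aligned (row names differ)")
  p <- vapply(blocks, ncol, integer(1))
  if (is.null(weights)) weights <- 1 / sqrt(p)
  if (!is.null(names(weights))) weights <- weights[names(blocks)]
  assert_that(all(weights > 0), "block weights must be positive")
  xw <- mapply(function(b, w) b * w, blocks, weights, SIMPLIFY = FALSE)
  x <- do.call(cbind, xw)
  ends <- cumsum(p)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  ranges <- mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
  names(ranges) <- names(blocks)
  structure(list(x = x, ranges = ranges, weights = weights,
                 block_of = rep(names(blocks), p)),
            class = "superblock")
}

#' Unfold principal components analysis
#'
#' For a 3-way array (sample x week x feature) the array is mode-1 unfolded
#' into a samples x (week * feature) matrix; a 2-way input (e.g. a
#' single-week super-block) is used as is. The unfolded matrix is
#' mean-centered and decomposed by SVD.
#'
#' @param x matrix or 3-way array.
#' @param n_components components to retain.
#' @return a `pca_model` (see [fit_pca()]).
#' @export
upca <- function(x, n_components) {
  if (length(dim(x)) == 3) {
    d <- dim(x)
    if (anyNA(x))
      stop2("inconsistent week coverage: NA slices in the 3-way array")
    x <- matrix(x, nrow = d[1], ncol = d[2] * d[3],
                dimnames = list(dimnames(x)[[1]], NULL))
  }
  fit_pca(as.matrix(x), n_components, center = TRUE)
}

#' Multi-block PLS against a class factor
#'
#' NIPALS MB-PLS with super-score deflation: per component the block weight
#' sub-vectors `w_b = X_b' u` are normalized jointly (the concatenated
#' weight has unit norm), block scores are `t_b = X_b w_b / ||w_b||`, the
#' super score is `t = sum_b omega_b t_b` with `omega_b = ||w_b||`
#' (`sum omega^2 = 1`), and every block is deflated on the super score.
#' This variant's super scores coincide with the scores of an ordinary PLS
#' on the weighted concatenated super-block. Block importance per component
#' is `omega_b^2` (summing to 1). Component signs are oriented so the
#' `positive_class` mean super score is positive on every component.
#'
#' @param blocks named list of scaled, sample-aligned matrices.
#' @param labels class labels (2 classes).
#' @param n_components number of common components.
#' @param weights optional block weights (default `1/sqrt(p_b)`).
#' @param positive_class class oriented to positive scores (default
#'   `"faster"` when present, else the first level).
#' @return an `mbpls_model`: super scores `T`, per-block scores
#'   `block_scores`, super weights/loadings `W`/`P` (columns of the weighted
#'   super-block), `omega` (blocks x components), `block_importance`,
#'   `ranges`, `weights`, class centroids, and per-block explained-variance
#'   bookkeeping (`r2x_block` and `residual_fraction_block`).
#' @export
fit_mbpls <- function(blocks, labels, n_components, weights = NULL,
                      positive_class = NULL) {
  assert_that(length(blocks) >= 2, "multi-block PLS needs >= 2 blocks")
  f <- droplevels(base::factor(labels))
  assert_that(nlevels(f) == 2, "two classes are required")
  sb <- assemble_superblock(blocks, weights)
  n <- nrow(sb$x)
  assert_that(length(f) == n, "one label per sample is required")
  if (is.null(positive_class))
    positive_class <- if ("faster" %in% levels(f)) "faster" else levels(f)[1]

  Yd <- stats::model.matrix(~ f - 1)
  Y <- scale(Yd, center = TRUE, scale = FALSE)
  Xb <- lapply(names(sb$ranges), function(b) sb$x[, sb$ranges[[b]], drop = FALSE])
  names(Xb) <- names(sb$ranges)
  ssx_b0 <- vapply(Xb, function(m) sum(m^2), numeric(1))

  B <- length(Xb)
  ptot <- ncol(sb$x)
  W <- matrix(0, ptot, n_components)
  P <- matrix(0, ptot, n_components)
  Tm <- matrix(0, n, n_components)
  omega <- matrix(0, B, n_components, dimnames = list(names(Xb), NULL))
  block_scores <- lapply(Xb, function(m) matrix(0, n, n_components))
  for (a in seq_len(n_components)) {
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    w <- rep(0, ptot)
    for (it in seq_len(500L)) {
      wb <- lapply(Xb, function(m) drop(crossprod(m, u)))
      w_new <- unlist(wb, use.names = FALSE)
      nw <- sqrt(sum(w_new^2))
      if (nw == 0) break
      w_new <- w_new / nw
      tt <- drop(do.call(cbind, Xb) %*% w_new)
      cc <- drop(crossprod(Y, tt)) / sum(tt^2)
      u_new <- drop(Y %*% cc) / sum(cc^2)
      delta <- sqrt(sum((w_new - w)^2))
      w <- w_new; u <- u_new
      if (delta < 1e-12) break
    }
    tt <- drop(do.call(cbind, Xb) %*% w)
    t2 <- sum(tt^2)
    assert_that(t2 > 0, sprintf("component %d collapsed; rank exhausted", a))
    # orient: positive_class scores positive
    if (mean(tt[f == positive_class]) < 0) { w <- -w; tt <- -tt }
    for (b in seq_along(Xb)) {
      idx <- sb$ranges[[b]]
      wb <- w[idx]
      omega[b, a] <- sqrt(sum(wb^2))
      block_scores[[b]][, a] <-
        if (omega[b, a] > 0) drop(Xb[[b]] %*% wb) / omega[b, a] else 0
    }
    pp <- drop(crossprod(do.call(cbind, Xb), tt)) / t2
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt
    for (b in seq_along(Xb)) {
      idx <- sb$ranges[[b]]
      Xb[[b]] <- Xb[[b]] - tcrossprod(tt, pp[idx])
    }
  }
  centroids <- apply(Tm, 2, function(col) tapply(col, f, mean))
  centroids <- matrix(centroids, nrow = nlevels(f),
                      dimnames = list(levels(f), NULL))
  resid_b <- vapply(Xb, function(m) sum(m^2), numeric(1)) / ssx_b0
  structure(list(n_components = n_components,
                 T = Tm, W = W, P = P,
                 R = W %*% solve(crossprod(P, W)),
                 block_scores = block_scores,
                 omega = omega,
                 block_importance = omega^2,
                 ranges = sb$ranges,
                 weights = sb$weights,
                 block_of = sb$block_of,
                 feature_ids = colnames(sb$x),
                 class_map = levels(f),
                 positive_class = positive_class,
                 centroids = centroids,
                 r2x_block = 1 - resid_b,
                 residual_fraction_block = resid_b),
            class = "mbpls_model")
}

#' Predict classes for new samples from an MB-PLS model
#' @param object an `mbpls_model`.
#' @param newblocks named list of matrices on the training (scaled) scale.
#' @param ... unused.
#' @return list with `scores` and `class` (nearest super-score centroid).
#' @export
predict.mbpls_model <- function(object, newblocks, ...) {
  xw <- mapply(function(b, w) as.matrix(b) * w,
               newblocks[names(object$ranges)],
               object$weights[names(object$ranges)], SIMPLIFY = FALSE)
  x <- do.call(cbind, xw)
  scores <- x %*% object$R
  d2 <- vapply(seq_len(nrow(object$centroids)), function(k) {
    rowSums(sweep(scores, 2, object$centroids[k, ], "-")^2)
  }, numeric(nrow(scores)))
  d2 <- matrix(d2, nrow = nrow(scores))
  list(scores = scores, class = object$class_map[apply(d2, 1, which.min)])
}

#' Rank and select features by their loadings on common components
#'
#' Features are ranked by the Euclidean norm of their loadings on the chosen
#' components, expressed on the blocks' common (unweighted) scaled-data
#' scale — super-block loadings are divided by their block weight, so that
#' features of narrow blocks (whose columns carry larger weights 1/sqrt(p))
#' are comparable with features of wide blocks. The sign of the first
#' chosen component's loading gives the direction of association (positive
#' = associated with the positively oriented class, by construction the
#' "faster" group).
#'
#' @param model an `mbpls_model`.
#' @param components components used for the ranking (default 1:2).
#' @param k number of top features to flag (default all).
#' @param quantile alternatively, retain the top loading-norm quantile
#'   (e.g. 0.25 keeps the top 25%); ignored when `k` is given.
#' @return data frame ranked by loading norm: feature_id, block,
#'   loading_norm, direction ("faster"/"slower" association), selected flag.
#' @export
select_by_loadings <- function(model, components = c(1, 2), k = NULL,
                               quantile = NULL) {
  stopifnot(inherits(model, "mbpls_model"))
  L <- model$P[, components, drop = FALSE] /
    model$weights[model$block_of]
  nrm <- sqrt(rowSums(L^2))
  neg_class <- setdiff(model$class_map, model$positive_class)[1]
  out <- data.frame(feature_id = model$feature_ids,
                    block = model$block_of,
                    loading_norm = nrm,
                    direction = ifelse(L[, 1] >= 0, model$positive_class,
                                       neg_class),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$loading_norm, out$feature_id), ]
  rownames(out) <- NULL
  n_sel <- if (!is.null(k)) min(k, nrow(out))
           else if (!is.null(quantile)) ceiling(quantile * nrow(out))
           else nrow(out)
  out$selected <- seq_len(nrow(out)) <= n_sel
  out
}

#' Leave-one-out error of the multi-block fusion chain
#'
#' Per fold, every block's scaler is re-estimated on the training samples
#' (default: autoscaling of the supplied analysis-scale matrices), MB-PLS is
#' refit, and the held-out sample is classified on the super scores. The
#' default classifier is a Fisher LDA on the training super scores —
#' mirroring the block-level PLS-then-LDA workflow, and down-weighting
#' common components that carry spread but little class separation (with a
#' two-class, rank-one response, later components are variance-dominated).
#' `"centroid"` uses the nearest class centroid instead.
#'
#' @param blocks named list of sample-aligned matrices on the analysis scale
#'   (e.g. log10 abundances, secretor-centered relative glycome).
#' @param labels two-class labels.
#' @param n_components common components (default 2).
#' @param weights optional block weights.
#' @param scalers named list of per-block scaling functions
#'   `function(x) list(x=, spec=)`; default [autoscale()] for every block.
#' @param milk_ids optional per-sample milk identifiers; samples sharing the
#'   held-out sample's milk are excluded from training (see [loo_cv()]).
#' @param classifier `"lda"` (Fisher LDA on super scores, default) or
#'   `"centroid"` (nearest class centroid).
#' @return as [loo_cv()].
#' @export
fusion_loo <- function(blocks, labels, n_components = 2, weights = NULL,
                       scalers = NULL, milk_ids = NULL,
                       classifier = c("lda", "centroid")) {
  classifier <- match.arg(classifier)
  bn <- names(blocks)
  if (is.null(scalers))
    scalers <- stats::setNames(rep(list(function(x) suppressWarnings(autoscale(x))),
                                   length(bn)), bn)
  n <- nrow(blocks[[1]])
  idx_all <- seq_len(n)
  fit_fn <- function(Xtr_idx_mat, ytr) {
    idx <- Xtr_idx_mat[, 1]
    scaled <- list(); specs <- list()
    for (b in bn) {
      sc <- scalers[[b]](blocks[[b]][idx, , drop = FALSE])
      scaled[[b]] <- sc$x
      specs[[b]] <- sc$spec
    }
    model <- fit_mbpls(scaled, ytr, n_components, weights = weights)
    lda <- if (classifier == "lda")
      suppressMessages(fit_lda_on_scores(model$T, ytr))
    list(model = model, lda = lda, specs = specs)
  }
  predict_fn <- function(fit, xte_idx_mat) {
    i <- xte_idx_mat[1, 1]
    newb <- list()
    for (b in bn) {
      xb <- blocks[[b]][i, , drop = FALSE]
      newb[[b]] <- if (!is.null(fit$specs[[b]])) apply_scaling(fit$specs[[b]], xb)
                   else xb
    }
    pr <- predict(fit$model, newb)
    if (is.null(fit$lda)) pr$class else predict(fit$lda, pr$scores)
  }
  loo_cv(matrix(idx_all, ncol = 1), labels, fit_fn, predict_fn,
         groups = milk_ids)
}
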