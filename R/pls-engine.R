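# Latent-variable core: NIPALS PLS2/PLS-DA, PCA, VIP, leave-one-out CV.

#' Fit a PLS2 model by NIPALS with X-deflation
#'
#' Standard NIPALS: per component the X-weight vector is iterated to
#' convergence (change in w below 1e-12, at most 500 iterations), the score
#' is `t = E w`, the X-loading `p = E't/(t't)`, and only X is deflated
#' (`E <- E - t p'`), so scores are mutually orthogonal and SIMCA-style.
#' Y-loadings are computed against the undeflated response. The sign of each
#' component is fixed so that the largest-magnitude element of its X-loading
#' is positive, making results platform-deterministic. Components whose
#' score norm collapses (rank exhausted) truncate the model with a warning.
#'
#' @param X centered predictor matrix (n x p).
#' @param Y centered response matrix (n x m) or vector.
#' @param n_components number of latent components (<= min(n-1, p)).
#' @return a `pls_model` with weights `W`, scores `T`, X-loadings `P`,
#'   Y-loadings `Q`, the projection matrix `R = W (P'W)^-1`, per-component
#'   `R2X`, cumulative `R2Y`, per-component explained Y sum of squares
#'   `ssy`, and per-feature `vip`.
#' @export
fit_pls <- function(X, Y, n_components) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  assert_that(n >= 3, "need at least 3 samples")
  assert_that(nrow(Y) == n, "X and Y must have the same number of rows")
  ssx0 <- sum(X^2)
  assert_that(ssx0 > 0, "X has zero variance")
  a_max <- min(n - 1L, p)
  assert_that(n_components <= a_max,
              sprintf("n_components must be <= min(n-1, p) = %d", a_max))

  E <- X
  W <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, m, n_components)
  r2x <- numeric(n_components)
  ssy <- numeric(n_components)
  ssy0 <- sum(Y^2)
  a_fit <- 0L
  for (a in seq_len(n_components)) {
    u <- Y[, which.max(apply(Y, 2, stats::var)), drop = TRUE]
    w <- rep(0, p)
    converged <- FALSE
    for (it in seq_len(500L)) {
      w_new <- drop(crossprod(E, u))
      nw <- sqrt(sum(w_new^2))
      if (nw == 0) break
      w_new <- w_new / nw
      tt <- drop(E %*% w_new)
      if (m == 1L) { w <- w_new; converged <- TRUE; break }
      cc <- drop(crossprod(Y, tt)) / sum(tt^2)
      u <- drop(Y %*% cc) / sum(cc^2)
      if (sqrt(sum((w_new - w)^2)) < 1e-12) { w <- w_new; converged <- TRUE; break }
      w <- w_new
    }
    if (!converged && sum(w^2) > 0)
      warning(sprintf("NIPALS did not converge for component %d; using best iterate", a))
    tt <- drop(E %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-12 * ssx0 / p || sum(w^2) == 0) {
      warning(sprintf("rank exhausted at component %d; model truncated", a))
      break
    }
    pp <- drop(crossprod(E, tt)) / t2
    qq <- drop(crossprod(Y, tt)) / t2
    j <- which.max(abs(pp))
    if (pp[j] < 0) { w <- -w; tt <- -tt; pp <- -pp; qq <- -qq }
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- pp; Q[, a] <- qq
    r2x[a] <- t2 * sum(pp^2) / ssx0
    ssy[a] <- t2 * sum(qq^2)
    E <- E - tcrossprod(tt, pp)
    a_fit <- a
  }
  assert_that(a_fit >= 1, "no PLS component could be extracted")
  idx <- seq_len(a_fit)
  W <- W[, idx, drop = FALSE]; Tm <- Tm[, idx, drop = FALSE]
  P <- P[, idx, drop = FALSE]; Q <- Q[, idx, drop = FALSE]
  model <- structure(list(
    n_components = a_fit,
    W = W, T = Tm, P = P, Q = Q,
    R = W %*% solve(crossprod(P, W)),
    R2X = r2x[idx],
    R2Ycum = if (ssy0 > 0) cumsum(ssy[idx]) / ssy0 else rep(NA_real_, a_fit),
    ssy = ssy[idx],
    residual_ssx_fraction = sum(E^2) / ssx0,
    feature_ids = colnames(X)), class = "pls_model")
  model$vip <- vip(model)
  model
}

#' Variable importance in the projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with unit-norm
#' weight vectors, where `SSY_a` is the response sum of squares explained by
#' component a. By construction the mean of the squared VIPs is 1.
#'
#' @param model a fitted `pls_model`.
#' @return numeric vector of per-feature VIP indices.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  tot <- sum(model$ssy)
  assert_that(tot > 0, "total explained Y sum of squares is zero")
  w2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")
  v <- sqrt(nrow(model$W) * drop(w2 %*% model$ssy) / tot)
  names(v) <- model$feature_ids
  v
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d components, R2X %s, cumulative R2Y %.3f>\n",
              x$n_components,
              paste(sprintf("%.2f", x$R2X), collapse = "+"),
              utils::tail(x$R2Ycum, 1)))
  invisible(x)
}

#' Fit a two-class (or multi-class) PLS-DA model
#'
#' The response is the centered one-hot class indicator matrix; X is centered
#' internally and the centering retained for prediction. Class prediction is
#' by nearest class centroid in score space (robust for two classes).
#'
#' @param X predictor matrix (raw or scaled; centered internally).
#' @param labels class labels (coerced to factor; >= 2 samples per class).
#' @param n_components number of latent components.
#' @return a `plsda_model` extending `pls_model` with `x_center`,
#'   `class_map` and per-class score centroids.
#' @export
fit_plsda <- function(X, labels, n_components) {
  X <- as.matrix(X)
  labels <- factor(labels)
  assert_that(nlevels(labels) >= 2, "need at least two classes")
  assert_that(all(table(labels) >= 2), "need >= 2 samples per class")
  Yd <- stats::model.matrix(~ labels - 1)
  Yc <- scale(Yd, center = TRUE, scale = FALSE)
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center, "-")
  model <- fit_pls(Xc, Yc, n_components)
  centroids <- apply(model$T, 2, function(col) tapply(col, labels, mean))
  centroids <- matrix(centroids, nrow = nlevels(labels),
                      dimnames = list(levels(labels), NULL))
  model$x_center <- x_center
  model$class_map <- levels(labels)
  model$centroids <- centroids
  class(model) <- c("plsda_model", class(model))
  model
}

#' Predict scores and classes from a PLS-DA model
#' @param object a `plsda_model`.
#' @param newdata matrix on the same scale as the training X.
#' @param ... unused.
#' @return list with `scores` and `class` (nearest score-space centroid).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = length(object$x_center),
                    dimnames = list(NULL, names(object$x_center)))
  scores <- sweep(newdata, 2, object$x_center, "-") %*% object$R
  d2 <- vapply(seq_len(nrow(object$centroids)), function(k) {
    rowSums(sweep(scores, 2, object$centroids[k, ], "-")^2)
  }, numeric(nrow(scores)))
  d2 <- matrix(d2, nrow = nrow(scores))
  list(scores = scores,
       class = object$class_map[apply(d2, 1, which.min)])
}

#' Principal components analysis by singular value decomposition
#'
#' @param X data matrix; mean-centered internally unless `center = FALSE`.
#' @param n_components number of components to retain; truncated to the
#'   matrix rank with a warning when larger.
#' @param center whether to mean-center the columns first (default TRUE).
#' @return a `pca_model` with `scores`, orthonormal `loadings`,
#'   `var_fraction` (squared-singular-value shares) and `center`.
#' @export
fit_pca <- function(X, n_components, center = TRUE) {
  X <- as.matrix(X)
  ctr <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, ctr, "-")
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (n_components > rank) {
    warning(sprintf("n_components reduced from %d to rank %d",
                    n_components, rank))
    n_components <- rank
  }
  idx <- seq_len(n_components)
  structure(list(scores = sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], n_components),
                 loadings = sv$v[, idx, drop = FALSE],
                 var_fraction = sv$d[idx]^2 / sum(sv$d^2),
                 center = ctr,
                 feature_ids = colnames(X)),
            class = "pca_model")
}

#' Leave-one-out cross-validated classification error
#'
#' Refits the full supplied chain (any scaling must live inside `fit_fn`)
#' without the held-out sample and predicts it. When `groups` is given the
#' fold also excludes every training sample sharing the held-out sample's
#' group (leave-group-out): with twins the same milk sample appears under
#' two infants, and keeping the duplicate row in training would leak the
#' held-out measurement (with the opposite label, for discordant twins).
#' Folds whose training set degenerates to a single class are skipped with
#' a warning and removed from the denominator.
#'
#' @param X predictor matrix (rows = samples).
#' @param labels class labels.
#' @param fit_fn function(X_train, labels_train) returning a fitted object.
#' @param predict_fn function(object, x_test_row_matrix) returning a class
#'   label (default: the `class` element of `predict()`).
#' @param groups optional per-sample grouping (e.g. milk sample id); all
#'   samples of the held-out group are excluded from the fold's training set.
#' @return list with `error` (misclassified fraction), `predicted`,
#'   `observed`, and `n_used`.
#' @export
loo_cv <- function(X, labels,
                   fit_fn,
                   predict_fn = function(fit, x) predict(fit, x)$class,
                   groups = NULL) {
  X <- as.matrix(X)
  labels <- factor(labels)
  n <- nrow(X)
  assert_that(n >= 4, "need at least 4 samples for leave-one-out")
  if (is.null(groups)) groups <- seq_len(n)
  assert_that(length(groups) == n, "one group per sample is required")
  pred <- rep(NA_character_, n)
  used <- rep(TRUE, n)
  for (i in seq_len(n)) {
    tr <- which(groups != groups[i])
    tr_lab <- droplevels(labels[tr])
    if (nlevels(tr_lab) < 2) {
      warning(sprintf("fold %d skipped: single class in training set", i))
      used[i] <- FALSE
      next
    }
    fit <- fit_fn(X[tr, , drop = FALSE], tr_lab)
    pred[i] <- as.character(predict_fn(fit, X[i, , drop = FALSE]))
  }
  err <- mean(pred[used] != as.character(labels)[used])
  list(error = err, predicted = pred, observed = as.character(labels),
       n_used = sum(used))
}
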