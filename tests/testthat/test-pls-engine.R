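centered <- function(m) sweep(m, 2, colMeans(m), "-")

test_that("first PLS component equals the closed form for univariate response", {
  set.seed(10)
  for (rep in 1:5) {
    X <- centered(matrix(stats::rnorm(50), 10, 5))
    y <- centered(matrix(stats::rnorm(10), 10, 1))
    m <- fit_pls(X, y, 1)
    w_closed <- drop(crossprod(X, y))
    w_closed <- w_closed / sqrt(sum(w_closed^2))
    expect_gt(abs(sum(m$W[, 1] * w_closed)), 1 - 1e-10)
  }
})

test_that("NIPALS agrees with the SVD-PLS oracle component-wise", {
  set.seed(11)
  dims <- list(c(8, 4, 2), c(12, 6, 1), c(20, 50, 3))
  for (d in dims) {
    X <- centered(matrix(stats::rnorm(d[1] * d[2]), d[1], d[2]))
    Y <- centered(matrix(stats::rnorm(d[1] * d[3]), d[1], d[3]))
    A <- 3
    m <- fit_pls(X, Y, A)
    o <- svd_pls_oracle(X, Y, A)
    for (a in seq_len(A)) {
      cosw <- abs(sum(m$W[, a] * o$W[, a])) /
        sqrt(sum(m$W[, a]^2) * sum(o$W[, a]^2))
      expect_gt(cosw, 1 - 1e-6)
      cost <- abs(sum(m$T[, a] * o$T[, a])) /
        sqrt(sum(m$T[, a]^2) * sum(o$T[, a]^2))
      expect_gt(cost, 1 - 1e-6)
    }
  }
})

test_that("PLS model satisfies its structural invariants", {
  set.seed(12)
  X <- centered(matrix(stats::rnorm(15 * 8), 15, 8))
  Y <- centered(matrix(stats::rnorm(15 * 2), 15, 2))
  m <- fit_pls(X, Y, 4)
  # scores mutually orthogonal
  G <- crossprod(m$T)
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(abs(G[i, j]), 1e-8 * sqrt(G[i, i] * G[j, j]))
  # unit-norm weights
  expect_equal(unname(colSums(m$W^2)), rep(1, 4), tolerance = 1e-10)
  # deflation conservation
  expect_equal(sum(m$R2X) + m$residual_ssx_fraction, 1, tolerance = 1e-8)
  expect_true(all(m$R2X >= 0 & m$R2X <= 1))
  expect_lte(utils::tail(m$R2Ycum, 1), 1 + 1e-10)
})

test_that("response orthogonal to X yields no explained Y variance", {
  set.seed(13)
  X <- centered(matrix(stats::rnorm(40), 10, 4))
  # build y orthogonal to all columns of X
  y <- stats::residuals(stats::lm(stats::rnorm(10) ~ X))
  m <- fit_pls(X, matrix(y - mean(y)), 1)
  expect_lt(m$R2Ycum[1], 1e-10)
})

test_that("VIP matches brute force, is 1 under symmetry, and mean VIP^2 = 1", {
  set.seed(14)
  X <- centered(matrix(stats::rnorm(12 * 6), 12, 6))
  Y <- centered(matrix(stats::rnorm(12), 12, 1))
  m <- fit_pls(X, Y, 3)
  expect_equal(unname(m$vip), vip_bruteforce(m$W, m$ssy), tolerance = 1e-10)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)
  # p equal-weight features, one component -> all VIP exactly 1
  Xs <- centered(matrix(rep(stats::rnorm(10), 4), 10, 4) +
                   matrix(stats::rnorm(40, 0, 1e-8), 10, 4))
  ms <- fit_pls(Xs, centered(matrix(Xs[, 1])), 1)
  expect_equal(unname(ms$vip), rep(1, 4), tolerance = 1e-3)
})

test_that("PLS-DA separates well-separated classes and not permuted labels", {
  set.seed(15)
  fx <- make_two_class(20, 10, shift = 5)
  m <- fit_plsda(fx$X, fx$g, 2)
  pred <- predict(m, fx$X)
  expect_equal(mean(pred$class != fx$g), 0)
  # permuted labels: little explained response variance
  fx2 <- make_two_class(50, 5, shift = 0)
  m2 <- fit_plsda(fx2$X, sample(fx2$g), 2)
  expect_lt(utils::tail(m2$R2Ycum, 1), 0.3)
  # degenerate: identical samples, different labels -> no crash
  Xd <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  Xd <- Xd + matrix(stats::rnorm(12, 0, 1e-6), 4, 3)
  expect_no_error(suppressWarnings(fit_plsda(Xd, c("a", "a", "b", "b"), 1)))
  expect_error(fit_plsda(fx$X, rep("a", 40), 1), "two classes")
})

test_that("PCA variance fractions and projection identities hold", {
  set.seed(16)
  X <- matrix(stats::rnorm(30), 10, 3)
  m <- fit_pca(X, 3)
  expect_equal(sum(m$var_fraction), 1, tolerance = 1e-10)
  expect_equal(unname(m$scores),
               unname(centered(X) %*% m$loadings), tolerance = 1e-10)
  expect_equal(unname(crossprod(m$loadings)), diag(3), tolerance = 1e-10)
  # rank-1 data on a line
  v <- stats::rnorm(8)
  Xl <- cbind(v, 2 * v)
  expect_warning(m1 <- fit_pca(Xl, 2), "rank")
  expect_equal(m1$var_fraction[1], 1, tolerance = 1e-10)
})

test_that("leave-one-out error is 0 for separated classes and ~0.5 at chance", {
  set.seed(17)
  fx <- make_two_class(10, 4, shift = 6)
  fit_fn <- function(X, g) fit_plsda(X, g, 1)
  cv <- loo_cv(fx$X, fx$g, fit_fn)
  expect_equal(cv$error, 0)
  # chance level: labels independent of X
  errs <- replicate(20, {
    fxn <- make_two_class(20, 5, shift = 0)
    loo_cv(fxn$X, fxn$g, fit_fn)$error
  })
  expect_lt(abs(mean(errs) - 0.5), 0.15)
})

test_that("a fixture with exactly 2 of 28 misclassified folds yields 7.14%", {
  # 14 + 14 samples strongly separated except two class-a samples placed
  # inside the b cluster: exactly those two fail under leave-one-out
  set.seed(18)
  X <- rbind(matrix(stats::rnorm(24, 0, 0.1), 12, 2),
             matrix(stats::rnorm(4, 10, 0.1), 2, 2),
             matrix(stats::rnorm(28, 10, 0.1), 14, 2))
  g <- rep(c("a", "b"), each = 14)
  cv <- loo_cv(X, g, function(Xt, gt) fit_plsda(Xt, gt, 1))
  expect_equal(sum(cv$predicted != cv$observed), 2)
  expect_equal(cv$error, 2 / 28)
  expect_equal(round(100 * cv$error, 2), 7.14)
})

test_that("grouped leave-one-out excludes duplicate milk rows from training", {
  # two duplicated rows with opposite labels are a coin flip, not a leak
  set.seed(19)
  base <- make_two_class(6, 3, shift = 4)
  X <- rbind(base$X, base$X[1, , drop = FALSE])
  g <- c(base$g, "b")              # duplicate of an 'a' row labelled 'b'
  groups <- c(seq_len(12), 1L)     # rows 1 and 13 share a milk sample
  cv <- loo_cv(X, g, function(Xt, gt) fit_plsda(Xt, gt, 1), groups = groups)
  # the duplicated pair gets one error (same prediction, opposite labels)
  expect_equal(sum(cv$predicted[c(1, 13)] != cv$observed[c(1, 13)]), 1)
})
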