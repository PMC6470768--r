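test_that("ANOVA decomposition reconstructs exactly and splits sums of squares", {
  set.seed(20)
  for (rep in 1:5) {
    X <- matrix(stats::rnorm(18 * 6, 5), 18, 6)
    g <- rep(c("faster", "slower"), c(8, 10))
    d <- anova_decompose(X, g)
    recon <- sweep(d$effect + d$residual, 2, d$grand_mean, "+")
    expect_equal(recon, X, tolerance = 1e-10)
    # effect rows constant within groups
    for (lev in unique(g)) {
      eg <- d$effect[g == lev, , drop = FALSE]
      expect_lt(max(apply(eg, 2, function(v) diff(range(v)))), 1e-12)
    }
    # SS_total = SS_effect + SS_residual, per feature
    Xc <- sweep(X, 2, d$grand_mean, "-")
    expect_equal(colSums(Xc^2), colSums(d$effect^2) + colSums(d$residual^2),
                 tolerance = 1e-8)
  }
  # identical group means -> zero effect
  Xi <- rbind(diag(3), diag(3))
  di <- anova_decompose(Xi, rep(c("a", "b"), each = 3))
  expect_equal(max(abs(di$effect)), 0)
  expect_error(anova_decompose(Xi, c("a", rep("b", 5))), "at least 2 samples")
})

test_that("nuisance sweeping removes the secondary factor's means", {
  set.seed(21)
  X <- matrix(stats::rnorm(24 * 4), 24, 4)
  g <- rep(c("a", "b"), each = 12)
  wk <- rep(rep(c("w2", "w3", "w4"), each = 4), 2)
  d <- anova_decompose(X, g, nuisance = wk)
  recon <- sweep(d$effect + d$nuisance_effect + d$residual, 2, d$grand_mean, "+")
  expect_equal(recon, X, tolerance = 1e-10)
  for (w in unique(wk))
    expect_lt(max(abs(colMeans(d$residual[wk == w, ]))), 1e-10)
})

test_that("AoV-PLS separates pure-effect data and finds nothing in null data", {
  # noiseless group effect: component-1 scores separate with a margin
  g <- rep(c("faster", "slower"), each = 6)
  X <- outer(ifelse(g == "faster", 1, -1), c(2, -1, 0.5)) +
    matrix(stats::rnorm(36, 0, 1e-9), 12, 3)
  fit <- fit_aov_pls(X, g, 1)
  s <- fit$pls$T[, 1]
  expect_true(max(s[g == "slower"]) < min(s[g == "faster"]) ||
                max(s[g == "faster"]) < min(s[g == "slower"]))
  # null: cumulative R2Y stays low
  set.seed(22)
  Xn <- matrix(stats::rnorm(60 * 10), 60, 10)
  fitn <- fit_aov_pls(Xn, rep(c("a", "b"), 30), 2)
  expect_lt(utils::tail(fitn$pls$R2Ycum, 1), 0.3)
})

test_that("one-way AoV-PLS equals PLS-DA on centered data", {
  set.seed(23)
  fx <- make_two_class(10, 8, shift = 1, n_shifted = 3)
  aov <- fit_aov_pls(fx$X, fx$g, 2)
  da <- fit_plsda(fx$X, fx$g, 2)
  for (a in 1:2)
    expect_gte(abs(stats::cor(aov$pls$T[, a], da$T[, a])), 0.999)
  expect_equal(unname(aov$pls$vip), unname(da$vip), tolerance = 1e-8)
})

test_that("Fisher LDA recovers the closed-form direction and midpoint threshold", {
  set.seed(24)
  mu <- c(2, -1)
  S <- rbind(matrix(stats::rnorm(400), 200, 2),
             sweep(matrix(stats::rnorm(400), 200, 2), 2, mu, "+"))
  g <- rep(c("a", "b"), each = 200)
  lda <- fit_lda_on_scores(S, g)
  # identity covariance: direction proportional to mu1 - mu2
  dmu <- colMeans(S[g == "a", ]) - colMeans(S[g == "b", ])
  cosang <- abs(sum(lda$direction * dmu)) /
    sqrt(sum(lda$direction^2) * sum(dmu^2))
  expect_gte(cosang, 0.99)
  # 1-D scores: threshold is the midpoint of the projected class means,
  # i.e. the raw-score midpoint (2+8)/2 mapped through the direction
  s1 <- matrix(c(1, 2, 3, 7, 8, 9), 6, 1)
  lda1 <- fit_lda_on_scores(s1, rep(c("a", "b"), each = 3))
  expect_equal(lda1$threshold, unname(lda1$direction) * (2 + 8) / 2)
  expect_equal(unname(predict(lda1, s1)), rep(c("a", "b"), each = 3))
  # equal class means: training error near chance
  set.seed(25)
  Sn <- matrix(stats::rnorm(200), 100, 2)
  gn <- rep(c("a", "b"), 50)
  ldan <- fit_lda_on_scores(Sn, gn)
  err <- mean(predict(ldan, Sn) != gn)
  expect_lt(abs(err - 0.5), 0.15)
  # singular scatter is ridged, not fatal
  Ssing <- cbind(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_no_error(suppressMessages(
    fit_lda_on_scores(Ssing, c("a", "a", "b", "b"))))
})

test_that("chain LOO error: power under planted effects, chance under null, deterministic", {
  set.seed(26)
  hits <- 0
  for (s in 1:20) {
    fx <- make_two_class(30, 10, shift = 2, n_shifted = 5, seed = 100 + s)
    cv <- cv_error_chain(fx$X, fx$g, 1, scaling = "autoscale")
    if (cv$error <= 0.1) hits <- hits + 1
  }
  expect_gte(hits, 18)
  errs <- vapply(1:20, function(s) {
    fx <- make_two_class(15, 10, shift = 0, seed = 200 + s)
    cv_error_chain(fx$X, fx$g, 1, scaling = "autoscale")$error
  }, numeric(1))
  expect_gt(mean(errs), 0.3); expect_lt(mean(errs), 0.7)
  # deterministic given inputs
  fx <- make_two_class(10, 6, shift = 1, seed = 7)
  cv1 <- cv_error_chain(fx$X, fx$g, 2, scaling = "autoscale")
  cv2 <- cv_error_chain(fx$X, fx$g, 2, scaling = "autoscale")
  expect_identical(cv1, cv2)
})

test_that("VIP selection honours threshold, ordering and the planted truth", {
  set.seed(27)
  # one dominant feature among 10
  n <- 40
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(stats::rnorm(n * 10, 0, 1), n, 10,
              dimnames = list(NULL, sprintf("f%02d", 1:10)))
  X[, 4] <- X[, 4] + 3 * y
  fit <- fit_aov_pls(X, ifelse(y > 0, "a", "b"), 1)
  sel <- select_vip_features(fit, 1.5)
  expect_true("f04" %in% sel)
  expect_gt(fit$pls$vip["f04"], 1.5)
  expect_equal(unname(vip_bruteforce(fit$pls$W, fit$pls$ssy)[4]),
               unname(fit$pls$vip["f04"]), tolerance = 1e-10)
  # threshold 0 selects everything, ranked by VIP
  all_sel <- select_vip_features(fit, 0)
  expect_setequal(as.character(all_sel), colnames(X))
  expect_equal(as.character(all_sel)[1], "f04")
  # all-equal weights: nobody clears 1.5
  Xeq <- outer(y, rep(1, 6)) + matrix(stats::rnorm(n * 6, 0, 1e-6), n, 6)
  colnames(Xeq) <- sprintf("e%d", 1:6)
  fiteq <- fit_aov_pls(Xeq, ifelse(y > 0, "a", "b"), 1)
  expect_length(select_vip_features(fiteq, 1.5), 0)
  expect_equal(unname(fiteq$pls$vip), rep(1, 6), tolerance = 1e-3)
})

test_that("planted-feature recovery: VIP >= 1.5 recall and precision", {
  # effect 1.0, 5 planted among 100 features, 30 samples per group
  recalls <- precisions <- numeric(20)
  for (s in 1:20) {
    fx <- make_two_class(30, 100, shift = 1, n_shifted = 5, seed = 300 + s)
    fit <- fit_aov_pls(suppressWarnings(autoscale(fx$X))$x, fx$g, 2)
    sel <- as.character(select_vip_features(fit, 1.5))
    planted <- sprintf("f%02d", 1:5)
    recalls[s] <- mean(planted %in% sel)
    precisions[s] <- if (length(sel)) mean(sel %in% planted) else 0
  }
  expect_gte(mean(recalls), 0.8)
  expect_gte(mean(precisions), 0.5)
})
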