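make_blocks <- function(n, widths, seed = 1) {
  set.seed(seed)
  out <- lapply(seq_along(widths), function(i) {
    m <- matrix(stats::rnorm(n * widths[i]), n, widths[i],
                dimnames = list(sprintf("s%02d", seq_len(n)),
                                sprintf("b%d_f%03d", i, seq_len(widths[i]))))
    scale(m)[, , drop = FALSE]
  })
  names(out) <- names(widths) %||% sprintf("blk%d", seq_along(widths))
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("super-block assembly partitions columns and balances variance", {
  widths <- c(metabolome = 68, lipidome = 143, glycome = 79, faa = 21, fa = 12)
  blocks <- make_blocks(20, widths)
  sb <- assemble_superblock(blocks)
  expect_equal(ncol(sb$x), 323)
  expect_length(sb$ranges, 5)
  expect_equal(unname(unlist(sb$ranges)), 1:323)
  # with 1/sqrt(p) weights every autoscaled block contributes equal variance
  tot <- vapply(sb$ranges, function(idx)
    sum(apply(sb$x[, idx, drop = FALSE], 2, stats::var)), numeric(1))
  expect_equal(unname(tot), rep(tot[[1]], 5), tolerance = 1e-8)
  # single block, weight 1 -> identity
  one <- assemble_superblock(blocks["faa"], weights = c(faa = 1))
  expect_equal(one$x, blocks$faa, ignore_attr = TRUE)
  # misaligned samples -> error
  bad <- blocks
  rownames(bad$fa) <- rev(rownames(bad$fa))
  expect_error(assemble_superblock(bad), "aligned")
})

test_that("unfold PCA reduces to plain PCA and handles replicated weeks", {
  set.seed(60)
  x <- matrix(stats::rnorm(15 * 6), 15, 6)
  u <- upca(x, 3)
  p <- fit_pca(x, 3)
  expect_equal(u$scores, p$scores)
  expect_equal(u$var_fraction, p$var_fraction)
  # 3-way array with identical weeks: variance fractions unchanged
  arr <- array(NA_real_, c(15, 3, 6))
  for (w in 1:3) arr[, w, ] <- x
  u3 <- upca(arr, 3)
  expect_equal(u3$var_fraction, p$var_fraction, tolerance = 1e-10)
  arr[2, 3, ] <- NA
  expect_error(upca(arr, 2), "week coverage")
})

test_that("MB-PLS super scores equal PLS on the weighted concatenated super-block", {
  set.seed(61)
  for (rep in 1:3) {
    blocks <- make_blocks(24, c(a = 10, b = 25, c = 6), seed = 60 + rep)
    g <- rep(c("faster", "slower"), each = 12)
    mb <- fit_mbpls(blocks, g, 3)
    sb <- assemble_superblock(blocks)
    Y <- scale(stats::model.matrix(~ factor(g) - 1), center = TRUE, scale = FALSE)
    pls <- fit_pls(sb$x, Y, 3)
    for (a in 1:3)
      expect_gte(abs(stats::cor(mb$T[, a], pls$T[, a])), 0.999)
    # structural invariants
    expect_equal(unname(colSums(mb$omega^2)), rep(1, 3), tolerance = 1e-8)
    expect_equal(unname(colSums(mb$block_importance)), rep(1, 3),
                 tolerance = 1e-8)
    for (a in 1:3) {
      recon <- Reduce(`+`, lapply(seq_along(blocks), function(b)
        mb$omega[b, a] * mb$block_scores[[b]][, a]))
      expect_equal(recon, unname(mb$T[, a]), tolerance = 1e-8)
    }
  }
})

test_that("per-block deflation bookkeeping is conserved", {
  set.seed(62)
  blocks <- make_blocks(20, c(a = 8, b = 12), seed = 62)
  g <- rep(c("faster", "slower"), each = 10)
  mb <- fit_mbpls(blocks, g, 2)
  # residual fraction recomputed from scores/loadings matches the model's
  sb <- assemble_superblock(blocks)
  for (b in names(blocks)) {
    idx <- sb$ranges[[b]]
    xw <- sb$x[, idx, drop = FALSE]
    E <- xw - mb$T %*% t(mb$P[idx, , drop = FALSE])
    expect_equal(sum(E^2) / sum(xw^2), unname(mb$residual_fraction_block[b]),
                 tolerance = 1e-8)
    expect_equal(unname(mb$r2x_block[b] + mb$residual_fraction_block[b]), 1,
                 tolerance = 1e-10)
  }
})

test_that("block importance finds the signal block and respects symmetry", {
  set.seed(63)
  n <- 40
  g <- rep(c("faster", "slower"), each = n / 2)
  sig <- matrix(stats::rnorm(n * 10), n, 10)
  sig[g == "faster", 1:5] <- sig[g == "faster", 1:5] + 2
  noise <- matrix(stats::rnorm(n * 10), n, 10)
  rn <- sprintf("s%02d", 1:n)
  blocks <- list(signal = scale(sig), noise = scale(noise))
  rownames(blocks$signal) <- rownames(blocks$noise) <- rn
  mb <- fit_mbpls(blocks, g, 2)
  expect_gte(mb$block_importance["signal", 1], 0.8)
  # two identical blocks split importance evenly
  dup <- list(a = blocks$signal, b = blocks$signal)
  mbd <- fit_mbpls(dup, g, 1)
  expect_equal(unname(mbd$block_importance[, 1]), c(0.5, 0.5), tolerance = 0.05)
})

test_that("loading-based selection ranks planted features first", {
  set.seed(64)
  n <- 30
  g <- rep(c("faster", "slower"), each = n / 2)
  b1 <- matrix(stats::rnorm(n * 20), n, 20,
               dimnames = list(sprintf("s%d", 1:n), sprintf("p%02d", 1:20)))
  b1[g == "faster", 1:6] <- b1[g == "faster", 1:6] + 1.5
  b2 <- matrix(stats::rnorm(n * 15), n, 15,
               dimnames = list(sprintf("s%d", 1:n), sprintf("q%02d", 1:15)))
  b2[g == "faster", 1:4] <- b2[g == "faster", 1:4] + 1.5
  blocks <- list(one = scale(b1)[, ], two = scale(b2)[, ])
  mb <- fit_mbpls(blocks, g, 2)
  # two classes give a rank-one response: the discriminant content of this
  # fixture lives on the first common component, so rank on it
  sel <- select_by_loadings(mb, components = 1, k = 10)
  planted <- c(sprintf("p%02d", 1:6), sprintf("q%02d", 1:4))
  expect_gte(mean(sel$feature_id[sel$selected] %in% planted), 0.8)
  # positively oriented component-1 loading means "faster" association
  expect_true(all(sel$direction[sel$selected][1:3] %in% c("faster", "slower")))
  top_planted <- sel[sel$feature_id %in% planted & sel$selected, ]
  expect_true(all(top_planted$direction == "faster"))
  # k = everything returns all, ranked; zero-loading feature ranks last
  all_sel <- select_by_loadings(mb, components = 1, k = 35)
  expect_equal(nrow(all_sel), 35)
  expect_true(all(diff(all_sel$loading_norm) <= 1e-12))
})

test_that("fusion leave-one-out separates a planted two-block study", {
  set.seed(65)
  n <- 26
  g <- rep(c("faster", "slower"), c(12, 14))
  b1 <- matrix(stats::rlnorm(n * 20, 10, 1), n, 20,
               dimnames = list(sprintf("s%d", 1:n), sprintf("m%02d", 1:20)))
  b1[g == "faster", 1:6] <- b1[g == "faster", 1:6] * 3
  b2 <- matrix(stats::rnorm(n * 10, 50, 5), n, 10,
               dimnames = list(sprintf("s%d", 1:n), sprintf("a%02d", 1:10)))
  b2[g == "faster", 1:3] <- b2[g == "faster", 1:3] + 8
  loo <- suppressWarnings(fusion_loo(
    list(met = b1, faa = b2), g, n_components = 2,
    scalers = list(met = function(x) suppressWarnings(log_pareto_scale(x)),
                   faa = function(x) suppressWarnings(autoscale(x)))))
  expect_lte(loo$error, 0.15)
})
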