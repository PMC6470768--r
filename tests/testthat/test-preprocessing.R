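qc_fixture <- function(qc_values) {
  # 3 QC rows + 2 biological rows; the tested feature is 'f1'
  m <- cbind(f1 = c(qc_values, 10, 20),
             f2 = c(100, 100, 100, 5, 6))
  rownames(m) <- c("QC_01", "QC_02", "QC_03", "s1", "s2")
  meta <- data.frame(sample_id = rownames(m),
                     is_qc = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  list(tab = feature_table("faa", m), meta = meta)
}

test_that("QC RSD filter removes exactly the unstable features", {
  fx <- qc_fixture(c(100, 100, 100))   # RSD 0 -> kept
  expect_equal(ncol(qc_rsd_filter(fx$tab, fx$meta)$values), 2)
  fx <- qc_fixture(c(50, 100, 150))    # sd/mean = 50/100 = 0.5 -> removed
  out <- suppressMessages(qc_rsd_filter(fx$tab, fx$meta, cutoff = 0.30))
  expect_equal(feature_ids(out), "f2")
  # infinite cutoff keeps everything
  expect_equal(ncol(qc_rsd_filter(fx$tab, fx$meta, cutoff = Inf)$values), 2)
  # no QC rows -> error
  meta2 <- fx$meta; meta2$is_qc <- FALSE
  expect_error(qc_rsd_filter(fx$tab, meta2), "QC rows")
})

test_that("QC RSD filter never removes a feature at or below the cutoff", {
  set.seed(4)
  for (rep in 1:5) {
    p <- 20
    qc <- matrix(stats::rlnorm(5 * p, 5, 0.3), 5, p,
                 dimnames = list(sprintf("QC_%02d", 1:5), sprintf("f%02d", 1:p)))
    meta <- data.frame(sample_id = rownames(qc), is_qc = TRUE)
    rsd_all <- apply(qc, 2, function(v) stats::sd(v) / mean(v))
    kept <- feature_ids(suppressMessages(
      qc_rsd_filter(feature_table("faa", qc), meta, cutoff = 0.30)))
    expect_setequal(kept, names(rsd_all)[rsd_all <= 0.30])
  }
})

test_that("relative HMO abundances are per-sample percentages", {
  m <- rbind(s1 = c(2, 3, 5), s2 = c(1, 1, 2))
  colnames(m) <- c("2100", "3110a", "3000")
  rel <- relative_hmo_abundance(feature_table("glycome", m))
  expect_equal(unname(rel$values["s1", ]), c(20, 30, 50))
  set.seed(1)
  mr <- matrix(stats::runif(50, 0.1, 10), 10, 5,
               dimnames = list(sprintf("s%d", 1:10), sprintf("310%d", 0:4)))
  relr <- relative_hmo_abundance(feature_table("glycome", mr))
  expect_equal(unname(rowSums(relr$values)), rep(100, 10), tolerance = 1e-9)
  # single feature -> all 100
  one <- relative_hmo_abundance(feature_table("glycome", mr[, 1, drop = FALSE]))
  expect_true(all(one$values == 100))
  # all-zero sample is named in the error
  mz <- mr; mz[3, ] <- 0
  expect_error(relative_hmo_abundance(feature_table("glycome", mz)), "s3")
})

test_that("HMO composition codes parse, classify and round-trip", {
  c1 <- parse_hmo_code("3210")
  expect_equal(c(c1$hex, c1$fuc, c1$hexnac, c1$neuac), c(3, 2, 1, 0))
  expect_equal(c1$fucosylation_class, "di")
  expect_false(c1$sialylated)
  c2 <- parse_hmo_code("4230b")
  expect_equal(c(c2$hex, c2$fuc, c2$hexnac, c2$neuac), c(4, 2, 3, 0))
  expect_equal(c2$isomer, "b")
  c3 <- parse_hmo_code("3000")
  expect_equal(c3$fucosylation_class, "neutral-unfucosylated")
  expect_false(c3$sialylated)
  expect_true(parse_hmo_code("3001")$sialylated)
  expect_error(parse_hmo_code("32x0"), "malformed")
  expect_error(parse_hmo_code("321"), "malformed")
  for (code in c("3210", "4230b", "2100", "3110a", "6430d"))
    expect_equal(format_hmo_code(parse_hmo_code(code)), code)
})

test_that("largest-gap split matches exhaustive enumeration of split points", {
  # oracle: try every split point of the sorted values, score by gap width
  gap_oracle <- function(x) {
    s <- sort(x)
    gaps <- vapply(seq_len(length(s) - 1), function(i) s[i + 1] - s[i],
                   numeric(1))
    i <- which.max(gaps)
    list(cut = (s[i] + s[i + 1]) / 2, gap = gaps[i])
  }
  set.seed(8)
  for (rep in 1:20) {
    x <- c(stats::rnorm(5, 0), stats::rnorm(5, 10))
    gs <- gap_split(x)
    or <- gap_oracle(x)
    expect_equal(gs$cut, or$cut)
    expect_equal(gs$gap, or$gap)
  }
})

test_that("secretor classification splits low from high 2'-FL mothers", {
  # one milk sample per mother; mothers with near-zero 2'-FL
  vals <- c(0.01, 0.02, 11, 12, 13)
  m <- cbind(`2100` = vals, `3000` = 100 - vals)
  rownames(m) <- sprintf("M%02d_I%02d_W3", 1:5, 1:5)
  meta <- data.frame(sample_id = rownames(m),
                     mother_id = sprintf("M%02d", 1:5),
                     is_qc = FALSE)
  st <- classify_secretor(feature_table("glycome", m), meta)
  expect_equal(unname(st[c("M01", "M02")]), rep("non-secretor", 2))
  expect_equal(unname(st[c("M03", "M04", "M05")]), rep("secretor", 3))
  # homogeneous high values: gap split rejected, all secretor
  vh <- seq(10, 20, length.out = 8)
  mh <- cbind(`2100` = vh, `3000` = 100 - vh)
  rownames(mh) <- sprintf("M%02d_I%02d_W3", 1:8, 1:8)
  metah <- data.frame(sample_id = rownames(mh),
                      mother_id = sprintf("M%02d", 1:8), is_qc = FALSE)
  expect_true(all(classify_secretor(feature_table("glycome", mh), metah) ==
                    "secretor"))
  expect_error(classify_secretor(feature_table("glycome", mh[1:2, ]),
                                 metah[1:2, ]), "3 mothers")
})

test_that("secretor status is recovered on synthetic cohorts", {
  cfg <- synthetic_config(n_dyads = 50, n_twin_sets = 0,
                          n_discordant_twin_sets = 0, secretor_prob = 0.8,
                          seed = 31)
  meta <- generate_cohort(cfg)
  gen <- generate_blocks(meta, cfg)
  bio <- meta[!meta$is_qc, ]
  rel <- relative_hmo_abundance(
    feature_table("glycome", gen$tables$glycome$values[bio$sample_id, ]))
  st <- classify_secretor(rel, meta)
  truth <- tapply(bio$secretor, bio$mother_id, function(s) s[1])
  expect_gte(mean(st[names(truth)] == truth), 0.95)
})

test_that("log-Pareto scaling centers and leaves variance equal to the pre-scaling SD", {
  set.seed(2)
  x <- matrix(stats::rlnorm(200, 10, 1), 20, 10,
              dimnames = list(sprintf("s%d", 1:20), sprintf("f%d", 1:10)))
  sc <- log_pareto_scale(x)
  expect_lt(max(abs(colMeans(sc$x))), 1e-10)
  lx <- log10(x + sc$spec$pseudocount)
  expect_equal(unname(apply(sc$x, 2, stats::var)),
               unname(apply(lx, 2, stats::sd)), tolerance = 1e-10)
  # hand-computed triplet, pseudocount 1
  tri <- matrix(c(10, 100, 1000), 3, 1, dimnames = list(NULL, "f"))
  out <- log_pareto_scale(tri, pseudocount = 1)
  l <- log10(c(11, 101, 1001))
  expected <- (l - mean(l)) / sqrt(stats::sd(l))
  expect_equal(unname(out$x[, 1]), expected, tolerance = 1e-12)
  # inverse transform recovers the data
  expect_equal(invert_scaling(sc$spec, sc$x), x, tolerance = 1e-8)
})

test_that("autoscaling gives unit variance and matches the direct formula", {
  set.seed(3)
  x <- matrix(stats::rnorm(60, 5, 2), 12, 5,
              dimnames = list(sprintf("s%d", 1:12), sprintf("f%d", 1:5)))
  sc <- autoscale(x)
  expect_lt(max(abs(colMeans(sc$x))), 1e-10)
  expect_equal(unname(apply(sc$x, 2, stats::var)), rep(1, 5), tolerance = 1e-10)
  expect_equal(sc$x, sweep(sweep(x, 2, colMeans(x), "-"), 2,
                           apply(x, 2, stats::sd), "/"))
  expect_equal(invert_scaling(sc$spec, sc$x), x, tolerance = 1e-10)
  # constant column is guarded
  xc <- cbind(x, cst = rep(7, 12))
  expect_warning(sc2 <- autoscale(xc), "constant")
  expect_true(all(sc2$x[, "cst"] == 0))
})

test_that("secretor-stratified centering removes the stratum means and the 2'-FL gap", {
  set.seed(6)
  status <- rep(c("secretor", "non-secretor"), c(15, 5))
  fl2 <- c(stats::rnorm(15, 12, 1), stats::rnorm(5, 0.05, 0.01))
  other <- stats::rnorm(20)
  x <- cbind(fl2 = fl2, other = other)
  ctr <- secretor_stratified_center(x, status)
  for (s in unique(status))
    expect_lt(max(abs(colMeans(ctr[status == s, ]))), 1e-10)
  # cross-stratum separation is gone: before centering the largest gap
  # splits exactly secretors from non-secretors; afterwards any remaining
  # gap no longer aligns with status
  gs0 <- gap_split(log10(fl2 + 1e-6))
  expect_true(gs0$accepted)
  expect_equal(log10(fl2 + 1e-6) < gs0$cut, status == "non-secretor",
               ignore_attr = TRUE)
  gs1 <- gap_split(ctr[, "fl2"])
  if (gs1$accepted)
    expect_false(all((ctr[, "fl2"] < gs1$cut) == (status == "non-secretor")))
  # one stratum only equals plain centering
  ctr1 <- secretor_stratified_center(x, rep("secretor", 20))
  expect_equal(ctr1, scale(x, scale = FALSE), ignore_attr = TRUE)
  # singleton stratum becomes zero, with a warning
  expect_warning(ctr2 <- secretor_stratified_center(x, c("a", rep("b", 19))),
                 "single sample")
  expect_equal(unname(ctr2[1, ]), c(0, 0))
})
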