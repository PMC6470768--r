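# Filtering, scaling, and glycome-specific transforms.

#' Remove technically unstable features by pooled-QC relative SD
#'
#' A feature is kept when its relative standard deviation (sd/mean) across
#' the pooled-QC replicate injections is at most `cutoff` (default 30%).
#' Features with zero mean across QC rows are treated as unstable.
#'
#' @param table a [feature_table()].
#' @param metadata cohort metadata with an `is_qc` flag.
#' @param cutoff RSD cutoff as a fraction (default 0.30).
#' @return the filtered [feature_table()]; removed features are reported.
#' @export
qc_rsd_filter <- function(table, metadata, cutoff = 0.30) {
  qc_ids <- metadata$sample_id[metadata$is_qc]
  qc_ids <- intersect(qc_ids, sample_ids(table))
  assert_that(length(qc_ids) >= 3, "need at least 3 QC rows for the RSD filter")
  qc <- table$values[qc_ids, , drop = FALSE]
  r <- apply(qc, 2, function(v) {
    m <- mean(v)
    if (m == 0) Inf else stats::sd(v) / m
  })
  drop <- which(r > cutoff)
  if (length(drop))
    message(sprintf("qc_rsd_filter('%s'): removed %d/%d features (RSD > %.0f%%): %s",
                    table$block_name, length(drop), ncol(table$values),
                    100 * cutoff,
                    paste(utils::head(names(drop), 10), collapse = ", ")))
  keep <- setdiff(seq_len(ncol(table$values)), drop)
  feature_table(table$block_name, table$values[, keep, drop = FALSE],
                table$feature_meta)
}

#' Relative HMO abundances (percent of per-sample total)
#'
#' Each glycome row is divided by its total peak area and expressed as a
#' percentage, so every sample's relative abundances sum to 100.
#'
#' @param glycome a glycome [feature_table()].
#' @return a [feature_table()] of percentages.
#' @export
relative_hmo_abundance <- function(glycome) {
  tot <- rowSums(glycome$values)
  if (any(tot <= 0))
    stop2(sprintf("sample '%s' has zero total HMO peak area",
                  rownames(glycome$values)[which(tot <= 0)[1]]))
  feature_table(glycome$block_name, 100 * glycome$values / tot,
                glycome$feature_meta)
}

#' Parse an HMO monosaccharide composition code
#'
#' Codes are four digits (hexose, fucose, N-acetylhexosamine,
#' N-acetylneuraminic acid counts) with an optional lower-case isomer letter,
#' e.g. `"3210"` = 3 Hex / 2 Fuc / 1 HexNAc / 0 NeuAc, or `"4230b"` =
#' isomer b of 4 Hex / 2 Fuc / 3 HexNAc / 0 NeuAc.
#'
#' @param code composition string.
#' @return an `hmo_composition` list with counts, `isomer`,
#'   `fucosylation_class` (neutral-unfucosylated / mono / di / tri / tetra,
#'   by fucose count) and `sialylated` (any NeuAc).
#' @export
parse_hmo_code <- function(code) {
  m <- regmatches(code, regexec("^([0-9])([0-9])([0-9])([0-9])([a-z]?)$", code))[[1]]
  assert_that(length(m) == 6,
              sprintf("malformed HMO composition code '%s'", code))
  counts <- as.integer(m[2:5])
  fuc_class <- switch(as.character(min(counts[2], 4)),
                      "0" = "neutral-unfucosylated", "1" = "mono",
                      "2" = "di", "3" = "tri", "4" = "tetra")
  structure(list(hex = counts[1], fuc = counts[2], hexnac = counts[3],
                 neuac = counts[4],
                 isomer = if (nzchar(m[6])) m[6] else NA_character_,
                 fucosylation_class = fuc_class,
                 sialylated = counts[4] > 0),
            class = "hmo_composition")
}

#' Format an HMO composition back into its code
#' @param comp an `hmo_composition` from [parse_hmo_code()].
#' @return the composition code string.
#' @export
format_hmo_code <- function(comp) {
  stopifnot(inherits(comp, "hmo_composition"))
  paste0(comp$hex, comp$fuc, comp$hexnac, comp$neuac,
         if (!is.na(comp$isomer)) comp$isomer else "")
}

#' Largest-gap split statistics of a 1-D sample
#'
#' Sorts the values, finds the largest consecutive gap, and compares it to
#' the median of the remaining gaps. The split is accepted when the largest
#' gap exceeds `ratio` times that median spread (a positive gap is required).
#'
#' @param x numeric values.
#' @param ratio acceptance multiple (default 3).
#' @return list with `accepted`, `cut` (midpoint of the widest gap),
#'   `gap`, and `spread` (median of the other gaps).
#' @export
gap_split <- function(x, ratio = 3) {
  s <- sort(x)
  g <- diff(s)
  if (length(g) == 0 || max(g) == 0)
    return(list(accepted = FALSE, cut = NA_real_, gap = 0, spread = 0))
  i <- which.max(g)
  spread <- stats::median(g[-i])
  accepted <- if (spread <= 0) g[i] > 0 else g[i] > ratio * spread
  list(accepted = accepted, cut = (s[i] + s[i + 1]) / 2,
       gap = g[i], spread = spread)
}

#' Classify maternal secretor status from milk 2'-FL levels
#'
#' Mothers are split on their mean relative 2'-FL abundance by the largest
#' gap in the sorted log10 values (abundances are log-normal, so cluster
#' separation is multiplicative; the split is accepted when the gap exceeds
#' 3x the median within-cluster spread); independently of the clustering,
#' mothers below an absolute floor of 1% relative 2'-FL are called
#' non-secretor. Secretor milk carries high 2'-FL; non-secretor milk has
#' very low or undetectable levels.
#'
#' @param glycome glycome [feature_table()] of relative abundances
#'   (see [relative_hmo_abundance()]).
#' @param metadata cohort metadata mapping samples to mothers.
#' @param fl2_feature_id identifier of the 2'-FL feature (default `"2100"`).
#' @param floor absolute non-secretor floor in percent (default 1).
#' @return named character vector (mother id -> "secretor"/"non-secretor").
#' @export
classify_secretor <- function(glycome, metadata, fl2_feature_id = "2100",
                              floor = 1) {
  assert_that(fl2_feature_id %in% feature_ids(glycome),
              sprintf("2'-FL feature '%s' not present", fl2_feature_id))
  bio <- metadata[!metadata$is_qc & metadata$sample_id %in% sample_ids(glycome), ]
  fl2 <- glycome$values[bio$sample_id, fl2_feature_id]
  mfl2 <- tapply(fl2, bio$mother_id, mean)
  assert_that(length(mfl2) >= 3, "need at least 3 mothers to classify")
  eps <- 1e-6
  gs <- gap_split(log10(as.numeric(mfl2) + eps))
  status <- rep("secretor", length(mfl2))
  names(status) <- names(mfl2)
  if (gs$accepted) status[log10(mfl2 + eps) < gs$cut] <- "non-secretor"
  status[mfl2 < floor] <- "non-secretor"
  status
}

apply_scaling_matrix <- function(x, spec) {
  if (spec$method == "log_pareto") x <- log10(x + spec$pseudocount)
  sweep(sweep(x, 2, spec$center, "-"), 2, spec$scale, "/")
}

reorder_to_spec <- function(x, spec) {
  if (!is.null(names(spec$center)) && !is.null(colnames(x)))
    x[, names(spec$center), drop = FALSE]
  else x
}

#' Log-Pareto scale a block
#'
#' Applies `log10(x + pseudocount)`, then centers each feature and divides by
#' the square root of its standard deviation (Pareto scaling), damping the
#' orders-of-magnitude spread of MS peak areas without inflating noise the
#' way full autoscaling does. The pseudocount defaults to half the smallest
#' nonzero value in the block (below-detection zeros are kept finite).
#' Features constant after the log transform get scale 1 with a warning.
#'
#' @param block a [feature_table()] or numeric matrix.
#' @param pseudocount abundance offset before the log; default half the
#'   smallest nonzero value.
#' @return list with `x` (scaled matrix) and `spec` (a `scaling_spec`
#'   retaining the statistics for [apply_scaling()]/[invert_scaling()]).
#' @export
log_pareto_scale <- function(block, pseudocount = NULL) {
  x <- if (inherits(block, "feature_table")) block$values else block
  assert_that(all(x >= 0), "log-Pareto scaling expects non-negative values")
  if (is.null(pseudocount)) {
    nz <- x[x > 0]
    pseudocount <- if (length(nz)) min(nz) / 2 else 1
  }
  assert_that(pseudocount > 0, "pseudocount must be positive")
  lx <- log10(x + pseudocount)
  mu <- colMeans(lx)
  sdv <- apply(lx, 2, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    warning(sprintf("%d constant feature(s) after log; scale set to 1",
                    sum(const)))
    sdv[const] <- 1
  }
  spec <- structure(list(method = "log_pareto", pseudocount = pseudocount,
                         center = mu, scale = sqrt(sdv)),
                    class = "scaling_spec")
  list(x = apply_scaling_matrix(x, spec), spec = spec)
}

#' Autoscale a block (unit variance)
#'
#' Centers each feature and divides by its standard deviation. Used for the
#' blocks whose features share comparable magnitudes (glycome relative
#' abundances, fatty acids, free amino acids). Constant features get scale 1
#' with a warning.
#'
#' @inheritParams log_pareto_scale
#' @return list with `x` and `spec` as in [log_pareto_scale()].
#' @export
autoscale <- function(block) {
  x <- if (inherits(block, "feature_table")) block$values else block
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    warning(sprintf("%d constant feature(s); scale set to 1", sum(const)))
    sdv[const] <- 1
  }
  spec <- structure(list(method = "autoscale", pseudocount = 0,
                         center = mu, scale = sdv),
                    class = "scaling_spec")
  list(x = apply_scaling_matrix(x, spec), spec = spec)
}

#' Apply a retained scaling to new data
#' @param spec a `scaling_spec`.
#' @param x matrix (or [feature_table()]) on the original abundance scale.
#' @return scaled matrix.
#' @export
apply_scaling <- function(spec, x) {
  stopifnot(inherits(spec, "scaling_spec"))
  if (inherits(x, "feature_table")) x <- x$values
  apply_scaling_matrix(reorder_to_spec(x, spec), spec)
}

#' Invert a retained scaling
#' @param spec a `scaling_spec`.
#' @param y scaled matrix.
#' @return matrix on the original abundance scale.
#' @export
invert_scaling <- function(spec, y) {
  stopifnot(inherits(spec, "scaling_spec"))
  x <- sweep(sweep(y, 2, spec$scale, "*"), 2, spec$center, "+")
  if (spec$method == "log_pareto") x <- 10^x - spec$pseudocount
  x
}

#' Center features within maternal secretor strata
#'
#' Subtracts, per feature, the mean of each secretor stratum, removing the
#' cross-stratum separation (notably of 2'-FL) before multi-omics fusion.
#' A stratum of size 1 is centered on its own value (becomes 0), with a
#' warning.
#'
#' @param x scaled glycome matrix (samples x features).
#' @param statuses per-sample secretor status (character vector aligned with
#'   the rows of `x`).
#' @return centered matrix.
#' @export
secretor_stratified_center <- function(x, statuses) {
  assert_that(length(statuses) == nrow(x),
              "one status per row of x is required")
  out <- x
  for (s in unique(statuses)) {
    idx <- which(statuses == s)
    if (length(idx) < 2)
      warning(sprintf("secretor stratum '%s' has a single sample", s))
    out[idx, ] <- sweep(x[idx, , drop = FALSE], 2,
                        colMeans(x[idx, , drop = FALSE]), "-")
  }
  out
}
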