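# Synthetic cohort and multi-omics block generator.
#
# Emulates a two-growth-group preterm mother-infant dyad study: weekly milk
# samples (weeks 2-4), twin sets (some with discordant growth), maternal
# secretor status driving 2'-FL, pooled-QC technical replicates, and planted
# group-discriminant features with a configurable standardized effect size.

#' Configuration for the synthetic milk-omics study
#'
#' Defaults reproduce the structure of the studied sub-cohort: 26 dyads in
#' two growth groups, four twin sets of which two are growth-discordant,
#' ~20% non-secretor mothers, three weekly samples per dyad and pooled-QC
#' replicates.
#'
#' @param n_dyads number of mother-infant dyads (infants; twins share a
#'   mother, so the number of mothers is `n_dyads - n_twin_sets`).
#' @param n_twin_sets number of twin pairs.
#' @param n_discordant_twin_sets twin pairs with one infant per growth group.
#' @param weeks lactation weeks sampled (default 2, 3, 4).
#' @param block_sizes named integer vector, features per omics block.
#' @param n_planted named integer vector, group-discriminant features planted
#'   per block.
#' @param effect_size standardized mean difference (Cohen's d) between growth
#'   groups on the log scale for planted features.
#' @param secretor_prob probability that a mother is a secretor.
#' @param qc_replicates number of pooled-QC technical replicate injections.
#' @param qc_cv technical coefficient of variation of stable features across
#'   QC replicates.
#' @param unstable_frac fraction of features given a large technical CV
#'   (drawn from U(0.4, 0.8)) so that the QC-RSD filter has realistic work.
#' @param birthweight_corr target correlation between birth weight and the
#'   weight Z-score change (negative in the cohort).
#' @param missing_rate fraction of below-detection zeros injected into
#'   biological samples.
#' @param week_corr within-mother week-to-week correlation of the latent
#'   feature profile.
#' @param seed integer seed; regeneration with the same seed is
#'   bit-reproducible.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_dyads = 26L,
                             n_twin_sets = 4L,
                             n_discordant_twin_sets = 2L,
                             weeks = c(2L, 3L, 4L),
                             block_sizes = c(metabolome_pos = 120L,
                                             metabolome_neg = 110L,
                                             lipidome = 140L,
                                             glycome = 40L,
                                             faa = 20L, fa = 12L),
                             n_planted = c(metabolome_pos = 12L,
                                           metabolome_neg = 11L,
                                           lipidome = 14L,
                                           glycome = 6L,
                                           faa = 3L, fa = 2L),
                             effect_size = 1.0,
                             secretor_prob = 0.8,
                             qc_replicates = 8L,
                             qc_cv = 0.10,
                             unstable_frac = 0.05,
                             birthweight_corr = -0.5,
                             missing_rate = 0.02,
                             week_corr = 0.5,
                             seed = 1L) {
  assert_that(n_discordant_twin_sets <= n_twin_sets,
              "n_discordant_twin_sets must not exceed n_twin_sets")
  assert_that(n_twin_sets <= n_dyads / 2,
              "n_twin_sets must not exceed n_dyads/2")
  assert_that(secretor_prob >= 0 && secretor_prob <= 1,
              "secretor_prob must lie in [0, 1]")
  assert_that(effect_size >= 0, "effect_size must be non-negative")
  assert_that(qc_cv > 0, "qc_cv must be positive")
  assert_that(all(names(n_planted) %in% names(block_sizes)),
              "n_planted names must match block_sizes names")
  assert_that(all(block_sizes[names(n_planted)] >= n_planted),
              "every block must have at least n_planted features")
  cfg <- list(n_dyads = as.integer(n_dyads),
              n_twin_sets = as.integer(n_twin_sets),
              n_discordant_twin_sets = as.integer(n_discordant_twin_sets),
              weeks = as.integer(weeks),
              block_sizes = block_sizes,
              n_planted = n_planted,
              effect_size = effect_size,
              secretor_prob = secretor_prob,
              qc_replicates = as.integer(qc_replicates),
              qc_cv = qc_cv,
              unstable_frac = unstable_frac,
              birthweight_corr = birthweight_corr,
              missing_rate = missing_rate,
              week_corr = week_corr,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Names of the clinical confounders carried by the cohort metadata
#' @return character vector of column names.
#' @export
confounder_names <- function() {
  c("maternal_bmi", "birth_weight", "gestational_age",
    "protein_intake", "lipid_intake", "energy_intake",
    "parenteral_days", "ventilation_days", "hospital_stay")
}

#' Generate the cohort design and clinical metadata
#'
#' One row per infant-week plus one row per pooled-QC injection. The weight
#' Z-score change is drawn from a two-mode Gaussian mixture (modes at the
#' published group medians -0.479 and -1.538 SD) so that the growth-group
#' split is clean; birth weight is negatively correlated with the Z-score
#' change at the configured strength; twins share a mother (hence milk
#' samples) and discordant twin sets have one infant per growth group.
#'
#' @param config a [synthetic_config()].
#' @return a data frame of cohort metadata (see [validate_cohort_metadata()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_inf <- config$n_dyads
  n_twin <- config$n_twin_sets
  n_disc <- config$n_discordant_twin_sets
  n_mothers <- n_inf - n_twin
  assert_that(n_mothers >= 1, "infeasible twin configuration: no mothers left")

  mother_ids <- sprintf("M%02d", seq_len(n_mothers))
  # first n_twin mothers carry twins; first n_disc of those are discordant
  infant_mother <- c(rep(mother_ids[seq_len(n_twin)], each = 2),
                     mother_ids[seq(n_twin + 1, length.out = n_mothers - n_twin)])
  n_inf_chk <- length(infant_mother)
  stopifnot(n_inf_chk == n_inf)
  infant_ids <- sprintf("I%02d", seq_len(n_inf))
  twin_set <- rep(NA_character_, n_inf)
  if (n_twin > 0)
    twin_set[seq_len(2 * n_twin)] <- rep(sprintf("T%02d", seq_len(n_twin)), each = 2)

  # growth groups
  group <- character(n_inf)
  for (k in seq_len(n_twin)) {
    idx <- which(twin_set == sprintf("T%02d", k))
    if (k <= n_disc) {
      group[idx] <- c("faster", "slower")
    } else {
      group[idx] <- rep(sample(c("faster", "slower"), 1), 2)
    }
  }
  singles <- which(is.na(twin_set))
  group[singles] <- sample(c("faster", "slower"), length(singles), replace = TRUE)

  # weight Z-score change: Gaussian modes at the two group medians
  dz <- ifelse(group == "faster",
               stats::rnorm(n_inf, -0.479, 0.189),
               stats::rnorm(n_inf, -1.538, 0.417))

  # birth weight correlated (negatively) with delta Z-score
  r <- config$birthweight_corr
  z_std <- as.numeric(scale(dz))
  bw_lat <- r * z_std + sqrt(max(0, 1 - r^2)) * stats::rnorm(n_inf)
  birth_weight <- pmax(0.6, 1.43 + 0.30 * bw_lat)

  # per-mother variables
  secretor <- ifelse(stats::rbinom(n_mothers, 1, config$secretor_prob) == 1,
                     "secretor", "non-secretor")
  names(secretor) <- mother_ids
  maternal_bmi <- stats::rnorm(n_mothers, 23.5, 4.2)
  names(maternal_bmi) <- mother_ids
  ga_mother <- pmin(33, pmax(26, stats::rnorm(n_mothers, 30.5, 1.5)))
  names(ga_mother) <- mother_ids

  infants <- data.frame(
    infant_id = infant_ids,
    mother_id = infant_mother,
    twin_set_id = twin_set,
    growth_group = group,
    delta_weight_zscore = dz,
    secretor = unname(secretor[infant_mother]),
    maternal_bmi = unname(maternal_bmi[infant_mother]),
    birth_weight = birth_weight,
    gestational_age = unname(ga_mother[infant_mother]),
    protein_intake = stats::rnorm(n_inf, 3.5, 0.4),
    lipid_intake = stats::rnorm(n_inf, 6.2, 0.9),
    energy_intake = stats::rnorm(n_inf, 125, 12),
    parenteral_days = pmax(0, round(stats::rnorm(n_inf, 12, 6))),
    ventilation_days = pmax(0, round(stats::rnorm(n_inf, 3, 3))),
    hospital_stay = pmax(25, round(stats::rnorm(n_inf, 50, 8))),
    stringsAsFactors = FALSE)

  rows <- merge(infants,
                expand.grid(infant_id = infant_ids, week = config$weeks,
                            stringsAsFactors = FALSE),
                by = "infant_id")
  rows <- rows[order(rows$infant_id, rows$week), ]
  rows$sample_id <- sprintf("%s_%s_W%d", rows$mother_id, rows$infant_id, rows$week)
  rows$milk_id <- sprintf("%s_W%d", rows$mother_id, rows$week)
  rows$is_qc <- FALSE

  if (config$qc_replicates > 0) {
    qc <- rows[rep(1, config$qc_replicates), ]
    qc[] <- lapply(qc, function(col) { col[] <- NA; col })
    qc$sample_id <- sprintf("QC_%02d", seq_len(config$qc_replicates))
    qc$is_qc <- TRUE
    rows <- rbind(rows, qc)
  }
  rownames(rows) <- NULL
  cols <- c("sample_id", "mother_id", "infant_id", "twin_set_id", "milk_id",
            "week", "is_qc", "growth_group", "delta_weight_zscore", "secretor",
            confounder_names())
  meta <- rows[, cols]
  validate_cohort_metadata(meta)
  meta
}

#' Validate cohort metadata
#'
#' Checks identifier uniqueness, the week domain, that QC rows carry no
#' growth group, and that all clinical confounders are present.
#' @param metadata data frame as produced by [generate_cohort()] or read from
#'   `samples.csv`.
#' @return the metadata, invisibly, on success.
#' @export
validate_cohort_metadata <- function(metadata) {
  need <- c("sample_id", "mother_id", "infant_id", "week", "is_qc",
            "growth_group", "delta_weight_zscore", "secretor",
            confounder_names())
  missing_cols <- setdiff(need, names(metadata))
  assert_that(length(missing_cols) == 0,
              paste("metadata is missing columns:",
                    paste(missing_cols, collapse = ", ")))
  assert_that(!anyDuplicated(metadata$sample_id),
              "duplicate sample_id in metadata")
  wk <- metadata$week[!metadata$is_qc]
  assert_that(all(wk %in% 2:4), "weeks must lie in {2, 3, 4}")
  assert_that(all(is.na(metadata$growth_group[metadata$is_qc])),
              "QC rows must not carry a growth group")
  bio <- metadata[!metadata$is_qc, ]
  assert_that(all(bio$growth_group %in% c("faster", "slower")),
              "growth_group must be 'faster' or 'slower'")
  invisible(metadata)
}

# mother-level milk group: +0.5 all-faster, -0.5 all-slower, 0 discordant
milk_group_score <- function(metadata) {
  bio <- metadata[!metadata$is_qc, ]
  tapply(bio$growth_group, bio$mother_id, function(g) {
    g <- unique(g)
    if (length(g) > 1) 0 else if (g == "faster") 0.5 else -0.5
  })
}

make_hmo_codes <- function(p) {
  canonical <- c("2100", "3110a", "3110b", "3210", "3000", "4210b", "4210d",
                 "4230b", "4230c", "4240b", "4220a", "5310a", "3100", "2110",
                 "3120a", "4200", "6430d", "4231a", "3001", "3101a", "4301a",
                 "5320b", "3211a", "3121a", "4311a")
  if (p <= length(canonical)) return(canonical[seq_len(p)])
  grid <- expand.grid(hex = 2:6, fuc = 0:4, hexnac = 0:4, neuac = 0:2)
  grid <- grid[grid$fuc <= grid$hex & grid$hexnac < grid$hex, ]
  codes <- sprintf("%d%d%d%d", grid$hex, grid$fuc, grid$hexnac, grid$neuac)
  codes <- setdiff(unique(codes), substr(canonical, 1, 4))
  extra <- character(0)
  for (letter in c("", "a", "b", "c")) {
    extra <- c(extra, paste0(codes, letter))
    if (length(canonical) + length(extra) >= p) break
  }
  c(canonical, extra[seq_len(p - length(canonical))])
}

hmo_mass <- function(code) {
  comp <- parse_hmo_code(code)
  # reduced-oligosaccharide monoisotopic mass from residue masses
  162.0528 * comp$hex + 146.0579 * comp$fuc + 203.0794 * comp$hexnac +
    291.0954 * comp$neuac + 18.0106 + 2.0157
}

#' Generate omics feature tables for a synthetic cohort
#'
#' Log-normal abundances with feature-specific location/scale (log10 location
#' U(4,7), scale U(0.1,0.5), matching orders-of-magnitude MS peak-area
#' spread), a smooth multiplicative week drift, within-mother week-to-week
#' correlation, group-discriminant features shifted by the configured
#' standardized effect on the log scale, a glycome block whose FUT2-dependent
#' features (2'-FL and an LNFP-I analogue) collapse to near zero for
#' non-secretor mothers, pooled-QC technical replicates with the configured
#' CV, and below-detection zeros at the configured rate. Twins share their
#' mother's milk values.
#'
#' @param metadata output of [generate_cohort()].
#' @param config the same [synthetic_config()].
#' @return list with `tables` (named list of [feature_table()]s) and `truth`
#'   (a `planted_truth` list: per block, planted feature ids and effect signs,
#'   technically unstable feature ids, and FUT2-dependent ids for the
#'   glycome).
#' @export
generate_blocks <- function(metadata, config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_cohort_metadata(metadata)
  set.seed(config$seed + 1L)

  bio <- metadata[!metadata$is_qc, ]
  milk <- unique(bio[, c("milk_id", "mother_id", "week")])
  mothers <- unique(milk$mother_id)
  gscore <- milk_group_score(metadata)
  secretor <- tapply(bio$secretor, bio$mother_id, function(s) s[[1]])

  tables <- list()
  truth <- list()
  for (b in names(config$block_sizes)) {
    p <- as.integer(config$block_sizes[[b]])
    if (b == "glycome") {
      fid <- make_hmo_codes(p)
      fut2 <- intersect(c("2100", "3110a"), fid)
    } else {
      prefix <- c(metabolome_pos = "MP", metabolome_neg = "MN",
                  lipidome = "LP", faa = "AA", fa = "FA")[b]
      if (is.na(prefix)) stop2(sprintf("unknown block name '%s'", b))
      fid <- sprintf("%s%04d", prefix, seq_len(p))
      fut2 <- character(0)
    }

    loc <- stats::runif(p, 4, 7)
    scl <- stats::runif(p, 0.1, 0.5)
    drift <- stats::rnorm(p, 0, 0.04)
    if (length(fut2)) {
      # 2'-FL and LNFP-I are major HMOs (~10% relative abundance each
      # in secretor milk); pin their locations near the top of the range
      loc[match(fut2, fid)] <- c(7.0, 6.7)[seq_along(fut2)]
    }

    n_pl <- as.integer(config$n_planted[b] %||% 0L)
    plantable <- setdiff(seq_len(p), match(fut2, fid))
    planted <- sort(sample(plantable, min(n_pl, length(plantable))))
    sign_pl <- sample(c(-1, 1), length(planted), replace = TRUE)
    n_unst <- round(config$unstable_frac * p)
    stable_always <- union(planted, match(fut2, fid))
    unstable <- sort(sample(setdiff(seq_len(p), stable_always), n_unst))

    zm <- matrix(stats::rnorm(length(mothers) * p), length(mothers), p,
                 dimnames = list(mothers, NULL))
    wc <- config$week_corr
    logval <- matrix(NA_real_, nrow(milk), p,
                     dimnames = list(milk$milk_id, fid))
    for (i in seq_len(nrow(milk))) {
      m <- milk$mother_id[i]
      z <- sqrt(wc) * zm[m, ] + sqrt(1 - wc) * stats::rnorm(p)
      v <- loc + drift * (milk$week[i] - 3) + scl * z
      if (length(planted))
        v[planted] <- v[planted] +
          sign_pl * config$effect_size * scl[planted] * gscore[[m]]
      if (length(fut2) && secretor[[m]] == "non-secretor")
        v[match(fut2, fid)] <- v[match(fut2, fid)] - 2.3
      logval[i, ] <- v
    }

    # pooled-QC technical replicates around the pooled profile
    pooled <- colMeans(logval)
    cv <- rep(config$qc_cv, p)
    cv[unstable] <- stats::runif(length(unstable), 0.4, 0.8)
    sigma <- sqrt(log(1 + cv^2))
    nqc <- config$qc_replicates
    qcval <- matrix(0, nqc, p)
    for (r in seq_len(nqc))
      qcval[r, ] <- 10^pooled * exp(sigma * stats::rnorm(p) - sigma^2 / 2)

    abund <- 10^logval
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(abund)) < config$missing_rate,
                     nrow(abund), ncol(abund))
      abund[mask] <- 0
    }

    values <- matrix(0, nrow(metadata), p,
                     dimnames = list(metadata$sample_id, fid))
    biorows <- !metadata$is_qc
    values[biorows, ] <- abund[metadata$milk_id[biorows], , drop = FALSE]
    if (nqc > 0) values[metadata$is_qc, ] <- qcval

    fmeta <- data.frame(
      feature_id = fid,
      mz = if (b == "glycome") vapply(fid, hmo_mass, numeric(1))
           else stats::runif(p, 80, 1100),
      rt = stats::runif(p, 0.5, 20),
      annotation_level = sample(c("1", "2", "unannotated"), p, replace = TRUE,
                                prob = c(0.25, 0.45, 0.3)),
      hmo_code = if (b == "glycome") fid else NA_character_,
      stringsAsFactors = FALSE)

    tables[[b]] <- feature_table(b, values, fmeta)
    truth[[b]] <- list(planted = fid[planted],
                       sign = stats::setNames(sign_pl, fid[planted]),
                       unstable = fid[unstable],
                       fut2 = fut2)
  }
  class(truth) <- "planted_truth"
  list(tables = tables, truth = truth)
}

#' Materialize a full synthetic study directory
#'
#' Writes `samples.csv`, one `<block>.csv` and `features_<block>.csv` per
#' omics block, and `planted_truth_<block>.csv` ground-truth tables, in the
#' same delimited-text formats the pipeline reads.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list from [generate_blocks()] plus the metadata.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- generate_cohort(config)
  gen <- generate_blocks(meta, config)
  utils::write.csv(meta, file.path(dir, "samples.csv"), row.names = FALSE)
  for (b in names(gen$tables)) {
    write_feature_table(gen$tables[[b]], file.path(dir, paste0(b, ".csv")))
    utils::write.csv(gen$tables[[b]]$feature_meta,
                     file.path(dir, paste0("features_", b, ".csv")),
                     row.names = FALSE)
    tr <- gen$truth[[b]]
    utils::write.csv(
      data.frame(feature_id = tr$planted, sign = unname(tr$sign)),
      file.path(dir, paste0("planted_truth_", b, ".csv")), row.names = FALSE)
  }
  invisible(c(gen, list(metadata = meta)))
}
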