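# End-to-end orchestration: simulate -> load -> QC filter -> scale ->
# AoV-PLS/LDA -> VIP -> Mann-Whitney+FDR -> MLR -> fusion -> report.

#' Pipeline configuration
#'
#' @param out_dir output directory for the study report.
#' @param input_dir directory with `samples.csv` and `<block>.csv` tables;
#'   when NULL a synthetic study is simulated into `out_dir/data`.
#' @param synthetic a [synthetic_config()] used when simulating.
#' @param alpha significance level (default 0.05).
#' @param mw_q_threshold Mann-Whitney q-value threshold (default 0.05).
#' @param mlr_q_threshold MLR reliability q-value threshold (default 0.1).
#' @param vip_threshold VIP selection cutoff (default 1.5).
#' @param rsd_cutoff pooled-QC RSD filter cutoff (default 0.30).
#' @param display_components latent components displayed/reported (default 2).
#' @param max_components largest LDA-fed component count scanned (default 3).
#' @param fusion_week lactation week used for fusion (default 3).
#' @param fusion_components common components of the fusion models (default 2).
#' @param seed integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL,
                            synthetic = synthetic_config(),
                            alpha = 0.05,
                            mw_q_threshold = 0.05,
                            mlr_q_threshold = 0.1,
                            vip_threshold = 1.5,
                            rsd_cutoff = 0.30,
                            display_components = 2L,
                            max_components = 3L,
                            fusion_week = 3L,
                            fusion_components = 2L,
                            seed = 1L) {
  assert_that(mw_q_threshold > 0 && mw_q_threshold <= 1,
              "mw_q_threshold must lie in (0, 1]")
  assert_that(mlr_q_threshold > 0 && mlr_q_threshold <= 1,
              "mlr_q_threshold must lie in (0, 1]")
  assert_that(vip_threshold > 0, "vip_threshold must be positive")
  cfg <- list(out_dir = out_dir, input_dir = input_dir, synthetic = synthetic,
              alpha = alpha, mw_q_threshold = mw_q_threshold,
              mlr_q_threshold = mlr_q_threshold,
              vip_threshold = vip_threshold, rsd_cutoff = rsd_cutoff,
              display_components = as.integer(display_components),
              max_components = as.integer(max_components),
              fusion_week = as.integer(fusion_week),
              fusion_components = as.integer(fusion_components),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

log_pareto_blocks <- function() c("metabolome_pos", "metabolome_neg", "lipidome")

#' Scale one block according to its convention
#'
#' Metabolome/lipidome blocks are log-Pareto scaled (their peak areas span
#' orders of magnitude); the glycome is converted to relative abundances,
#' autoscaled and centered within maternal secretor strata; fatty-acid and
#' free-amino-acid blocks are autoscaled.
#'
#' @param table a filtered [feature_table()].
#' @param metadata cohort metadata (biological samples of the table).
#' @param secretor_status named per-mother status (needed for the glycome).
#' @return list with `x` (scaled matrix, biological samples only), `spec`,
#'   and for the glycome the per-sample `statuses`.
#' @export
scale_block <- function(table, metadata, secretor_status = NULL) {
  bio_ids <- metadata$sample_id[!metadata$is_qc]
  bio_ids <- intersect(sample_ids(table), bio_ids)
  vals <- table$values[bio_ids, , drop = FALSE]
  if (table$block_name %in% log_pareto_blocks()) {
    sc <- suppressWarnings(log_pareto_scale(vals))
    return(list(x = sc$x, spec = sc$spec))
  }
  if (table$block_name == "glycome") {
    rel <- relative_hmo_abundance(
      feature_table(table$block_name, vals, table$feature_meta))
    sc <- suppressWarnings(autoscale(rel$values))
    if (is.null(secretor_status))
      return(list(x = sc$x, spec = sc$spec))
    mo <- metadata$mother_id[match(rownames(sc$x), metadata$sample_id)]
    statuses <- unname(secretor_status[mo])
    return(list(x = suppressWarnings(secretor_stratified_center(sc$x, statuses)),
                spec = sc$spec, statuses = statuses))
  }
  sc <- suppressWarnings(autoscale(vals))
  list(x = sc$x, spec = sc$spec)
}

format_p <- function(p) ifelse(is.na(p), "NA", sprintf("%.4f", p))

#' Week-restricted multi-omics fusion stage
#'
#' Builds the fusion inputs for one lactation week — VIP-selected
#' metabolome (ESI+ and ESI- concatenated) and lipidome features on the raw
#' abundance scale, the full glycome as secretor-centered autoscaled
#' relative abundances, and the full fatty-acid and free-amino-acid blocks —
#' scales them per their block convention, and runs unfold PCA, MB-PLS, and
#' the leave-milk-out fusion error.
#'
#' @param filtered named list of QC-filtered [feature_table()]s (blocks
#'   `metabolome_pos`, `metabolome_neg`, `lipidome`, `glycome`, `faa`, `fa`).
#' @param metadata cohort metadata.
#' @param secretor_status named per-mother status from [classify_secretor()].
#' @param vip_ids named list of VIP-selected feature ids per block (only the
#'   metabolome/lipidome entries are used).
#' @param week lactation week to fuse (default 3).
#' @param n_components common components (default 2).
#' @return list with `samples`, `labels`, `superblock`, `upca`, `mbpls`,
#'   `selection` (top-quartile loadings) and `loo`.
#' @export
run_fusion <- function(filtered, metadata, secretor_status, vip_ids,
                       week = 3, n_components = 2) {
  bio <- metadata[!metadata$is_qc, ]
  w3 <- bio[bio$week == week, ]
  pick <- function(b, ids = NULL) {
    v <- filtered[[b]]$values[w3$sample_id, , drop = FALSE]
    if (!is.null(ids)) v <- v[, ids, drop = FALSE]
    v
  }
  raw_blocks <- list(
    metabolome = cbind(pick("metabolome_pos", vip_ids$metabolome_pos),
                       pick("metabolome_neg", vip_ids$metabolome_neg)),
    lipidome = pick("lipidome", vip_ids$lipidome),
    glycome = pick("glycome"),
    faa = pick("faa"),
    fa = pick("fa"))
  empty <- names(raw_blocks)[vapply(raw_blocks, ncol, integer(1)) == 0]
  if (length(empty)) {
    message(sprintf("fusion: dropping empty block(s): %s",
                    paste(empty, collapse = ", ")))
    raw_blocks <- raw_blocks[setdiff(names(raw_blocks), empty)]
    assert_that(length(raw_blocks) >= 2,
                "fewer than 2 non-empty blocks left for fusion")
  }
  if ("glycome" %in% names(raw_blocks)) {
    glyc_rel <- relative_hmo_abundance(
      feature_table("glycome", raw_blocks$glycome))$values
    glyc_sc <- suppressWarnings(autoscale(glyc_rel))$x
    statuses <- unname(secretor_status[w3$mother_id])
    raw_blocks$glycome <- suppressWarnings(
      secretor_stratified_center(glyc_sc, statuses))
  }
  lp <- function(x) suppressWarnings(log_pareto_scale(x))
  au <- function(x) suppressWarnings(autoscale(x))
  scalers <- lapply(stats::setNames(nm = names(raw_blocks)), function(b)
    if (b %in% c("metabolome", "lipidome")) lp else au)
  scaled_blocks <- lapply(names(raw_blocks), function(b)
    scalers[[b]](raw_blocks[[b]])$x)
  names(scaled_blocks) <- names(raw_blocks)
  sb <- assemble_superblock(scaled_blocks)
  pca <- upca(sb$x, min(4, nrow(sb$x) - 1))
  mb <- fit_mbpls(scaled_blocks, w3$growth_group, n_components)
  sel <- select_by_loadings(mb, components = seq_len(n_components),
                            quantile = 0.25)
  loo <- suppressWarnings(fusion_loo(
    raw_blocks, w3$growth_group, n_components = n_components,
    scalers = scalers, milk_ids = w3$milk_id))
  list(samples = w3$sample_id, labels = w3$growth_group, superblock = sb,
       upca = pca, mbpls = mb, selection = sel, loo = loo)
}

#' Build a result table mirroring the published table conventions
#'
#' Columns: per-group `median (P25-P75)`, Mann-Whitney p and q with
#' significance glyphs (`**` q<0.01, `*` q<0.05, `#` q<0.1 trend), the VIP
#' index with a flag at the selection threshold, and MLR p/q with the
#' reliability glyph `#` (q < 0.1).
#'
#' @param univ data frame from [univariate_screen()].
#' @param mlr data frame from [run_mlr_screen()] (may be NULL).
#' @param vip named VIP vector (may be NULL).
#' @param vip_threshold VIP flag cutoff.
#' @param mlr_q_threshold MLR reliability cutoff.
#' @return data frame ready for `write.csv`; empty input yields a
#'   headers-only table.
#' @export
make_report_table <- function(univ, mlr = NULL, vip = NULL,
                              vip_threshold = 1.5, mlr_q_threshold = 0.1) {
  out <- data.frame(feature_id = univ$feature_id,
                    faster_median = univ$faster,
                    slower_median = univ$slower,
                    mw_p = format_p(univ$p),
                    mw_q = format_p(univ$q),
                    mw_tier = univ$tier,
                    stringsAsFactors = FALSE)
  if (!is.null(vip)) {
    out$vip <- sprintf("%.2f", unname(vip[out$feature_id]))
    out$vip_flag <- ifelse(vip[out$feature_id] >= vip_threshold, "VIP", "")
  }
  if (!is.null(mlr) && nrow(mlr)) {
    idx <- match(out$feature_id, mlr$feature_id)
    out$mlr_p <- format_p(mlr$p[idx])
    out$mlr_q <- format_p(mlr$q[idx])
    out$mlr_flag <- ifelse(!is.na(mlr$q[idx]) & mlr$q[idx] < mlr_q_threshold,
                           "#", "")
  }
  out
}

#' Simulate a study and run the week-restricted fusion chain
#'
#' Convenience wrapper: generates a synthetic study, applies the QC-RSD
#' filter, selects VIP features per metabolome/lipidome block from an
#' AoV-PLS fit, classifies maternal secretor status, and runs [run_fusion()].
#'
#' @param config a [synthetic_config()].
#' @param n_components common components (default 2).
#' @param vip_threshold VIP selection cutoff (default 1.5).
#' @param week lactation week to fuse (default 3).
#' @return the [run_fusion()] result, plus `metadata` and `truth`.
#' @export
run_fusion_study <- function(config, n_components = 2, vip_threshold = 1.5,
                             week = 3) {
  meta <- generate_cohort(config)
  gen <- generate_blocks(meta, config)
  bio <- meta[!meta$is_qc, ]
  filtered <- lapply(gen$tables, function(tab)
    suppressMessages(qc_rsd_filter(tab, meta)))
  vips <- lapply(c(metabolome_pos = "metabolome_pos",
                   metabolome_neg = "metabolome_neg",
                   lipidome = "lipidome"), function(b) {
    x <- suppressWarnings(
      log_pareto_scale(filtered[[b]]$values[bio$sample_id, , drop = FALSE]))$x
    fit <- fit_aov_pls(x, bio$growth_group, 2)
    as.character(select_vip_features(fit, vip_threshold))
  })
  rel <- relative_hmo_abundance(feature_table(
    "glycome", filtered$glycome$values[bio$sample_id, , drop = FALSE]))
  status <- classify_secretor(rel, meta)
  out <- run_fusion(filtered, meta, status, vips, week = week,
                    n_components = n_components)
  out$metadata <- meta
  out$truth <- gen$truth
  out
}

#' Run the full milk-omics analysis pipeline
#'
#' Executes the nine stages (simulate, load, qc_filter, scale, discriminate,
#' univariate, mlr, fuse, report), writing per-block filtered and result
#' tables, discriminant summaries, fusion scores/loadings/selection, and a
#' plain-text run manifest into `config$out_dir`. Any stage failure aborts
#' with the stage name; partial outputs are removed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      unlink(list.files(out, full.names = TRUE), recursive = TRUE)
      stop2(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    stages <<- c(stages, name)
    res
  }

  sim <- run_stage("simulate", function() {
    if (is.null(config$input_dir)) {
      dir <- file.path(out, "data")
      simulate_study(config$synthetic, dir)
      dir
    } else config$input_dir
  })

  loaded <- run_stage("load", function() {
    meta <- utils::read.csv(file.path(sim, "samples.csv"),
                            stringsAsFactors = FALSE)
    validate_cohort_metadata(meta)
    block_files <- list.files(sim, pattern = "^(metabolome_pos|metabolome_neg|lipidome|glycome|faa|fa)\\.csv$")
    tables <- list()
    for (f in block_files) {
      b <- sub("\\.csv$", "", f)
      fm <- file.path(sim, paste0("features_", b, ".csv"))
      tables[[b]] <- suppressMessages(read_feature_table(
        file.path(sim, f), b,
        feature_meta = if (file.exists(fm)) fm else NULL))
    }
    list(metadata = meta, tables = tables)
  })
  meta <- loaded$metadata

  filtered <- run_stage("qc_filter", function() {
    lapply(loaded$tables, function(tab)
      suppressMessages(qc_rsd_filter(tab, meta, cutoff = config$rsd_cutoff)))
  })

  scaled <- run_stage("scale", function() {
    status <- classify_secretor(
      relative_hmo_abundance(
        feature_table("glycome",
                      filtered$glycome$values[meta$sample_id[!meta$is_qc], ,
                                              drop = FALSE],
                      filtered$glycome$feature_meta)),
      meta)
    res <- lapply(filtered, scale_block, metadata = meta,
                  secretor_status = status)
    res$secretor_status <- status
    res
  })

  bio <- meta[!meta$is_qc, ]
  bio <- bio[match(rownames(scaled[[1]]$x), bio$sample_id), ]

  disc <- run_stage("discriminate", function() {
    lapply(names(filtered), function(b) {
      x <- scaled[[b]]$x
      sel <- select_n_components(x, bio$growth_group,
                                 max_components = config$max_components,
                                 scaling = "none", milk_ids = bio$milk_id)
      fit <- fit_aov_pls(x, bio$growth_group, sel$n_components)
      cv <- cv_error_chain(x, bio$growth_group, sel$n_components,
                           scaling = "none", infant_ids = bio$infant_id,
                           milk_ids = bio$milk_id)
      vip_ids <- select_vip_features(fit, config$vip_threshold)
      list(block = b, fit = fit, n_components = sel$n_components,
           cv = cv, vip_ids = vip_ids)
    }) |> stats::setNames(names(filtered))
  })

  univ <- run_stage("univariate", function() {
    lapply(filtered, function(tab) {
      if (tab$block_name == "glycome")
        tab <- relative_hmo_abundance(
          feature_table("glycome",
                        tab$values[bio$sample_id, , drop = FALSE],
                        tab$feature_meta))
      univariate_screen(tab, meta)
    })
  })

  mlr <- run_stage("mlr", function() {
    lapply(names(filtered), function(b) {
      ids <- as.character(disc[[b]]$vip_ids)
      if (length(ids) == 0) {
        message(sprintf("mlr: block '%s' has no VIP candidates; 0 models", b))
        return(suppressWarnings(run_mlr_screen(
          feature_table(b, filtered[[b]]$values[, character(0), drop = FALSE]),
          meta, q_threshold = config$mlr_q_threshold)))
      }
      tab <- feature_table(b, filtered[[b]]$values[, ids, drop = FALSE],
                           filtered[[b]]$feature_meta)
      suppressMessages(run_mlr_screen(tab, meta,
                                      q_threshold = config$mlr_q_threshold))
    }) |> stats::setNames(names(filtered))
  })

  fusion <- run_stage("fuse", function() {
    vips <- lapply(disc, function(d) as.character(d$vip_ids))
    run_fusion(filtered, meta, scaled$secretor_status, vips,
               week = config$fusion_week,
               n_components = config$fusion_components)
  })

  run_stage("report", function() {
    for (b in names(filtered)) {
      write_feature_table(filtered[[b]], file.path(out, paste0("filtered_", b, ".csv")))
      utils::write.csv(
        make_report_table(univ[[b]], mlr[[b]], disc[[b]]$fit$pls$vip,
                          config$vip_threshold, config$mlr_q_threshold),
        file.path(out, paste0("table_", b, ".csv")), row.names = FALSE)
      utils::write.csv(
        data.frame(feature_id = as.character(disc[[b]]$vip_ids),
                   vip = attr(disc[[b]]$vip_ids, "vip")),
        file.path(out, paste0("vip_", b, ".csv")), row.names = FALSE)
    }
    disc_summary <- do.call(rbind, lapply(disc, function(d)
      data.frame(block = d$block, n_components = d$n_components,
                 r2x_cum = sum(d$fit$pls$R2X),
                 r2y_cum = utils::tail(d$fit$pls$R2Ycum, 1),
                 cv_error = d$cv$error,
                 cv_error_infant = d$cv$infant_error,
                 n_vip = length(d$vip_ids))))
    utils::write.csv(disc_summary, file.path(out, "discriminant_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(sample_id = fusion$samples, group = fusion$labels,
                 fusion$mbpls$T),
      file.path(out, "fusion_scores.csv"), row.names = FALSE)
    utils::write.csv(fusion$selection, file.path(out, "fusion_selection.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(block = rownames(fusion$mbpls$block_importance),
                 fusion$mbpls$block_importance),
      file.path(out, "fusion_block_importance.csv"), row.names = FALSE)

    manifest <- c(
      sprintf("lactomics %s", as.character(utils::packageVersion("lactomics"))),
      sprintf("stages: %s", paste(c(stages, "report"), collapse = ", ")),
      sprintf("seed: %d", config$seed),
      sprintf("synthetic seed: %d", config$synthetic$seed),
      sprintf("alpha: %g; MW q: %g; MLR q: %g; VIP: %g; RSD: %g",
              config$alpha, config$mw_q_threshold, config$mlr_q_threshold,
              config$vip_threshold, config$rsd_cutoff),
      sprintf("fusion week: %d; fusion components: %d",
              config$fusion_week, config$fusion_components),
      vapply(names(filtered), function(b)
        sprintf("block %s: %d -> %d features after QC-RSD filter; %d VIP >= %g",
                b, ncol(loaded$tables[[b]]$values), ncol(filtered[[b]]$values),
                length(disc[[b]]$vip_ids), config$vip_threshold),
        character(1)),
      sprintf("fusion LOO error: %.4f", fusion$loo$error))
    writeLines(manifest, file.path(out, "manifest.txt"))
    TRUE
  })

  invisible(list(metadata = meta, tables = loaded$tables, filtered = filtered,
                 scaled = scaled, discriminant = disc, univariate = univ,
                 mlr = mlr, fusion = fusion, stages = c(stages)))
}
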