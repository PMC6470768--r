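# Feature-table container and delimited-text I/O.

#' Construct a feature table (one omics block)
#'
#' Canonical layout is samples in rows, features in columns (the n x p
#' multivariate-model convention). Values are non-negative peak areas in
#' arbitrary units; below-detection measurements are stored as 0.
#'
#' @param block_name block identity (e.g. "metabolome_pos", "glycome").
#' @param values numeric matrix, samples x features, with dimnames.
#' @param feature_meta optional data frame with one row per feature
#'   (`feature_id`, `mz` in Daltons, `rt` in minutes, `annotation_level` in
#'   {1, 2, unannotated}, optional `hmo_code`).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(block_name, values, feature_meta = NULL) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) &&
                (ncol(values) == 0 || !is.null(colnames(values))),
              "values must carry sample and feature identifiers as dimnames")
  assert_that(!anyDuplicated(rownames(values)), "duplicate sample identifiers")
  assert_that(!anyDuplicated(colnames(values)), "duplicate feature identifiers")
  assert_that(all(is.finite(values)), "values must be finite")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop2(sprintf("negative abundance at sample '%s', feature '%s'",
                  rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (!is.null(feature_meta)) {
    assert_that(is.data.frame(feature_meta) && "feature_id" %in% names(feature_meta),
                "feature_meta must be a data frame with a feature_id column")
    feature_meta <- feature_meta[match(colnames(values), feature_meta$feature_id), ,
                                 drop = FALSE]
    rownames(feature_meta) <- NULL
  }
  structure(list(block_name = block_name, values = values,
                 feature_meta = feature_meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table '%s': %d samples x %d features, %.1f%% zeros>\n",
              x$block_name, nrow(x$values), ncol(x$values),
              100 * mean(x$values == 0)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Sample identifiers of a feature table
#' @param x a `feature_table`.
#' @return character vector.
#' @export
sample_ids <- function(x) rownames(x$values)

#' Feature identifiers of a feature table
#' @param x a `feature_table`.
#' @return character vector.
#' @export
feature_ids <- function(x) colnames(x$values)

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

#' Read a feature table from delimited text
#'
#' The delimiter (comma or tab) is auto-detected. Orientation is declared by
#' the header's first cell: `sample_id` means samples in rows (canonical),
#' `feature_id` means features in rows (transposed on load). Duplicate
#' identifiers, negative abundances and non-numeric cells are rejected with
#' an error naming the offending row/column. A short load report (samples,
#' features, zero fraction) is emitted as a message.
#'
#' @param path file path.
#' @param block_name block identity to record.
#' @param feature_meta optional feature metadata data frame (or path to a
#'   `features_<block>.csv` file).
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, block_name, feature_meta = NULL) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  orient <- names(df)[1]
  assert_that(orient %in% c("sample_id", "feature_id"),
              "first header cell must be 'sample_id' or 'feature_id'")
  ids <- df[[1]]
  num <- df[-1]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !(num[[j]] %in% c("NA", "")))
    if (length(bad))
      stop2(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                    num[[j]][bad[1]], ids[bad[1]], names(num)[j]))
    num[[j]] <- v
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orient == "feature_id") m <- t(m)
  if (any(m < 0, na.rm = TRUE)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop2(sprintf("negative abundance at sample '%s', feature '%s'",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  if (is.character(feature_meta))
    feature_meta <- utils::read.csv(feature_meta, stringsAsFactors = FALSE)
  tab <- feature_table(block_name, m, feature_meta)
  message(sprintf("loaded block '%s': %d samples, %d features, %.1f%% zeros",
                  block_name, nrow(m), ncol(m), 100 * mean(m == 0)))
  tab
}

#' Write a feature table to delimited text (canonical orientation)
#' @param table a [feature_table()].
#' @param path output path.
#' @param sep field separator (default comma).
#' @return invisibly, `path`.
#' @export
write_feature_table <- function(table, path, sep = ",") {
  df <- data.frame(sample_id = rownames(table$values),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict blocks to their common samples, in canonical order
#'
#' All tables are subset to the intersection of their sample identifiers
#' (also intersected with non-QC metadata ids when metadata is given) and
#' reordered by a canonical sort on sample_id, so the operation is invariant
#' to input order and idempotent. Dropped samples are reported.
#'
#' @param tables list of [feature_table()]s.
#' @param metadata optional cohort metadata; when given, alignment is
#'   restricted to its sample ids.
#' @return list of aligned feature tables (same names).
#' @export
align_blocks <- function(tables, metadata = NULL) {
  assert_that(length(tables) >= 1, "need at least one table")
  common <- Reduce(intersect, lapply(tables, sample_ids))
  if (!is.null(metadata)) common <- intersect(common, metadata$sample_id)
  assert_that(length(common) > 0, "no samples shared by all blocks")
  common <- sort(common)
  lapply(tables, function(tab) {
    dropped <- setdiff(sample_ids(tab), common)
    if (length(dropped))
      message(sprintf("align_blocks: dropping %d sample(s) from '%s'",
                      length(dropped), tab$block_name))
    feature_table(tab$block_name, tab$values[common, , drop = FALSE],
                  tab$feature_meta)
  })
}
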