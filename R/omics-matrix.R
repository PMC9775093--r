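#' Construct an omics feature matrix
#'
#' An `omics_matrix` holds one omics block as a samples-by-features numeric
#' matrix together with its modality. Methylation blocks carry beta values
#' and must lie in \[0, 1\].
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `rownames(values)`).
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to `colnames(values)`).
#' @param omics_kind Either `"expression"` or `"methylation"`.
#' @return An object of class `omics_matrix`: a list with elements
#'   `values` (dimnamed matrix) and `omics_kind`.
#' @export
omics_matrix <- function(values, sample_ids = rownames(values),
                         feature_ids = colnames(values),
                         omics_kind = c("expression", "methylation")) {
  omics_kind <- match.arg(omics_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop("sample and feature identifiers are required")
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("length of 'sample_ids' does not match nrow(values)")
  }
  if (length(feature_ids) != ncol(values)) {
    stop("length of 'feature_ids' does not match ncol(values)")
  }
  .check_unique(sample_ids, "sample ID")
  .check_unique(feature_ids, "feature ID")
  if (anyNA(values)) {
    stop("omics matrix contains missing values")
  }
  if (omics_kind == "methylation" &&
      (min(values) < 0 || max(values) > 1)) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "methylation beta value outside [0, 1] at sample '%s', feature '%s'",
      sample_ids[bad[1]], feature_ids[bad[2]]))
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, omics_kind = omics_kind),
            class = "omics_matrix")
}

.check_unique <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s: '%s'", what, dup[1]))
  }
  invisible(TRUE)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d samples x %d features\n",
              x$omics_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Sample identifiers of a cohort object
#' @param x An `omics_matrix` or label vector.
#' @return Character vector of sample IDs.
#' @export
sample_ids <- function(x) {
  if (inherits(x, "omics_matrix")) return(rownames(x$values))
  names(x)
}

#' Read an omics feature matrix from TSV/CSV
#'
#' The file must have a header row of feature IDs and a first column of
#' sample IDs (samples in rows). A `transpose` flag accommodates the
#' genes-in-rows dialect. Missing values are an error unless
#' `impute = TRUE`, in which case each missing cell is replaced by its
#' column (feature) mean.
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param omics_kind `"expression"` or `"methylation"`.
#' @param impute Replace missing cells by the feature mean instead of
#'   erroring.
#' @param transpose Set when the file stores features in rows.
#' @return An [omics_matrix].
#' @export
read_omics_matrix <- function(path, omics_kind = c("expression", "methylation"),
                              impute = FALSE, transpose = FALSE) {
  omics_kind <- match.arg(omics_kind)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  row_ids <- raw[[1]]
  feat_ids <- colnames(raw)[-1]
  .check_unique(row_ids, if (transpose) "feature ID" else "sample ID")
  .check_unique(feat_ids, if (transpose) "sample ID" else "feature ID")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  is_missing <- is.na(num) & (is.na(vals) | toupper(trimws(vals)) %in%
                                c("NA", "NAN", ""))
  bad <- which(is.na(num) & !is_missing, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 vals[bad[1, 1], bad[1, 2]], row_ids[bad[1, 1]],
                 feat_ids[bad[1, 2]]))
  }
  if (any(is_missing)) {
    if (!impute) {
      w <- which(is_missing, arr.ind = TRUE)
      stop(sprintf(
        "missing value at row '%s', column '%s' (use impute = TRUE for column-mean imputation)",
        row_ids[w[1, 1]], feat_ids[w[1, 2]]))
    }
    for (j in seq_len(ncol(num))) {
      miss <- is.na(num[, j])
      if (any(miss)) {
        if (all(miss)) stop(sprintf("column '%s' is entirely missing", feat_ids[j]))
        num[miss, j] <- mean(num[!miss, j])
      }
    }
  }
  dimnames(num) <- list(row_ids, feat_ids)
  if (transpose) num <- t(num)
  omics_matrix(num, omics_kind = omics_kind)
}

#' Write an omics matrix as TSV
#' @param x An [omics_matrix].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a binary label vector
#'
#' @param labels Values in \{0, 1\}: 0 = non-cancer, 1 = cancer.
#' @param sample_ids Sample identifiers, same length as `labels`.
#' @return Named integer vector of class `label_vector`.
#' @export
label_vector <- function(labels, sample_ids = names(labels)) {
  if (is.null(sample_ids)) stop("sample identifiers are required")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(labels)) {
    stop("'sample_ids' and 'labels' lengths differ")
  }
  .check_unique(sample_ids, "sample ID")
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 (non-cancer) or 1 (cancer)")
  }
  structure(stats::setNames(labels, sample_ids), class = "label_vector")
}

#' Read labels from a two-column TSV (sample_id, label)
#' @param path File path.
#' @return A [label_vector].
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  label_vector(df[[2]], df[[1]])
}

#' Write labels as a two-column TSV
#' @param labels A [label_vector].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.alteration_levels <- c("SNV", "indel", "fusion", "rearrangement")

#' Construct a variant table
#'
#' Minimal MAF-like table of genomic alterations: one row per
#' (sample, gene, alteration) record; duplicates are allowed since a
#' sample may carry several alterations of one gene.
#'
#' @param sample_id,gene Character vectors.
#' @param alteration One of `"SNV"`, `"indel"`, `"fusion"`,
#'   `"rearrangement"` per record.
#' @param detail Optional free-text detail (e.g. protein change).
#' @return A `data.frame` of class `variant_table`.
#' @export
variant_table <- function(sample_id = character(), gene = character(),
                          alteration = character(), detail = "") {
  df <- data.frame(sample_id = as.character(sample_id),
                   gene = as.character(gene),
                   alteration = as.character(alteration),
                   detail = as.character(detail),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$gene))) stop("variant records require a non-empty gene")
  bad <- setdiff(unique(df$alteration), .alteration_levels)
  if (length(bad) > 0) {
    stop(sprintf("unknown alteration type '%s' (allowed: %s)",
                 bad[1], paste(.alteration_levels, collapse = ", ")))
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read a variant table from a 4-column TSV
#' @param path File path with columns sample_id, gene, alteration, detail.
#' @return A [variant_table].
#' @export
read_variant_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  variant_table(df$sample_id, df$gene, df$alteration,
                if ("detail" %in% names(df)) df$detail else "")
}

#' Construct a therapy rule table
#'
#' Maps (gene, alteration pattern) pairs to anti-cancer agents for the
#' rule-based annotation attached to predictions. `alteration_pattern`
#' is a regular expression matched against the full alteration type
#' (`"."` or `".*"` match any). Pairs must be unique; the table may be
#' empty.
#'
#' @param gene,alteration_pattern,agent Character vectors of equal length.
#' @return A `data.frame` of class `therapy_rule_table`.
#' @export
therapy_rule_table <- function(gene = character(),
                               alteration_pattern = character(),
                               agent = character()) {
  df <- data.frame(gene = as.character(gene),
                   alteration_pattern = as.character(alteration_pattern),
                   agent = as.character(agent), stringsAsFactors = FALSE)
  key <- paste(df$gene, df$alteration_pattern, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate therapy rule for (%s)",
                 sub("\r", ", ", dup[1], fixed = TRUE)))
  }
  class(df) <- c("therapy_rule_table", "data.frame")
  df
}

#' Read therapy rules from a 3-column TSV
#' @param path File path with columns gene, alteration_pattern, agent.
#' @return A [therapy_rule_table].
#' @export
read_therapy_rules <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  therapy_rule_table(df$gene, df$alteration_pattern, df$agent)
}

#' Default therapy rule table
#'
#' A minimal, user-editable starting point pairing well-known actionable
#' NSCLC gene alterations with targeted agents. Edit or replace it with
#' institutional rules via [read_therapy_rules()]; it is annotation-only
#' and never influences classification.
#'
#' @return A [therapy_rule_table].
#' @export
default_therapy_rules <- function() {
  read_therapy_rules(system.file("extdata", "therapy_rules.tsv",
                                 package = "omicsgraphnet", mustWork = TRUE))
}

#' Align omics blocks, labels and variants on shared samples
#'
#' Reorders every omics matrix and the label vector to the intersection
#' of their sample IDs (in the order of the first matrix) and reports
#' the samples dropped from each input. Variants are filtered to the
#' retained cohort.
#'
#' @param matrices List of [omics_matrix] objects (at least one).
#' @param labels A [label_vector].
#' @param variants Optional [variant_table].
#' @return A list of class `cohort` with elements `matrices`, `labels`,
#'   `variants`, and `dropped` (character vector of removed sample IDs).
#' @export
align_cohort <- function(matrices, labels, variants = NULL) {
  if (length(matrices) < 1) stop("at least one omics matrix is required")
  stopifnot(all(vapply(matrices, inherits, TRUE, "omics_matrix")))
  ids <- rownames(matrices[[1]]$values)
  for (m in matrices[-1]) ids <- ids[ids %in% rownames(m$values)]
  ids <- ids[ids %in% names(labels)]
  if (length(ids) == 0) {
    stop("no samples shared by all omics blocks and the labels")
  }
  all_ids <- unique(c(unlist(lapply(matrices, sample_ids)), names(labels)))
  dropped <- setdiff(all_ids, ids)
  matrices <- lapply(matrices, function(m) {
    omics_matrix(m$values[ids, , drop = FALSE], omics_kind = m$omics_kind)
  })
  labels <- label_vector(unclass(labels)[ids], ids)
  if (!is.null(variants)) {
    variants <- variants[variants$sample_id %in% ids, , drop = FALSE]
  }
  structure(list(matrices = matrices, labels = labels,
                 variants = variants, dropped = dropped),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples (%d cancer / %d control), %d omics block(s)\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0),
              length(x$matrices)))
  if (length(x$dropped) > 0) {
    cat(sprintf("  dropped %d unaligned sample(s)\n", length(x$dropped)))
  }
  invisible(x)
}
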