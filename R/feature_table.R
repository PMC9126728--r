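#' LC-MS feature table
#'
#' Container for an untargeted LC-MS intensity matrix: rows are features
#' (identified by an m/z value and a retention time), columns are samples
#' (study subjects or pooled QC injections). Missing intensities are `NA`.
#'
#' @param intensity Numeric matrix, features x samples, `NA` = absent. Row
#'   names must be feature IDs, column names sample IDs.
#' @param features `data.frame` with columns `feature_id`, `mz` (Da),
#'   `rt` (min), one row per intensity-matrix row.
#' @param samples `data.frame` with columns `sample_id`,
#'   `role` (`"subject"` or `"QC"`) and `class` (constitution label for
#'   subjects, `NA` for QC), one row per intensity-matrix column.
#' @param ion_mode `"positive"` or `"negative"`.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensity, features, samples,
                          ion_mode = c("positive", "negative")) {
  ion_mode <- match.arg(ion_mode)
  stopifnot(is.matrix(intensity), is.data.frame(features), is.data.frame(samples))
  .check(all(c("feature_id", "mz", "rt") %in% names(features)),
         "features", "needs columns feature_id, mz, rt")
  .check(all(c("sample_id", "role", "class") %in% names(samples)),
         "samples", "needs columns sample_id, role, class")
  .check(nrow(intensity) == nrow(features), "intensity", "row count != features")
  .check(ncol(intensity) == nrow(samples), "intensity", "column count != samples")
  .check(!anyDuplicated(features$feature_id), "features", "feature IDs must be unique")
  .check(all(samples$role %in% c("subject", "QC")), "samples",
         "role must be 'subject' or 'QC'")
  .check(sum(samples$role == "subject") >= 1, "samples", "needs >=1 subject column")
  .check(all(is.na(intensity) | intensity >= 0), "intensity",
         "intensities must be >= 0 where present")
  rownames(intensity) <- features$feature_id
  colnames(intensity) <- samples$sample_id
  structure(list(intensity = intensity, features = features,
                 samples = samples, ion_mode = ion_mode),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  n_qc <- sum(x$samples$role == "QC")
  cat(sprintf("<feature_table> %s mode: %d features x %d samples (%d subject, %d QC)\n",
              x$ion_mode, nrow(x$intensity), ncol(x$intensity),
              ncol(x$intensity) - n_qc, n_qc))
  cat(sprintf("  missing entries: %d (%.2f%%)\n", sum(is.na(x$intensity)),
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' @rdname feature_table
#' @param x A `feature_table`.
#' @export
n_features <- function(x) nrow(x$intensity)

# intensity submatrices by column role
subject_matrix <- function(x) x$intensity[, x$samples$role == "subject", drop = FALSE]
qc_matrix <- function(x) x$intensity[, x$samples$role == "QC", drop = FALSE]

#' @rdname feature_table
#' @export
subject_classes <- function(x) {
  s <- x$samples[x$samples$role == "subject", ]
  setNames(s$class, s$sample_id)
}

# restrict to a feature subset, preserving table order
ft_subset_features <- function(x, ids) {
  keep <- x$features$feature_id %in% ids
  feature_table(x$intensity[keep, , drop = FALSE],
                x$features[keep, , drop = FALSE],
                x$samples, x$ion_mode)
}

#' Read / write feature tables as delimited text
#'
#' The on-disk format is tab-delimited: the table file has a header row of
#' sample IDs after the three fixed columns `feature_id`, `mz`, `rt`; an empty
#' cell is an absent intensity. The sidecar metadata file has columns
#' `sample_id`, `role`, `class`, `ion_mode`.
#'
#' @param table_path,meta_path Paths of the intensity table and metadata files.
#' @return `read_feature_table()` returns a [feature_table].
#' @export
read_feature_table <- function(table_path, meta_path) {
  tab <- read.delim(table_path, check.names = FALSE, na.strings = c("NA", ""))
  meta <- read.delim(meta_path, na.strings = c("NA", ""))
  .check(identical(names(tab)[1:3], c("feature_id", "mz", "rt")),
         "table", "first three columns must be feature_id, mz, rt")
  ids <- as.character(meta$sample_id)
  mat <- as.matrix(tab[, ids, drop = FALSE])
  mode(mat) <- "double"
  feature_table(mat, tab[, 1:3],
                data.frame(sample_id = ids, role = meta$role,
                           class = meta$class, stringsAsFactors = FALSE),
                ion_mode = unique(meta$ion_mode))
}

#' @rdname read_feature_table
#' @param x A `feature_table` to write.
#' @export
write_feature_table <- function(x, table_path, meta_path) {
  out <- cbind(x$features, as.data.frame(x$intensity, check.names = FALSE))
  write.table(out, table_path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  meta <- cbind(x$samples, ion_mode = x$ion_mode)
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(c(table_path, meta_path))
}
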