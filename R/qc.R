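#' QC instrument-stability check by pairwise Pearson correlation
#'
#' Computes the full pairwise Pearson correlation matrix over the pooled-QC
#' replicate columns (correlating intensity profiles across features).
#' Features with any absent QC value are excluded. The run passes if the
#' minimum off-diagonal r-squared exceeds 0.99, the conventional near-unity
#' stability criterion for pooled QC injections.
#'
#' @param table A [feature_table] with >= 2 QC columns.
#' @param log10_intensities Correlate `log10(x + 1)` instead of raw
#'   intensities (default `FALSE`: raw scale).
#' @return A `qc_report` list: `cor` (symmetric matrix with unit diagonal),
#'   `min_r` (minimum off-diagonal r), `pass` (`min_r^2 > 0.99`),
#'   `n_features_used`.
#' @export
qc_pearson <- function(table, log10_intensities = FALSE) {
  qc <- qc_matrix(table)
  if (ncol(qc) < 2) stop("qc_pearson requires >= 2 QC columns", call. = FALSE)
  qc <- qc[stats::complete.cases(qc), , drop = FALSE]
  if (log10_intensities) qc <- log10(qc + 1)
  cm <- cor(qc)
  off <- cm[row(cm) != col(cm)]
  structure(list(cor = cm, min_r = min(off), pass = min(off)^2 > 0.99,
                 n_features_used = nrow(qc)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d QC columns, %d features used\n",
              ncol(x$cor), x$n_features_used))
  cat(sprintf("  min off-diagonal r = %.5f (r^2 = %.5f) -> %s\n",
              x$min_r, x$min_r^2, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Remove features unstable in the QC replicates
#'
#' Per feature, the coefficient of variation over the QC columns is the
#' sample (n-1) standard deviation divided by the mean of the present values,
#' on the raw intensity scale. Features with CV strictly greater than the
#' threshold are removed (a CV exactly at the threshold is retained), as are
#' features whose QC mean is 0 or with fewer than 2 present QC values (CV
#' undefined). Subject intensities of retained features are untouched.
#'
#' @param table A [feature_table] with >= 2 QC columns.
#' @param threshold CV cutoff as a fraction (default 0.30).
#' @return List: `table` (filtered [feature_table]), `removed` (feature IDs),
#'   `cv` (named per-feature realized CV, `NA` where undefined).
#' @export
cv_filter <- function(table, threshold = 0.30) {
  qc <- qc_matrix(table)
  if (ncol(qc) < 2) stop("cv_filter requires >= 2 QC columns", call. = FALSE)
  n_ok <- rowSums(!is.na(qc))
  m <- rowMeans(qc, na.rm = TRUE)
  s <- apply(qc, 1, sd, na.rm = TRUE)
  cv <- ifelse(n_ok >= 2 & m > 0, s / m, NA_real_)
  names(cv) <- table$features$feature_id
  drop <- is.na(cv) | cv > threshold
  list(table = ft_subset_features(table, names(cv)[!drop]),
       removed = names(cv)[drop],
       cv = cv)
}

# fill NA entries of mat (features x samples) column-class-wise:
# class mean of present values computed on `train_cols`, falling back to the
# train grand mean of the feature, then 0. Columns in `grand_cols` (if any)
# are filled with the train grand mean directly (no class label used).
.impute_by_class <- function(mat, classes, train_cols = seq_len(ncol(mat)),
                             grand_cols = integer(0)) {
  grand <- rowMeans(mat[, train_cols, drop = FALSE], na.rm = TRUE)
  grand[is.nan(grand)] <- 0
  class_cols <- setdiff(seq_len(ncol(mat)), grand_cols)
  for (cls in unique(classes[class_cols])) {
    cols <- class_cols[classes[class_cols] == cls]
    tcols <- intersect(train_cols, which(classes == cls))
    cmean <- if (length(tcols)) rowMeans(mat[, tcols, drop = FALSE], na.rm = TRUE)
             else rep(NaN, nrow(mat))
    cmean[is.nan(cmean)] <- grand[is.nan(cmean)]
    for (j in cols) {
      miss <- is.na(mat[, j])
      mat[miss, j] <- cmean[miss]
    }
  }
  for (j in grand_cols) {
    miss <- is.na(mat[, j])
    mat[miss, j] <- grand[miss]
  }
  mat
}

#' Fill missing intensities with per-class feature means
#'
#' Replaces each absent subject intensity with the mean of the present values
#' of that feature within the sample's constitution class; if a class has no
#' present value for a feature the grand mean of the feature is used, and 0
#' if the feature is absent everywhere. QC columns are untouched.
#'
#' With `scope = "global_by_class"` the fill happens immediately using all
#' subjects (the verbatim pre-modeling procedure). With
#' `scope = "trainfold_by_class"` the table is returned unchanged and marked:
#' filling is deferred to [cross_validate()], which uses training-fold means
#' only, so class information never leaks from test folds.
#'
#' @param table A [feature_table] whose subject columns all carry a class.
#' @param scope Imputation scope (see Details).
#' @return A [feature_table].
#' @export
impute_missing <- function(table,
                           scope = c("global_by_class", "trainfold_by_class")) {
  scope <- match.arg(scope)
  subj <- table$samples$role == "subject"
  if (anyNA(table$samples$class[subj]))
    stop("impute_missing: every subject column must carry a class label",
         call. = FALSE)
  if (scope == "trainfold_by_class") {
    attr(table, "impute_scope") <- scope
    return(table)
  }
  classes <- ifelse(subj, table$samples$class, NA_character_)
  mat <- table$intensity
  mat[, subj] <- .impute_by_class(mat[, subj, drop = FALSE], classes[subj])
  feature_table(mat, table$features, table$samples, table$ion_mode)
}
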