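#' One-vs-reference differential feature screening
#'
#' For every biased constitution, each feature is tested for a location
#' difference against the reference class (Pinghe) with a two-sided
#' two-sample test; absent intensities are excluded observation-wise. The
#' default is a Welch t-test on `log10(x + 1)` at uncorrected `alpha = 0.05`
#' (a Mann–Whitney alternative is provided). A feature is differential for a
#' class iff `p < alpha` (strict).
#'
#' @param table A [feature_table] (typically CV-filtered, not yet imputed).
#' @param reference Reference class, default `"Pinghe"`.
#' @param alpha Significance level (strict `p < alpha`).
#' @param test `"welch"` (log10 Welch t) or `"wilcoxon"` (rank-sum on raw
#'   intensities).
#' @param classes Biased classes to screen; defaults to every non-reference
#'   class present in the table.
#' @return A `differential_result`: list with `sets` (per class, character
#'   vector of differential feature IDs), `p_values` (features x classes
#'   matrix), `alpha`, `test`, `reference`.
#' @export
differential_features <- function(table, reference = "Pinghe", alpha = 0.05,
                                  test = c("welch", "wilcoxon"),
                                  classes = NULL) {
  test <- match.arg(test)
  labels <- subject_classes(table)
  if (is.null(classes)) classes <- setdiff(unique(labels), reference)
  .check(reference %in% labels, "reference", "reference class absent from table")
  for (cl in c(reference, classes))
    if (sum(labels == cl) < 2)
      stop(sprintf("differential_features: class '%s' has < 2 samples", cl),
           call. = FALSE)

  x <- subject_matrix(table)
  ref <- x[, labels == reference, drop = FALSE]
  pmat <- matrix(NA_real_, nrow(x), length(classes),
                 dimnames = list(rownames(x), classes))
  for (cl in classes) {
    grp <- x[, labels == cl, drop = FALSE]
    pmat[, cl] <- if (test == "welch") .welch_p(grp, ref) else .wilcox_p(grp, ref)
  }
  sets <- lapply(setNames(classes, classes), function(cl) {
    p <- pmat[, cl]
    rownames(x)[!is.na(p) & p < alpha]
  })
  structure(list(sets = sets, p_values = pmat, alpha = alpha, test = test,
                 reference = reference),
            class = "differential_result")
}

# vectorized two-sided Welch t on log10(x+1); NA where either group has < 2
# present values or both group variances are 0
.welch_p <- function(a, b) {
  a <- log10(a + 1); b <- log10(b + 1)
  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- rowSums((a - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((b - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * pt(-abs(tt), df)
  p[n1 < 2 | n2 < 2 | se2 == 0] <- NA_real_
  p
}

.wilcox_p <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (all(c(x, y) == c(x, y)[1])) return(NA_real_)
    suppressWarnings(wilcox.test(x, y)$p.value)
  }, numeric(1))
}

#' Common/unique decomposition of differential sets
#'
#' For each biased class `i` with differential set `D_i`, the common part is
#' the overlap with the union of every other class's set,
#' `C_i = D_i` \eqn{\cap \cup_{j \ne i}} `D_j`, and the unique part is
#' `U_i = D_i \ C_i` — the class's m/z signature. The pooled modeling set is
#' the union of all unique parts. Empty sets are allowed throughout.
#'
#' @param differential A `differential_result` from [differential_features()],
#'   or a bare named list of per-class feature-ID sets.
#' @return A `signature_sets` list: `differential`, `common`, `unique` (each
#'   a named per-class list), `pooled` (character vector) and `counts`
#'   (per-class data.frame of set sizes).
#' @export
decompose_signatures <- function(differential) {
  sets <- if (inherits(differential, "differential_result")) differential$sets
          else differential
  .check(length(sets) >= 1 && !is.null(names(sets)), "differential",
         "named per-class sets required")
  classes <- names(sets)
  common <- unique_ <- vector("list", length(classes))
  names(common) <- names(unique_) <- classes
  for (cl in classes) {
    others <- unique(unlist(sets[setdiff(classes, cl)], use.names = FALSE))
    common[[cl]] <- intersect(sets[[cl]], others)
    unique_[[cl]] <- setdiff(sets[[cl]], common[[cl]])
  }
  counts <- data.frame(
    class = classes,
    n_differential = vapply(sets, length, integer(1)),
    n_common = vapply(common, length, integer(1)),
    n_unique = vapply(unique_, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(differential = sets, common = common, unique = unique_,
                 pooled = unique(unlist(unique_, use.names = FALSE)),
                 counts = counts),
            class = "signature_sets")
}

#' @export
print.signature_sets <- function(x, ...) {
  cat("<signature_sets>\n")
  print(x$counts, row.names = FALSE)
  cat(sprintf("  pooled unique features: %d\n", length(x$pooled)))
  invisible(x)
}

#' Restrict a feature table to the pooled unique signature
#'
#' Keeps only the features in the pooled unique set (the union of all
#' per-class unique signatures); all sample columns, including the reference
#' class, are retained so a nine-class model can be trained downstream.
#'
#' @param table A [feature_table].
#' @param sets A `signature_sets` from [decompose_signatures()].
#' @return The projected [feature_table].
#' @export
project_to_signature <- function(table, sets) {
  stopifnot(inherits(sets, "signature_sets"))
  if (length(sets$pooled) == 0)
    stop(paste("project_to_signature: pooled unique signature is empty;",
               "consider a larger alpha or stronger effect sizes"),
         call. = FALSE)
  ft_subset_features(table, sets$pooled)
}

#' Write signature sets as delimited text
#'
#' One row per (class, feature, set) membership with the feature's p-value,
#' plus a per-class count summary file.
#'
#' @param sets A `signature_sets`.
#' @param differential The `differential_result` the sets came from (for
#'   p-values); optional.
#' @param path,counts_path Output file paths (tab-delimited).
#' @export
write_signature_sets <- function(sets, path, counts_path = NULL,
                                 differential = NULL) {
  rows <- do.call(rbind, lapply(names(sets$differential), function(cl) {
    ids <- sets$differential[[cl]]
    if (!length(ids)) return(NULL)
    set <- ifelse(ids %in% sets$unique[[cl]], "unique", "common")
    p <- if (!is.null(differential)) differential$p_values[ids, cl] else NA_real_
    data.frame(class = cl, feature_id = ids, p_value = p,
               set = set, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(class = character(), feature_id = character(),
                       p_value = numeric(), set = character())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(counts_path))
    write.table(sets$counts, counts_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
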