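#' Stratified k-fold plan
#'
#' Splits samples into `k` disjoint test folds covering the cohort, balanced
#' two ways: per-class counts per fold differ by at most one (class-wise
#' seeded shuffle, remainders assigned greedily to the least-loaded folds)
#' and hence overall fold sizes differ by at most one.
#'
#' @param labels Named vector of class labels (names are sample IDs; indices
#'   are used when unnamed).
#' @param k Number of folds (default 10).
#' @param seed RNG seed; the plan is a pure function of it.
#' @return A `fold_plan`: list with `k`, `folds` (list of test-sample ID
#'   vectors) and `seed`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  .check(k >= 2, "k", "must be >= 2")
  ids <- names(labels)
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  tabs <- table(labels)
  small <- names(tabs)[tabs < k]
  if (length(small))
    stop(sprintf("stratified_kfold: class '%s' has %d samples, fewer than k = %d",
                 small[1], tabs[small[1]], k), call. = FALSE)
  set.seed(as.integer(seed))
  folds <- rep(list(character(0)), k)
  load <- integer(k)
  for (cls in names(tabs)) {
    cls_ids <- sample(ids[labels == cls])
    n_c <- length(cls_ids)
    q <- n_c %/% k
    r <- n_c %% k
    sizes <- rep(q, k)
    if (r > 0) {
      extra <- order(load, runif(k))[seq_len(r)]
      sizes[extra] <- sizes[extra] + 1L
    }
    stops <- cumsum(sizes)
    starts <- stops - sizes + 1L
    for (f in seq_len(k))
      if (sizes[f] > 0)
        folds[[f]] <- c(folds[[f]], cls_ids[starts[f]:stops[f]])
    load <- load + sizes
  }
  structure(list(k = k, folds = folds, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Confusion matrix with a fixed class order
#'
#' @param true,predicted Label vectors of equal length.
#' @param classes Class order; defaults to the canonical constitution order
#'   when all labels are constitutions, sorted labels otherwise.
#' @return Integer K x K matrix, rows = true, columns = predicted.
#' @export
confusion_matrix <- function(true, predicted, classes = NULL) {
  if (is.null(classes)) {
    u <- unique(c(as.character(true), as.character(predicted)))
    classes <- if (all(u %in% constitution_types()))
      intersect(constitution_types(), u) else sort(u)
  }
  as.matrix(table(factor(true, levels = classes),
                  factor(predicted, levels = classes)))
}

#' One-vs-rest classification accuracy of a class
#'
#' `(TP + TN) / (P + N)` for a single class against all others pooled: TP is
#' the class's diagonal entry, TN the sum of entries whose true and predicted
#' labels are both another class, and `P + N` the confusion-matrix total.
#'
#' @param confusion K x K confusion matrix (rows true, columns predicted).
#' @param class Class name or index.
#' @return Accuracy in `[0, 1]`.
#' @export
class_accuracy <- function(confusion, class) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  .check(total > 0, "confusion", "must have positive total")
  i <- if (is.character(class)) match(class, rownames(confusion)) else class
  .check(!is.na(i) && i >= 1 && i <= nrow(confusion), "class", "not found")
  tp <- confusion[i, i]
  tn <- sum(confusion[-i, -i, drop = FALSE])
  (tp + tn) / total
}

# micro (plain multiclass) accuracy and mean one-vs-rest accuracy
.micro_accuracy <- function(confusion) sum(diag(confusion)) / sum(confusion)
.macro_ovr_accuracy <- function(confusion)
  mean(vapply(seq_len(nrow(confusion)),
              function(i) class_accuracy(confusion, i), numeric(1)))

#' Cross-validated evaluation of the signature classifier
#'
#' For each fold of the plan: fill missing values (per the imputation scope),
#' fit a forest on the nine training pieces and predict the held-out piece;
#' predictions are pooled into a single confusion matrix. Per-class one-vs-
#' rest accuracies are reported both pooled over folds and as the mean of the
#' per-fold values, and two overall accuracies are reported side by side:
#' micro (correct / total) and the mean of the nine per-class one-vs-rest
#' accuracies.
#'
#' Imputation scopes: `"trainfold_by_class"` (default) fills training rows
#' with training-fold class means and test rows with training-fold grand
#' feature means, so neither test intensities nor test labels inform the
#' fill; `"global_by_class"` fills once up front from the full data set (the
#' verbatim study procedure — class means then leak across folds).
#'
#' With `nested = TRUE` the differential screen and unique-signature
#' decomposition are re-run inside each training fold (pass the CV-filtered,
#' unprojected table); the default mirrors pre-selected signatures.
#'
#' @param table A [feature_table] restricted to the pooled unique signature
#'   (or CV-filtered when `nested = TRUE`).
#' @param config An [rf_config()]; per-fold seeds are derived from its seed.
#' @param plan A [stratified_kfold()] plan.
#' @param imputation_scope See Details.
#' @param nested Re-select signatures within each training fold.
#' @param alpha,test,reference Passed to [differential_features()] when
#'   `nested = TRUE`.
#' @return An `evaluation_report`: `confusion`, `per_class` (TP/TN/FP/FN,
#'   pooled and fold-mean one-vs-rest accuracy), `overall_micro`,
#'   `overall_macro_ovr`, `per_fold`, `predictions`, `k`, `ion_mode`.
#' @export
cross_validate <- function(table, config = rf_config(), plan,
                           imputation_scope = c("trainfold_by_class",
                                                "global_by_class"),
                           nested = FALSE, alpha = 0.05, test = "welch",
                           reference = "Pinghe") {
  imputation_scope <- match.arg(imputation_scope)
  stopifnot(inherits(table, "feature_table"), inherits(plan, "fold_plan"))
  labels <- subject_classes(table)
  classes <- intersect(constitution_types(), unique(labels))
  if (!length(classes) || !all(labels %in% constitution_types()))
    classes <- sort(unique(labels))
  plan_ids <- unlist(plan$folds, use.names = FALSE)
  .check(setequal(plan_ids, names(labels)) &&
           length(plan_ids) == length(labels),
         "plan", "fold plan must cover exactly the table's subjects")

  mat <- subject_matrix(table)
  if (imputation_scope == "global_by_class")
    mat <- .impute_by_class(mat, labels)

  pred_rows <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    test_ids <- plan$folds[[f]]
    train <- which(!colnames(mat) %in% test_ids)
    test_cols <- which(colnames(mat) %in% test_ids)
    fold_mat <- mat
    if (imputation_scope == "trainfold_by_class")
      fold_mat <- .impute_by_class(mat, labels, train_cols = train,
                                   grand_cols = test_cols)
    keep <- rep(TRUE, nrow(fold_mat))
    if (nested) {
      sub <- feature_table(
        fold_mat[, train, drop = FALSE],
        table$features,
        table$samples[match(colnames(fold_mat)[train],
                            table$samples$sample_id), ],
        table$ion_mode)
      sets <- tryCatch(
        decompose_signatures(differential_features(
          sub, reference = reference, alpha = alpha, test = test)),
        error = function(e) stop(sprintf("fold %d: %s", f, conditionMessage(e)),
                                 call. = FALSE))
      if (!length(sets$pooled))
        stop(sprintf("fold %d: nested signature selection produced no features", f),
             call. = FALSE)
      keep <- rownames(fold_mat) %in% sets$pooled
    }
    cfg_f <- config
    cfg_f$seed <- as.integer((config$seed + 7919 * f) %% 2147483647)
    forest <- tryCatch(
      fit_forest(t(fold_mat[keep, train, drop = FALSE]),
                 factor(labels[train], levels = classes), cfg_f),
      error = function(e) stop(sprintf("fold %d: %s", f, conditionMessage(e)),
                               call. = FALSE))
    pred <- predict(forest, t(fold_mat[keep, test_cols, drop = FALSE]))
    pred_rows[[f]] <- data.frame(
      sample_id = colnames(fold_mat)[test_cols],
      true = unname(labels[test_cols]),
      predicted = as.character(pred),
      fold = f, stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, pred_rows)
  confusion <- confusion_matrix(predictions$true, predictions$predicted,
                                classes)

  fold_class_acc <- sapply(seq_len(plan$k), function(f) {
    cf <- confusion_matrix(predictions$true[predictions$fold == f],
                           predictions$predicted[predictions$fold == f],
                           classes)
    vapply(seq_along(classes), function(i) class_accuracy(cf, i), numeric(1))
  })
  per_class <- data.frame(
    class = classes,
    TP = diag(confusion),
    FN = rowSums(confusion) - diag(confusion),
    FP = colSums(confusion) - diag(confusion),
    row.names = NULL, stringsAsFactors = FALSE)
  per_class$TN <- sum(confusion) - per_class$TP - per_class$FN - per_class$FP
  per_class$accuracy <- vapply(seq_along(classes),
                               function(i) class_accuracy(confusion, i),
                               numeric(1))
  per_class$accuracy_fold_mean <- rowMeans(fold_class_acc)

  per_fold <- data.frame(
    fold = seq_len(plan$k),
    n = vapply(plan$folds, length, integer(1)),
    accuracy = vapply(seq_len(plan$k), function(f) {
      d <- predictions[predictions$fold == f, ]
      mean(d$true == d$predicted)
    }, numeric(1)))

  structure(list(confusion = confusion, per_class = per_class,
                 overall_micro = .micro_accuracy(confusion),
                 overall_macro_ovr = .macro_ovr_accuracy(confusion),
                 per_fold = per_fold, predictions = predictions,
                 k = plan$k, ion_mode = table$ion_mode),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s mode, %d-fold CV, %d samples\n",
              x$ion_mode, x$k, sum(x$confusion)))
  cat(sprintf("  overall accuracy: micro %.4f, mean one-vs-rest %.4f\n",
              x$overall_micro, x$overall_macro_ovr))
  print(x$per_class[, c("class", "TP", "FN", "FP", "TN", "accuracy",
                        "accuracy_fold_mean")], row.names = FALSE,
        digits = 4)
  invisible(x)
}
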