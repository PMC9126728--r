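#' Random forest configuration
#'
#' Parameters of the from-scratch random forest: `n_trees` bootstrap
#' training sets are drawn with replacement (each the size of the training
#' set), one CART tree is grown per set with a fresh uniform random subset of
#' `m_features` candidate features at every node (Breiman-style; a per-tree
#' subsampling mode is available), and classification aggregates the trees'
#' votes.
#'
#' @param n_trees Number of trees (default 200).
#' @param m_features Candidate features per split; `NULL` = `floor(sqrt(p))`
#'   resolved at fit time.
#' @param max_depth Maximum tree depth (`Inf` = grow to purity).
#' @param min_samples_leaf Minimum samples per leaf (default 1).
#' @param bootstrap Draw bootstrap samples (default `TRUE`; disabling trains
#'   every tree on the full training set, a testing hook).
#' @param feature_sampling `"per_node"` (default, canonical random forest) or
#'   `"per_tree"` (one feature subset drawn per tree and used at every node).
#' @param seed Integer seed; training is a pure function of it.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 200L, m_features = NULL, max_depth = Inf,
                      min_samples_leaf = 1L, bootstrap = TRUE,
                      feature_sampling = c("per_node", "per_tree"),
                      seed = 1L) {
  feature_sampling <- match.arg(feature_sampling)
  cfg <- list(n_trees = as.integer(n_trees), m_features = m_features,
              max_depth = max_depth,
              min_samples_leaf = as.integer(min_samples_leaf),
              bootstrap = isTRUE(bootstrap),
              feature_sampling = feature_sampling, seed = as.integer(seed))
  .check(cfg$n_trees >= 1, "n_trees", "must be >= 1")
  .check(is.null(m_features) || m_features >= 1, "m_features", "must be >= 1")
  .check(cfg$max_depth >= 1, "max_depth", "must be >= 1")
  .check(cfg$min_samples_leaf >= 1, "min_samples_leaf", "must be >= 1")
  structure(cfg, class = "rf_config")
}

#' Gini impurity of a class-count vector
#'
#' `1 - sum((n_k / N)^2)`, the CART split criterion; 0 for a pure node, at
#' most `1 - 1/K` for `K` classes.
#'
#' @param class_counts Non-negative counts, at least one positive.
#' @return Impurity in `[0, 1 - 1/K]`.
#' @export
#' @examples
#' gini_impurity(c(10, 0, 0)) # 0
#' gini_impurity(c(5, 5))     # 0.5
gini_impurity <- function(class_counts) {
  .check(all(class_counts >= 0), "class_counts", "must be >= 0")
  n <- sum(class_counts)
  .check(n > 0, "class_counts", "must sum to > 0")
  1 - sum((class_counts / n)^2)
}

#' Best CART split of a sample set
#'
#' Exhaustive search over the candidate features and all midpoints between
#' consecutive distinct sorted values, maximizing the weighted Gini impurity
#' decrease. Ties break to the lowest feature (column order), then the lowest
#' threshold. Returns `NULL` when no split strictly decreases impurity.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Class labels (factor or vector), one per row of `x`.
#' @param candidate_features Column names or indices to search; default all.
#' @param min_samples_leaf Minimum samples each child must keep.
#' @return `NULL`, or a list with `feature` (column name or index),
#'   `threshold` (left branch is `x < threshold`) and `decrease`.
#' @export
best_split <- function(x, y, candidate_features = NULL,
                       min_samples_leaf = 1L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < 2) return(NULL)
  cand <- if (is.null(candidate_features)) seq_len(ncol(x))
          else if (is.character(candidate_features))
            match(candidate_features, colnames(x))
          else as.integer(candidate_features)
  .check(!anyNA(cand) && all(cand >= 1 & cand <= ncol(x)),
         "candidate_features", "must index columns of x")
  s <- cpp_best_split(x, as.integer(y) - 1L, as.integer(cand) - 1L,
                      nlevels(y), as.integer(min_samples_leaf))
  if (!s$found) return(NULL)
  f <- s$feature + 1L
  list(feature = if (!is.null(colnames(x))) colnames(x)[f] else f,
       threshold = s$threshold, decrease = s$decrease)
}

#' Fit a random forest
#'
#' @param x Training data: numeric matrix (samples x features, no missing
#'   values) or a [feature_table] (subject columns are used and transposed;
#'   run [impute_missing()] first).
#' @param y Class labels, one per sample; taken from the table's metadata
#'   when `x` is a [feature_table]. When every label is a constitution name
#'   the canonical constitution order (Pinghe first) is used as the class
#'   level order, which is also the vote tie-break order.
#' @param config An [rf_config()].
#' @return An object of class `tcm_forest`.
#' @export
fit_forest <- function(x, y = NULL, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  if (inherits(x, "feature_table")) {
    if (is.null(y)) y <- subject_classes(x)
    x <- t(subject_matrix(x))
  }
  x <- as.matrix(x)
  if (anyNA(x))
    stop("fit_forest: data contain absent values; run impute_missing() first",
         call. = FALSE)
  if (!is.factor(y)) {
    u <- unique(y)
    lev <- if (all(u %in% constitution_types()))
      intersect(constitution_types(), u) else sort(u)
    y <- factor(y, levels = lev)
  }
  .check(nlevels(y) >= 2, "y", "need >= 2 classes")
  stopifnot(nrow(x) == length(y))
  p <- ncol(x)
  mtry <- if (is.null(config$m_features)) max(1L, floor(sqrt(p)))
          else as.integer(config$m_features)
  .check(mtry >= 1 && mtry <= p, "m_features", "must be in 1..p")
  max_depth <- if (is.finite(config$max_depth))
    as.integer(config$max_depth) else -1L
  set.seed(config$seed)
  trees <- cpp_fit_forest(x, as.integer(y) - 1L, nlevels(y), config$n_trees,
                          mtry, max_depth, config$min_samples_leaf,
                          config$bootstrap,
                          config$feature_sampling == "per_tree")
  structure(list(trees = trees, classes = levels(y), config = config,
                 m_features = mtry, n_train = nrow(x),
                 feature_names = colnames(x)),
            class = "tcm_forest")
}

#' @export
print.tcm_forest <- function(x, ...) {
  cat(sprintf("<tcm_forest> %d trees, %d classes, %d features (mtry %d), seed %d\n",
              length(x$trees), length(x$classes),
              length(x$feature_names), x$m_features, x$config$seed))
  invisible(x)
}

#' Predict constitution classes with a fitted forest
#'
#' Each tree votes its leaf's majority class; the forest returns the modal
#' vote, with ties broken by the fixed class order (Pinghe first, then the
#' eight biased types).
#'
#' @param object A `tcm_forest`.
#' @param newdata Numeric matrix (samples x features) or [feature_table]
#'   covering the forest's feature space.
#' @param type `"class"` (default) or `"votes"` (per-class vote counts).
#' @param ... Unused.
#' @return Factor of predicted classes, or an integer vote matrix.
#' @export
predict.tcm_forest <- function(object, newdata, type = c("class", "votes"),
                               ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_table")) newdata <- t(subject_matrix(newdata))
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    if (!all(object$feature_names %in% colnames(newdata)))
      stop("predict: newdata is missing forest features", call. = FALSE)
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (ncol(newdata) < length(object$feature_names)) {
    stop("predict: newdata has too few features", call. = FALSE)
  }
  if (anyNA(newdata))
    stop("predict: newdata contains absent values; impute first", call. = FALSE)
  votes <- cpp_predict_votes(object$trees, newdata, length(object$classes))
  colnames(votes) <- object$classes
  rownames(votes) <- rownames(newdata)
  if (type == "votes") return(votes)
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' Serialize a forest to structured text and back
#'
#' JSON with one record per tree holding the per-node split records (feature
#' index, threshold, children, leaf class counts) and the bootstrap indices,
#' plus the class order, feature names and configuration.
#'
#' @param forest A `tcm_forest`.
#' @param path Output file.
#' @export
write_forest <- function(forest, path) {
  payload <- list(
    classes = forest$classes,
    feature_names = forest$feature_names,
    m_features = forest$m_features,
    n_train = forest$n_train,
    config = unclass(forest$config),
    trees = lapply(forest$trees, function(tr)
      list(feature = tr$feature, threshold = tr$threshold, left = tr$left,
           right = tr$right, counts = tr$counts, bootstrap = tr$bootstrap)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_forest
#' @return `read_forest()` returns the reconstructed `tcm_forest`.
#' @export
read_forest <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  cfg <- p$config
  config <- rf_config(n_trees = cfg$n_trees, m_features = cfg$m_features,
                      max_depth = if (is.null(cfg$max_depth) ||
                                      !is.finite(cfg$max_depth)) Inf
                                  else cfg$max_depth,
                      min_samples_leaf = cfg$min_samples_leaf,
                      bootstrap = cfg$bootstrap,
                      feature_sampling = cfg$feature_sampling,
                      seed = cfg$seed)
  trees <- if (is.data.frame(p$trees))
    lapply(seq_len(nrow(p$trees)), function(i) as.list(p$trees[i, ]))
  else p$trees
  trees <- lapply(trees, function(tr) {
    counts <- tr$counts
    if (is.list(counts)) counts <- do.call(rbind, counts)
    if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
    list(feature = as.integer(unlist(tr$feature)),
         threshold = as.numeric(unlist(tr$threshold)),
         left = as.integer(unlist(tr$left)),
         right = as.integer(unlist(tr$right)),
         counts = matrix(as.integer(counts), nrow = nrow(counts)),
         bootstrap = as.integer(unlist(tr$bootstrap)))
  })
  structure(list(trees = trees, classes = p$classes, config = config,
                 m_features = p$m_features, n_train = p$n_train,
                 feature_names = p$feature_names),
            class = "tcm_forest")
}
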