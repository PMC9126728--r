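test_that("gini_impurity follows the CART formula", {
  expect_equal(gini_impurity(c(10, 0, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(2, 1, 1)), 0.625)
  expect_error(gini_impurity(c(0, 0)), "sum")
  expect_error(gini_impurity(c(-1, 2)), ">= 0")
})

test_that("best_split enumerates midpoints with deterministic tie-breaks", {
  x <- matrix(c(1, 2, 9, 10), ncol = 1, dimnames = list(NULL, "f1"))
  s <- best_split(x, c("A", "A", "B", "B"))
  expect_identical(s$feature, "f1")
  expect_equal(s$threshold, 5.5)
  expect_equal(s$decrease, 0.5)

  # pure labels or constant features: no split
  expect_null(best_split(x, c("A", "A", "A", "A")))
  expect_null(best_split(matrix(rep(3, 4), ncol = 1), c("A", "A", "B", "B")))

  # duplicated column: tie resolves to the lower feature index
  x2 <- cbind(a = x[, 1], b = x[, 1])
  expect_identical(best_split(x2, c("A", "A", "B", "B"))$feature, "a")
})

test_that("best_split agrees with the exhaustive R oracle on random instances", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(4:14, 1); p <- sample(1:3, 1); K <- sample(2:3, 1)
    x <- matrix(round(rnorm(n * p), 2), n)
    y <- factor(sample(LETTERS[1:K], n, replace = TRUE))
    got <- best_split(x, y)
    fit <- oracle_cart(x, y)
    if (is.null(got)) {
      expect_true(is.na(fit$tree$feature))
    } else {
      expect_identical(as.integer(got$feature), fit$tree$feature)
      expect_equal(got$threshold, fit$tree$threshold)
    }
  }
})

test_that("a single full-feature unbagged tree reproduces the CART oracle", {
  set.seed(66)
  for (i in 1:15) {
    n <- sample(8:30, 1); p <- sample(2:5, 1); K <- sample(2:4, 1)
    x <- matrix(round(rnorm(n * p), 1), n, dimnames = list(NULL, paste0("f", 1:p)))
    y <- factor(sample(LETTERS[1:K], n, replace = TRUE))
    fo <- fit_forest(x, y, rf_config(n_trees = 1, m_features = p,
                                     bootstrap = FALSE, seed = i))
    oc <- oracle_cart(x, y)
    newx <- matrix(round(rnorm(12 * p), 1), 12, dimnames = list(NULL, paste0("f", 1:p)))
    expect_identical(as.character(predict(fo, x)), oracle_cart_predict(oc, x))
    expect_identical(as.character(predict(fo, newx)), oracle_cart_predict(oc, newx))
  }
})

test_that("training is deterministic and separable data reach accuracy 1", {
  set.seed(3)
  x <- rbind(matrix(rnorm(20 * 4, 0), 20), matrix(rnorm(20 * 4, 5), 20))
  colnames(x) <- paste0("f", 1:4)
  y <- rep(c("A", "B"), each = 20)
  fa <- fit_forest(x, y, rf_config(n_trees = 30, seed = 12))
  fb <- fit_forest(x, y, rf_config(n_trees = 30, seed = 12))
  expect_identical(fa$trees, fb$trees)
  expect_equal(mean(predict(fa, x) == y), 1)

  xna <- x; xna[1, 1] <- NA
  expect_error(fit_forest(xna, y), "impute_missing")
})

test_that("votes aggregate by majority with the fixed class-order tie rule", {
  leaf <- function(counts) list(feature = -1L, threshold = NA_real_,
                                left = -1L, right = -1L,
                                counts = matrix(as.integer(counts), 1),
                                bootstrap = 0L)
  mkforest <- function(trees, classes)
    structure(list(trees = trees, classes = classes, config = rf_config(),
                   m_features = 1L, n_train = 1L, feature_names = "f1"),
              class = "tcm_forest")
  x <- matrix(0, 1, 1, dimnames = list(NULL, "f1"))

  # votes (A, A, B) -> A
  fo <- mkforest(list(leaf(c(1, 0)), leaf(c(1, 0)), leaf(c(0, 1))), c("A", "B"))
  expect_identical(as.character(predict(fo, x)), "A")
  # tie (A, B) -> first class in order
  fo <- mkforest(list(leaf(c(1, 0)), leaf(c(0, 1))), c("A", "B"))
  expect_identical(as.character(predict(fo, x)), "A")
  # leaf-internal tie also resolves to the lowest class index
  fo <- mkforest(list(leaf(c(2, 2))), c("A", "B"))
  expect_identical(as.character(predict(fo, x)), "A")

  # a stump built from the hand example routes value 2 to the A leaf
  xs <- matrix(c(1, 2, 9, 10), ncol = 1, dimnames = list(NULL, "f1"))
  fo <- fit_forest(xs, c("A", "A", "B", "B"),
                   rf_config(n_trees = 1, m_features = 1, bootstrap = FALSE))
  expect_identical(as.character(predict(fo, matrix(2, 1, 1,
                                                   dimnames = list(NULL, "f1")))),
                   "A")
})

test_that("bootstrap bookkeeping: root counts cover N and OOB samples exist", {
  set.seed(9)
  n <- 100L
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("f", 1:3)))
  y <- sample(c("A", "B", "C"), n, replace = TRUE)
  fo <- fit_forest(x, y, rf_config(n_trees = 40, seed = 5))
  oob <- vapply(fo$trees, function(tr) {
    expect_identical(sum(tr$counts[1, ]), n)          # root = bootstrap size
    expect_length(tr$bootstrap, n)
    1 - length(unique(tr$bootstrap)) / n
  }, numeric(1))
  expect_gt(mean(oob), 0.25)                          # ~ e^-1 left out
})

test_that("accuracy is non-decreasing in forest size on held-out data", {
  set.seed(14)
  n <- 120
  x <- rbind(matrix(rnorm(n * 5, 0, 1.4), n),
             matrix(rnorm(n * 5, 1, 1.4), n))
  colnames(x) <- paste0("f", 1:5)
  y <- rep(c("A", "B"), each = n)
  tr_idx <- c(1:60, n + 1:60)
  acc <- vapply(c(1, 10, 50, 150), function(nt) {
    fo <- fit_forest(x[tr_idx, ], y[tr_idx], rf_config(n_trees = nt, seed = 77))
    mean(predict(fo, x[-tr_idx, ]) == y[-tr_idx])
  }, numeric(1))
  expect_true(all(diff(acc) >= -0.05))                # monotone within noise
  expect_gt(acc[4], acc[1] - 0.05)
})

test_that("per-tree feature sampling mode trains deterministically", {
  set.seed(31)
  x <- matrix(rnorm(40 * 6), 40, dimnames = list(NULL, paste0("f", 1:6)))
  y <- sample(c("A", "B"), 40, replace = TRUE)
  fa <- fit_forest(x, y, rf_config(n_trees = 10, m_features = 2,
                                   feature_sampling = "per_tree", seed = 4))
  fb <- fit_forest(x, y, rf_config(n_trees = 10, m_features = 2,
                                   feature_sampling = "per_tree", seed = 4))
  expect_identical(fa$trees, fb$trees)
  # each tree restricted to <= 2 distinct split features
  for (tr in fa$trees)
    expect_lte(length(unique(tr$feature[tr$feature >= 0])), 2)
})

test_that("forests round-trip through the text serialization", {
  set.seed(8)
  x <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("f", 1:4)))
  y <- sample(c("Pinghe", "Qixu", "Qiyu"), 30, replace = TRUE)
  fo <- fit_forest(x, y, rf_config(n_trees = 7, seed = 2))
  path <- tempfile(fileext = ".json")
  write_forest(fo, path)
  back <- read_forest(path)
  expect_identical(back$classes, fo$classes)
  expect_identical(back$feature_names, fo$feature_names)
  expect_identical(predict(back, x), predict(fo, x))
  expect_identical(predict(back, x, type = "votes"),
                   predict(fo, x, type = "votes"))
})
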