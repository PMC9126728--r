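test_that("stratified folds are balanced per class and overall", {
  labels <- setNames(rep(constitution_types(), each = 49),
                     sprintf("s%03d", 1:441))
  plan <- stratified_kfold(labels, 10, seed = 3)
  sizes <- lengths(plan$folds)
  expect_setequal(sizes, c(44, 45))                 # 441 = 9*44 + 45
  expect_identical(sort(unlist(plan$folds)), sort(names(labels)))
  for (f in plan$folds) {
    per_class <- table(labels[f])
    expect_lte(max(per_class) - min(per_class), 1)
  }
  expect_identical(plan, stratified_kfold(labels, 10, seed = 3))
  expect_false(identical(plan$folds,
                         stratified_kfold(labels, 10, seed = 4)$folds))
})

test_that("folds error when a class is smaller than k, and allow n = k", {
  labels <- setNames(rep(constitution_types(), each = 10), sprintf("t%02d", 1:90))
  plan <- stratified_kfold(labels, 10, seed = 1)
  for (f in plan$folds)
    expect_identical(as.vector(table(labels[f])), rep(1L, 9))
  short <- labels[1:85]                              # last class has 5 < 10
  expect_error(stratified_kfold(short, 10), "Tebing")
})

test_that("class_accuracy implements one-vs-rest (TP+TN)/(P+N)", {
  perfect <- diag(5) * 10
  dimnames(perfect) <- list(LETTERS[1:5], LETTERS[1:5])
  for (cl in LETTERS[1:5]) expect_equal(class_accuracy(perfect, cl), 1)

  conf <- matrix(c(3, 1, 2, 4), 2, byrow = TRUE,
                 dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(class_accuracy(conf, "x"), 0.7)

  # constructed 9x49 cohort: every class TP=45, 4 errors to the next class
  conf9 <- diag(rep(45L, 9))
  for (i in 1:9) conf9[i, i %% 9 + 1] <- conf9[i, i %% 9 + 1] + 4L
  dimnames(conf9) <- list(constitution_types(), constitution_types())
  expect_equal(sum(conf9), 441)
  expect_equal(class_accuracy(conf9, "Pinghe"), (45 + 388) / 441)
})

test_that("class_accuracy matches direct counting over random outcomes", {
  set.seed(19)
  for (i in 1:40) {
    K <- sample(3:6, 1); n <- sample(20:80, 1)
    cls <- LETTERS[1:K]
    true <- sample(cls, n, replace = TRUE)
    pred <- sample(cls, n, replace = TRUE)
    conf <- confusion_matrix(true, pred, cls)
    pick <- sample(cls, 1)
    expect_equal(class_accuracy(conf, pick),
                 oracle_class_accuracy(true, pred, pick))
  }
})

test_that("mean one-vs-rest accuracy dominates micro accuracy for K > 2", {
  set.seed(29)
  for (i in 1:50) {
    K <- sample(3:9, 1)
    conf <- matrix(rpois(K * K, 3), K)
    if (sum(conf) == 0) conf[1, 1] <- 1
    micro <- sum(diag(conf)) / sum(conf)
    macro <- mean(vapply(seq_len(K), function(j) class_accuracy(conf, j),
                         numeric(1)))
    expect_gte(macro + 1e-12, micro)
  }
})

make_cv_cohort <- function(seed, n_per_class = 10, n_features = 60,
                           effect_size = 1.5, missing_rate = 0.05) {
  cfg <- synth_config(n_per_class = n_per_class, n_features = n_features,
                      n_unique_per_class = setNames(rep(4L, 8), biased_types()),
                      n_shared = 8, effect_size = effect_size,
                      missing_rate = missing_rate, seed = seed)
  co <- generate_cohort(cfg)
  s <- decompose_signatures(differential_features(co$table))
  list(proj = project_to_signature(co$table, s), labels = co$labels)
}

test_that("cross_validate pools each subject exactly once and reproduces", {
  cc <- make_cv_cohort(seed = 61)
  plan <- stratified_kfold(cc$labels, 5, seed = 61)
  rfc <- rf_config(n_trees = 25, seed = 61)
  rep1 <- cross_validate(cc$proj, rfc, plan)
  rep2 <- cross_validate(cc$proj, rfc, plan)
  expect_identical(rep1$confusion, rep2$confusion)
  expect_identical(rep1$per_class, rep2$per_class)

  expect_equal(sum(rep1$confusion), length(cc$labels))
  expect_identical(sort(rep1$predictions$sample_id), sort(names(cc$labels)))
  expect_identical(rownames(rep1$confusion), constitution_types())
  with(rep1$per_class, expect_true(all(TP + TN + FP + FN == 90)))
  expect_equal(rep1$overall_micro, mean(rep1$predictions$true ==
                                          rep1$predictions$predicted))
})

test_that("strongly separated classes cross-validate almost perfectly", {
  cc <- make_cv_cohort(seed = 71, effect_size = 3, missing_rate = 0)
  plan <- stratified_kfold(cc$labels, 5, seed = 71)
  rep <- cross_validate(cc$proj, rf_config(n_trees = 60, seed = 71), plan)
  expect_true(all(rep$per_class$accuracy > 0.95))
})

test_that("global per-class imputation leaks: accuracy >= deferred fill on average", {
  accs <- vapply(1:12, function(seed) {
    cfg <- synth_config(n_per_class = 8, n_features = 40,
                        n_unique_per_class = setNames(rep(3L, 8), biased_types()),
                        n_shared = 5, effect_size = 0.6, missing_rate = 0.35,
                        seed = 100 + seed)
    co <- generate_cohort(cfg)
    s <- decompose_signatures(differential_features(co$table))
    proj <- project_to_signature(co$table, s)
    plan <- stratified_kfold(co$labels, 4, seed = seed)
    rfc <- rf_config(n_trees = 20, seed = seed)
    c(global = cross_validate(proj, rfc, plan,
                              imputation_scope = "global_by_class")$overall_micro,
      fold = cross_validate(proj, rfc, plan,
                            imputation_scope = "trainfold_by_class")$overall_micro)
  }, numeric(2))
  expect_gte(mean(accs["global", ]) - mean(accs["fold", ]), 0)
})

test_that("nested signature re-selection runs inside training folds", {
  cfg <- synth_config(n_per_class = 10, n_features = 60,
                      n_unique_per_class = setNames(rep(5L, 8), biased_types()),
                      n_shared = 5, effect_size = 2, missing_rate = 0, seed = 55)
  co <- generate_cohort(cfg)
  filt <- co$table                       # unprojected table goes in
  plan <- stratified_kfold(co$labels, 5, seed = 55)
  rep <- cross_validate(filt, rf_config(n_trees = 20, seed = 55), plan,
                        nested = TRUE, alpha = 0.05)
  expect_equal(sum(rep$confusion), 90)
  expect_gt(rep$overall_micro, 0.5)
})
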