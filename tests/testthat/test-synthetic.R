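test_that("cohort generation is a pure function of the seed", {
  cfg <- tiny_config(seed = 7)
  a <- generate_qc_replicates(cfg, generate_cohort(cfg))
  b <- generate_qc_replicates(cfg, generate_cohort(cfg))
  expect_identical(a$table$intensity, b$table$intensity)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(tiny_config(seed = 8))
  expect_false(identical(a$table$intensity[, 1:90], c2$table$intensity))
})

test_that("the study-scale design yields 9 x 49 = 441 subject columns", {
  cfg <- synth_config(n_per_class = 49, n_features = 150,
                      n_unique_per_class = setNames(rep(5L, 8), biased_types()),
                      n_shared = 10, seed = 1)
  co <- generate_cohort(cfg)
  expect_identical(ncol(co$table$intensity), 441L)
  expect_identical(unname(table(co$labels))[1], 49L)
  expect_setequal(unique(co$labels), constitution_types())
})

test_that("planted unique sets are pairwise disjoint and avoid the shared set", {
  for (seed in 1:8) {
    n_uni <- setNames(sample(0:6, 8, replace = TRUE), biased_types())
    cfg <- synth_config(n_per_class = 4, n_features = 80,
                        n_unique_per_class = n_uni,
                        n_shared = sample(0:10, 1), seed = seed)
    tr <- generate_cohort(cfg)$truth
    all_u <- unlist(tr$planted_unique, use.names = FALSE)
    expect_identical(anyDuplicated(all_u), 0L)
    expect_length(intersect(all_u, tr$planted_shared), 0)
    expect_identical(lengths(tr$planted_unique)[biased_types()],
                     setNames(sapply(n_uni, as.integer), biased_types()))
  }
})

test_that("planted features shift log2 class means by the configured effect", {
  cfg <- synth_config(n_per_class = 49, n_features = 300,
                      n_unique_per_class = setNames(rep(15L, 8), biased_types()),
                      n_shared = 0, effect_size = 1, missing_rate = 0, seed = 3)
  co <- generate_cohort(cfg)
  x <- log2(co$table$intensity)
  for (cls in c("Qixu", "Tebing")) {
    ids <- co$truth$planted_unique[[cls]]
    d <- rowMeans(x[ids, co$labels == cls]) -
         rowMeans(x[ids, co$labels == "Pinghe"])
    se <- sd(abs(d)) / sqrt(length(d))
    expect_lt(abs(mean(abs(d)) - cfg$effect_size), 3 * se)
    # unplanted features: no shift beyond noise
    other <- setdiff(rownames(x), unlist(co$truth$planted_unique))[1:50]
    d0 <- rowMeans(x[other, co$labels == cls]) -
          rowMeans(x[other, co$labels == "Pinghe"])
    expect_lt(abs(mean(d0)), 3 * sd(d0) / sqrt(length(d0)))
  }
})

test_that("missingness honours missing_rate", {
  co0 <- generate_cohort(tiny_config(seed = 5, missing_rate = 0))
  expect_false(anyNA(co0$table$intensity))
  cfg <- tiny_config(seed = 5, n_features = 400, missing_rate = 0.2)
  co <- generate_cohort(cfg)
  frac <- mean(is.na(co$table$intensity))
  n_cells <- length(co$table$intensity)
  expect_lt(abs(frac - 0.2), 4 * sqrt(0.2 * 0.8 / n_cells))
})

test_that("a null configuration produces ~alpha false positives downstream", {
  cfg <- synth_config(n_per_class = 25, n_features = 200,
                      n_unique_per_class = setNames(rep(0L, 8), biased_types()),
                      n_shared = 0, effect_size = 0, missing_rate = 0, seed = 21)
  co <- generate_cohort(cfg)
  d <- differential_features(co$table, alpha = 0.05)
  n_tests <- 8 * 200
  fp <- sum(lengths(d$sets))
  # binomial oracle on the pooled count (tests correlated via the shared
  # reference, so allow a wide band around the expectation)
  expect_lt(abs(fp - 0.05 * n_tests), 6 * sqrt(n_tests * 0.05 * 0.95))
})

test_that("QC replicates match their configuration", {
  cfg <- tiny_config(seed = 2, qc_n = 6)
  co <- generate_qc_replicates(cfg, generate_cohort(cfg))
  expect_identical(sum(co$table$samples$role == "QC"), 6L)
  expect_error(generate_qc_replicates(tiny_config(qc_n = 1), co),
               "qc_n")

  # zero-CV QC: identical replicate columns, perfect correlation
  cfg0 <- tiny_config(seed = 2, qc_cv_low = 0, qc_cv_high = 0,
                      qc_frac_unstable = 0)
  co0 <- generate_qc_replicates(cfg0, generate_cohort(cfg0))
  qc <- co0$table$intensity[, co0$table$samples$role == "QC"]
  expect_true(all(qc == qc[, 1]))
  expect_equal(qc_pearson(co0$table)$min_r, 1)
})

test_that("the unstable fraction controls how many realized QC CVs exceed 0.30", {
  cfg <- synth_config(n_per_class = 5, n_features = 1000,
                      n_unique_per_class = setNames(rep(0L, 8), biased_types()),
                      n_shared = 0, qc_frac_unstable = 0.1, missing_rate = 0,
                      seed = 13)
  co <- generate_qc_replicates(cfg, generate_cohort(cfg))
  expect_length(co$truth$unstable_qc_features, 100)
  qc <- co$table$intensity[, co$table$samples$role == "QC"]
  realized <- apply(qc, 1, sd) / rowMeans(qc)   # direct sd/mean oracle
  n_over <- sum(realized > 0.30)
  # realized CVs at n=6 are noisy around their targets; the crossing count
  # stays centred on the planted 100 but with inflated variance
  expect_gt(n_over, 55)
  expect_lt(n_over, 145)
})

test_that("configuration invariants are enforced with the field named", {
  expect_error(tiny_config(n_per_class = 0), "n_per_class")
  expect_error(tiny_config(missing_rate = 1), "missing_rate")
  expect_error(synth_config(n_features = 10,
                            n_unique_per_class = setNames(rep(5L, 8),
                                                          biased_types()),
                            n_shared = 0), "n_features")
  expect_error(tiny_config(qc_frac_unstable = 0.2, qc_cv_high = 0.25),
               "qc_cv_high")
  bad <- setNames(rep(3L, 8), c(biased_types()[-1], "NotAClass"))
  expect_error(synth_config(n_unique_per_class = bad), "n_unique_per_class")
})
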