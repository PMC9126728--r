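#' Synthetic cohort configuration
#'
#' Parameters of the seeded generator that emulates the study design the
#' package analyses: nine constitution classes (Pinghe as reference) of equal
#' size, an untargeted LC-MS feature table with lognormal intensities, a set
#' of planted differential features per biased class (some unique to one
#' class, some shared by several), pooled-QC replicate injections with
#' controlled per-feature CV, and completely-at-random missing intensities.
#'
#' Differential shifts are applied on the log scale: a feature planted for
#' class `c` has its class-`c` mean multiplied by `2^effect_size` (direction
#' randomized per feature/class). The reference class is never shifted.
#'
#' @param n_per_class Subjects per constitution (default 49, the study scale).
#' @param n_features Number of LC-MS features (default 2000).
#' @param n_unique_per_class Named integer vector over the eight biased
#'   classes: number of features differential ONLY in that class. Entries may
#'   be 0. Default 30 each.
#' @param n_shared Number of features differential in >= 2 biased classes.
#' @param shared_weights Optional named per-class inclusion probabilities for
#'   shared features; `NULL` = uniform membership of random size 2..8.
#' @param effect_size Planted log2 fold change (default 1).
#' @param base_log_mean,base_log_sd Natural-log mean/sd of per-feature
#'   baseline intensities (lognormal across features).
#' @param within_class_cv Biological coefficient of variation of replicate
#'   subjects within a class (default 0.30).
#' @param qc_n Number of pooled-QC replicate injections (default 6).
#' @param qc_cv_low,qc_cv_high Range of per-feature QC CVs; features flagged
#'   unstable draw their target CV from (0.30, `qc_cv_high`].
#' @param qc_frac_unstable Fraction of features given target QC CV > 0.30.
#' @param missing_rate Probability a subject intensity is absent (MCAR).
#' @param seed Integer RNG seed; generation is a pure function of it.
#' @param ion_mode Label for the generated table.
#' @param reference_class Reference constitution (default `"Pinghe"`).
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 49L,
                         n_features = 2000L,
                         n_unique_per_class = setNames(rep(30L, 8), biased_types()),
                         n_shared = 100L,
                         shared_weights = NULL,
                         effect_size = 1.0,
                         base_log_mean = log(1e5),
                         base_log_sd = 1.0,
                         within_class_cv = 0.30,
                         qc_n = 6L,
                         qc_cv_low = 0.02,
                         qc_cv_high = 0.60,
                         qc_frac_unstable = 0.10,
                         missing_rate = 0.05,
                         seed = 1L,
                         ion_mode = c("positive", "negative"),
                         reference_class = "Pinghe") {
  ion_mode <- match.arg(ion_mode)
  n_unique_per_class <- unlist(n_unique_per_class)   # accept YAML-style lists
  if (!is.null(shared_weights)) shared_weights <- unlist(shared_weights)
  cfg <- list(n_classes = 9L, n_per_class = as.integer(n_per_class),
              n_features = as.integer(n_features),
              n_unique_per_class = n_unique_per_class,
              n_shared = as.integer(n_shared), shared_weights = shared_weights,
              effect_size = effect_size, base_log_mean = base_log_mean,
              base_log_sd = base_log_sd, within_class_cv = within_class_cv,
              qc_n = as.integer(qc_n), qc_cv_low = qc_cv_low,
              qc_cv_high = qc_cv_high, qc_frac_unstable = qc_frac_unstable,
              missing_rate = missing_rate, seed = as.integer(seed),
              ion_mode = ion_mode, reference_class = reference_class)
  .check(cfg$n_per_class > 0, "n_per_class", "must be > 0")
  .check(cfg$n_features > 0, "n_features", "must be > 0")
  .check(cfg$reference_class %in% constitution_types(),
         "reference_class", "must be one of the nine constitutions")
  .check(setequal(names(cfg$n_unique_per_class),
                  setdiff(constitution_types(), cfg$reference_class)),
         "n_unique_per_class", "must be named over the eight biased classes")
  .check(all(cfg$n_unique_per_class >= 0), "n_unique_per_class", "entries must be >= 0")
  .check(cfg$n_shared >= 0, "n_shared", "must be >= 0")
  .check(sum(cfg$n_unique_per_class) + cfg$n_shared <= cfg$n_features,
         "n_features", "planted differential features exceed n_features")
  .check(cfg$effect_size >= 0, "effect_size", "must be >= 0")
  .check(cfg$base_log_sd >= 0, "base_log_sd", "must be >= 0")
  .check(cfg$within_class_cv >= 0, "within_class_cv", "must be >= 0")
  .check(cfg$qc_n >= 2, "qc_n", "must be >= 2")
  .check(cfg$qc_cv_low >= 0 && cfg$qc_cv_high >= cfg$qc_cv_low,
         "qc_cv_low", "need 0 <= qc_cv_low <= qc_cv_high")
  .check(cfg$qc_frac_unstable >= 0 && cfg$qc_frac_unstable <= 1,
         "qc_frac_unstable", "must be in [0, 1]")
  .check(cfg$qc_frac_unstable == 0 || cfg$qc_cv_high > 0.30,
         "qc_cv_high", "must exceed 0.30 when qc_frac_unstable > 0")
  .check(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
         "missing_rate", "must be in [0, 1)")
  if (!is.null(cfg$shared_weights)) {
    .check(setequal(names(cfg$shared_weights), names(cfg$n_unique_per_class)),
           "shared_weights", "must be named over the eight biased classes")
    .check(all(cfg$shared_weights >= 0 & cfg$shared_weights <= 1),
           "shared_weights", "entries must be probabilities in [0, 1]")
  }
  structure(cfg, class = "synth_config")
}

#' Study-scale generator configuration
#'
#' The matched-scale configuration used for the package's headline
#' evaluation: 9 x 49 subjects, 2000 features per ion mode, per-class unique
#' differential counts spanning the wide asymmetry seen in real serum
#' cohorts — including one class (Qiyu) with no unique features at all in
#' positive mode — and shared-feature class weights set so per-class
#' differential totals land in the hundreds.
#'
#' @inheritParams synth_config
#' @param ... Overrides passed on to [synth_config()].
#' @return A `synth_config`.
#' @export
study_config <- function(ion_mode = c("positive", "negative"), seed = 1L, ...) {
  ion_mode <- match.arg(ion_mode)
  uniq <- list(
    positive = c(Qixu = 5L, Yangxu = 52L, Yinxu = 11L, Tanshi = 18L,
                 Shire = 104L, Qiyu = 0L, Xueyu = 23L, Tebing = 209L),
    negative = c(Qixu = 26L, Yangxu = 16L, Yinxu = 32L, Tanshi = 37L,
                 Shire = 49L, Qiyu = 2L, Xueyu = 161L, Tebing = 64L))
  shared_target <- list(  # expected per-class shared differential counts
    positive = c(Qixu = 256, Yangxu = 196, Yinxu = 256, Tanshi = 282,
                 Shire = 622, Qiyu = 36, Xueyu = 262, Tebing = 667),
    negative = c(Qixu = 554, Yangxu = 218, Yinxu = 388, Tanshi = 551,
                 Shire = 482, Qiyu = 41, Xueyu = 162, Tebing = 346))
  n_shared <- 800L
  synth_config(n_unique_per_class = uniq[[ion_mode]],
               n_shared = n_shared,
               shared_weights = shared_target[[ion_mode]] / n_shared,
               ion_mode = ion_mode, seed = seed, ...)
}

#' Generate a synthetic cohort
#'
#' Draws a full subject feature table plus ground truth. Deterministic for a
#' fixed `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list of class `synthetic_cohort` with elements `table`
#'   (a [feature_table] of subject columns), `labels` (named vector
#'   sample -> constitution) and `truth` (planted unique sets per class,
#'   planted shared set, shared membership map; QC stability truth is added
#'   by [generate_qc_replicates()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  p <- config$n_features
  classes <- c(config$reference_class,
               setdiff(constitution_types(), config$reference_class))

  mz <- runif(p, 50, 1000)
  rt <- runif(p, 0, 32)
  ids <- sprintf("M%.4fT%.2f", mz, rt)
  while (anyDuplicated(ids)) {        # regenerate clashing IDs
    dup <- duplicated(ids)
    mz[dup] <- runif(sum(dup), 50, 1000)
    rt[dup] <- runif(sum(dup), 0, 32)
    ids[dup] <- sprintf("M%.4fT%.2f", mz[dup], rt[dup])
  }
  mu <- exp(rnorm(p, config$base_log_mean, config$base_log_sd))

  biased <- setdiff(classes, config$reference_class)
  n_uni <- config$n_unique_per_class[biased]
  n_planted <- sum(n_uni) + config$n_shared
  planted_idx <- if (n_planted > 0) sample.int(p, n_planted) else integer(0)
  uni_idx <- split(planted_idx[seq_len(sum(n_uni))],
                   rep(biased, n_uni))
  uni_idx <- lapply(setNames(biased, biased), function(b) sort(uni_idx[[b]]))
  shared_idx <- sort(planted_idx[seq_len(config$n_shared) + sum(n_uni)])

  # shared-feature class membership (always >= 2 classes)
  members <- lapply(shared_idx, function(i) {
    if (is.null(config$shared_weights)) {
      sample(biased, sample(2:8, 1))
    } else {
      w <- config$shared_weights[biased]
      for (try in 1:50) {
        m <- biased[runif(8) < w]
        if (length(m) >= 2) return(m)
      }
      sample(biased, 2, prob = pmax(w, 1e-6))
    }
  })

  # per-feature/class multiplicative shift matrix (log2 effect, random sign)
  shift <- matrix(0, p, length(classes), dimnames = list(NULL, classes))
  for (b in biased) if (length(uni_idx[[b]]))
    shift[uni_idx[[b]], b] <- sample(c(-1, 1), length(uni_idx[[b]]), replace = TRUE)
  if (length(shared_idx))
    for (k in seq_along(shared_idx))
      shift[shared_idx[k], members[[k]]] <-
        sample(c(-1, 1), length(members[[k]]), replace = TRUE)

  n <- config$n_per_class
  mat <- matrix(NA_real_, p, length(classes) * n)
  labels <- character(length(classes) * n)
  sample_ids <- character(length(classes) * n)
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    cols <- (ci - 1) * n + seq_len(n)
    m_c <- mu * 2^(shift[, cls] * config$effect_size)
    sdl <- sqrt(log(1 + config$within_class_cv^2))
    noise <- matrix(rnorm(p * n, -sdl^2 / 2, sdl), p, n)
    mat[, cols] <- m_c * exp(noise)
    labels[cols] <- cls
    sample_ids[cols] <- sprintf("%s_%02d", cls, seq_len(n))
  }
  if (config$missing_rate > 0)
    mat[runif(length(mat)) < config$missing_rate] <- NA_real_

  tab <- feature_table(mat,
                       data.frame(feature_id = ids, mz = mz, rt = rt,
                                  stringsAsFactors = FALSE),
                       data.frame(sample_id = sample_ids, role = "subject",
                                  class = labels, stringsAsFactors = FALSE),
                       ion_mode = config$ion_mode)
  truth <- list(
    planted_unique = lapply(uni_idx, function(i) ids[i]),
    planted_shared = ids[shared_idx],
    shared_members = setNames(members, ids[shared_idx]),
    unstable_qc_features = NULL)
  structure(list(table = tab, labels = setNames(labels, sample_ids),
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Add pooled-QC replicate columns
#'
#' Appends `qc_n` QC replicate columns drawn around each feature's grand mean
#' with a per-feature target CV: exactly `round(qc_frac_unstable * n_features)`
#' features draw their target CV above 0.30 (recorded in the cohort truth as
#' `unstable_qc_features`), the rest from `[qc_cv_low, min(qc_cv_high, 0.30)]`.
#'
#' @param config The [synth_config()] used for the cohort.
#' @param cohort A `synthetic_cohort` from [generate_cohort()] (or a bare
#'   [feature_table]).
#' @return The cohort with QC columns appended to its table and
#'   `truth$unstable_qc_features` filled in (a `feature_table` in, a
#'   `feature_table` plus attribute `unstable_qc_features` out).
#' @export
generate_qc_replicates <- function(config, cohort) {
  stopifnot(inherits(config, "synth_config"))
  .check(config$qc_n >= 2, "qc_n", "must be >= 2")
  tab <- if (inherits(cohort, "synthetic_cohort")) cohort$table else cohort
  set.seed(config$seed + 104729L)  # offset stream so cohort draws are not reused
  p <- nrow(tab$intensity)
  grand <- rowMeans(subject_matrix(tab), na.rm = TRUE)

  n_unstable <- round(config$qc_frac_unstable * p)
  unstable <- sort(sample.int(p, n_unstable))
  cv <- runif(p, config$qc_cv_low, min(config$qc_cv_high, 0.30))
  if (n_unstable > 0)
    cv[unstable] <- runif(n_unstable, 0.30, config$qc_cv_high)

  sdl <- sqrt(log(1 + cv^2))  # per-feature lognormal sd giving target CV
  qc <- matrix(NA_real_, p, config$qc_n)
  for (j in seq_len(config$qc_n))
    qc[, j] <- grand * exp(rnorm(p, -sdl^2 / 2, sdl))
  qc_ids <- sprintf("QC_%02d", seq_len(config$qc_n))
  newtab <- feature_table(cbind(tab$intensity, qc),
                          tab$features,
                          rbind(tab$samples,
                                data.frame(sample_id = qc_ids, role = "QC",
                                           class = NA_character_,
                                           stringsAsFactors = FALSE)),
                          tab$ion_mode)
  unstable_ids <- tab$features$feature_id[unstable]
  if (inherits(cohort, "synthetic_cohort")) {
    cohort$table <- newtab
    cohort$truth$unstable_qc_features <- unstable_ids
    cohort
  } else {
    attr(newtab, "unstable_qc_features") <- unstable_ids
    newtab
  }
}

#' Generate questionnaire responses aimed at a target constitution
#'
#' Draws item scores (1–5) on all nine subscales so that, under the
#' determination standard, every response is determined as the target type:
#' the Pinghe subscale conversion score always lands at or above 60, the
#' target biased subscale (if any) at or above 40 plus margin, and all other
#' biased subscales below 30.
#'
#' @param n_subjects Number of responses to draw.
#' @param target_class One of [constitution_types()].
#' @param seed RNG seed.
#' @param n_items Named integer vector of items per subscale (default 8 each).
#' @return List of `questionnaire_response` objects (named lists of integer
#'   item-score vectors, one per subscale).
#' @export
generate_questionnaires <- function(n_subjects, target_class, seed = 1L,
                                    n_items = setNames(rep(8L, 9), constitution_types())) {
  .check(target_class %in% constitution_types(), "target_class",
         "must be one of the nine constitutions")
  .check(setequal(names(n_items), constitution_types()) && all(n_items >= 1),
         "n_items", "must be named over all nine subscales, each >= 1")
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    resp <- lapply(setNames(constitution_types(), constitution_types()), function(sub) {
      conv <- if (sub == "Pinghe") runif(1, 65, 90)
              else if (sub == target_class) runif(1, 45, 80)
              else runif(1, 5, 25)
      .items_for_conversion(n_items[[sub]], conv)
    })
    structure(resp, class = "questionnaire_response")
  })
}

# integer item vector of length n whose conversion score ~= conv (0-100)
.items_for_conversion <- function(n, conv) {
  extra <- round(4 * n * conv / 100)       # original - n, in 0 .. 4n
  items <- rep(1L, n)
  while (extra > 0) {
    open <- which(items < 5L)
    pick <- open[sample.int(length(open), 1)]
    add <- min(5L - items[pick], extra, sample.int(4L, 1))
    items[pick] <- items[pick] + add
    extra <- extra - add
  }
  items
}
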