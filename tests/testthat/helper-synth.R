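# Small cohort helpers shared across test files.

tiny_config <- function(seed = 1L, n_per_class = 10L, n_features = 120L,
                        n_unique = 4L, n_shared = 12L, ...) {
  synth_config(n_per_class = n_per_class, n_features = n_features,
               n_unique_per_class = setNames(rep(as.integer(n_unique), 8),
                                             biased_types()),
               n_shared = n_shared, seed = seed, ...)
}

tiny_cohort <- function(seed = 1L, with_qc = TRUE, ...) {
  cfg <- tiny_config(seed = seed, ...)
  co <- generate_cohort(cfg)
  if (with_qc) co <- generate_qc_replicates(cfg, co)
  co
}

# hand-built feature_table from a plain matrix (subjects + optional QC cols)
make_table <- function(mat, classes = NULL, n_qc = 0, ion_mode = "positive") {
  p <- nrow(mat); n <- ncol(mat)
  n_subj <- n - n_qc
  ids <- sprintf("F%03d", seq_len(p))
  feats <- data.frame(feature_id = ids, mz = 50 + seq_len(p), rt = seq_len(p) / 10)
  if (is.null(classes)) classes <- rep("Pinghe", n_subj)
  samples <- data.frame(
    sample_id = c(sprintf("S%03d", seq_len(n_subj)),
                  if (n_qc > 0) sprintf("QC_%02d", seq_len(n_qc))),
    role = c(rep("subject", n_subj), rep("QC", n_qc)),
    class = c(classes, rep(NA_character_, n_qc)),
    stringsAsFactors = FALSE)
  feature_table(mat, feats, samples, ion_mode)
}
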