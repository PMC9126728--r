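# Independent oracles, written without reference to the package internals.

# Exhaustive CART in plain R: full feature search at every node, midpoint
# thresholds between consecutive distinct values, strictly positive Gini
# decrease, ties to lowest feature then lowest threshold, left branch x < thr.
oracle_cart <- function(x, y, min_leaf = 1L) {
  y <- as.factor(y)
  K <- nlevels(y)
  yi <- as.integer(y)
  grow <- function(idx) {
    cnt <- tabulate(yi[idx], K)
    n <- length(idx)
    node <- list(counts = cnt, feature = NA_integer_, threshold = NA_real_,
                 left = NULL, right = NULL)
    if (sum(cnt > 0) <= 1 || n < 2 || n < 2 * min_leaf) return(node)
    g0 <- 1 - sum((cnt / n)^2)
    best <- NULL
    for (f in seq_len(ncol(x))) {
      ord <- order(x[idx, f])
      sv <- x[idx, f][ord]; sy <- yi[idx][ord]
      lc <- integer(K); rc <- tabulate(sy, K)
      for (i in seq_len(n - 1)) {
        lc[sy[i]] <- lc[sy[i]] + 1L
        rc[sy[i]] <- rc[sy[i]] - 1L
        if (sv[i] < sv[i + 1]) {
          nl <- i; nr <- n - i
          if (nl < min_leaf || nr < min_leaf) next
          thr <- (sv[i] + sv[i + 1]) / 2
          dec <- g0 - nl / n * (1 - sum((lc / nl)^2)) -
                      nr / n * (1 - sum((rc / nr)^2))
          if (dec > 0 && (is.null(best) || dec > best$dec ||
              (dec == best$dec && (f < best$f ||
               (f == best$f && thr < best$thr)))))
            best <- list(f = f, thr = thr, dec = dec)
        }
      }
    }
    if (is.null(best)) return(node)
    sel <- x[idx, best$f] < best$thr
    node$feature <- best$f
    node$threshold <- best$thr
    node$left <- grow(idx[sel])
    node$right <- grow(idx[!sel])
    node
  }
  list(tree = grow(seq_len(nrow(x))), classes = levels(y))
}

oracle_cart_predict <- function(fit, newx) {
  pred1 <- function(node, v) {
    while (!is.na(node$feature))
      node <- if (v[node$feature] < node$threshold) node$left else node$right
    which.max(node$counts)  # tie -> lowest class index
  }
  fit$classes[apply(newx, 1, function(v) pred1(fit$tree, v))]
}

# Brute-force common/unique decomposition: nested loops over every feature
# of every set, no set operations.
oracle_decompose <- function(sets) {
  classes <- names(sets)
  uniq <- common <- setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    u <- character(0); cm <- character(0)
    for (f in sets[[cl]]) {
      in_other <- FALSE
      for (other in classes) {
        if (other == cl) next
        for (g in sets[[other]]) if (identical(f, g)) in_other <- TRUE
      }
      if (in_other) cm <- c(cm, f) else u <- c(u, f)
    }
    uniq[[cl]] <- u
    common[[cl]] <- cm
  }
  list(unique = uniq, common = common)
}

# Pearson r from the raw covariance / sd definition
oracle_pearson <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# One-vs-rest accuracy by direct counting over the outcome list
oracle_class_accuracy <- function(true, pred, cls) {
  hits <- 0
  for (i in seq_along(true)) {
    if (true[i] == cls && pred[i] == cls) hits <- hits + 1
    if (true[i] != cls && pred[i] != cls) hits <- hits + 1
  }
  hits / length(true)
}

# Literal transcription of the determination standard for a truth-table check
oracle_determination <- function(conv) {
  biased <- conv[setdiff(names(conv), "Pinghe")]
  v <- setNames(rep("no", length(conv)), names(conv))
  if (conv[["Pinghe"]] >= 60) {
    if (all(biased < 30)) v["Pinghe"] <- "yes"
    else if (all(biased < 40)) v["Pinghe"] <- "probably_yes"
    for (b in names(biased)) {
      if (biased[[b]] >= 40) v[b] <- "yes"
      else if (biased[[b]] >= 30 && biased[[b]] < 40) v[b] <- "probably_yes"
    }
  }
  yes_b <- names(biased)[v[names(biased)] == "yes"]
  final <- if (length(yes_b) >= 2) "mixed"
           else if (length(yes_b) == 1) yes_b
           else if (v[["Pinghe"]] == "yes") "Pinghe"
           else "undetermined"
  list(verdicts = v, final_type = final)
}
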