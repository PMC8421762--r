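# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (enumeration / pair loops / exact tail sums) and never
# share code with the functions they check.

# AUC by looping over every positive/negative pair.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Max Youden J by trying every observed score (and the all-pos/all-neg
# rules) as a cut-point with the rule "positive iff score >= threshold".
brute_force_max_j <- function(scores, labels) {
  cands <- c(-Inf, sort(unique(scores)), Inf)
  best <- -Inf
  for (thr in cands) {
    pred <- scores >= thr
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Exact-binomial mid-p two-sided tail for the discordant-pair sign test:
# computed purely from Binomial(n, 1/2) point probabilities.
midp_binomial <- function(b, c) {
  n <- b + c
  k <- max(b, c)
  p <- 2 * (pbinom(k, n, 0.5, lower.tail = FALSE) + 0.5 * dbinom(k, n, 0.5))
  min(p, 1)
}

# Small raw item table built directly from a code matrix.
tiny_table <- function(codes, labels, items = NULL) {
  codes <- as.matrix(codes)
  if (is.null(colnames(codes))) {
    colnames(codes) <- sprintf("IT%02d", seq_len(ncol(codes)))
  }
  d <- data.frame(subject_id = sprintf("s%03d", seq_len(nrow(codes))),
                  label = as.integer(labels))
  d <- cbind(d, as.data.frame(codes))
  item_table(d, items)
}

# Small quiet forest configuration for unit tests.
test_config <- function(seed = 1, ...) {
  forest_config(n_trees = 50, n_runs = 4, n_folds = 4, n_perm = 2,
                seed = seed, ...)
}
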