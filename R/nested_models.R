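#' Youden-index optimal classification threshold
#'
#' Searches every distinct operating point of the ROC curve — midpoints
#' between adjacent sorted unique scores, plus minus and plus infinity —
#' and returns the cut-point maximizing Youden's
#' `J = sensitivity + specificity - 1`. The prediction rule is positive
#' when `score >= threshold`. Ties in `J` break toward higher specificity
#' (and then toward the higher threshold).
#'
#' @param scores Numeric positive-class scores.
#' @param labels Binary labels (1 = positive/ASD).
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
#' @examples
#' youden_threshold(c(0.8, 0.7, 0.4, 0.6, 0.3, 0.2), c(1, 1, 1, 0, 0, 0))
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("both classes must be present to place a threshold")
  }
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  stats_at <- vapply(cand, function(thr) {
    pred <- scores >= thr
    c(sens = sum(pred & labels == 1L) / n_pos,
      spec = sum(!pred & labels == 0L) / n_neg)
  }, numeric(2))
  j <- stats_at["sens", ] + stats_at["spec", ] - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-stats_at["spec", best], -cand[best])][1]
  tibble(threshold = cand[best],
         sensitivity = unname(stats_at["sens", best]),
         specificity = unname(stats_at["spec", best]),
         youden_j = unname(j[best]))
}

#' Train the nested family of reduced-feature models
#'
#' Step 2 of the procedure. For each `k`, a random forest is trained on the
#' top-`k` items of the importance ranking, so feature sets are nested by
#' construction (`{1}, {1,2}, ..., {1..n}`). Performance is measured on
#' pooled out-of-fold scores of a class-stratified cross-validation of the
#' training partition: AUC, the Youden-optimal threshold, and sensitivity,
#' specificity and accuracy at that threshold. Each model's threshold is
#' frozen here and reused verbatim when the model later faces the
#' validation set.
#'
#' @param train A recoded `item_tbl` (the training partition).
#' @param ranking A `feature_ranking` from [aggregate_ranking()] covering
#'   the table's items.
#' @param config A [forest_config()].
#' @param ks Which family members to train; defaults to `1:n` over all
#'   ranked features.
#' @param balanced If `TRUE` (default) `acc` is balanced accuracy, else
#'   plain accuracy.
#' @return A tibble of class `model_family`: one row per `k` with columns
#'   `k`, `feature_ids` (list), `auc`, `threshold`, `youden_j`,
#'   `sensitivity`, `specificity`, `acc`.
#' @export
train_reduced_models <- function(train, ranking, config = forest_config(),
                                 ks = NULL, balanced = TRUE) {
  if (nrow(ranking) == 0L) abort("empty ranking")
  if (!all(ranking$item_id %in% item_ids(train))) {
    abort("ranking refers to items absent from the table")
  }
  enc <- encode_for_forest(train)
  ordered_ids <- ranking$item_id
  ks <- ks %||% seq_along(ordered_ids)
  labels <- as.integer(enc$y == "pos")
  folds <- make_folds(enc$y, config$n_folds, derive_seed(config$seed, 3))

  rows <- purrr::map(ks, function(k) {
    feats <- ordered_ids[seq_len(k)]
    xk <- enc$x[feats]
    oof <- numeric(nrow(xk))
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      fit <- fit_forest(xk[tr, , drop = FALSE], enc$y[tr], config,
                        derive_seed(config$seed, 104729, k, f))
      oof[!tr] <- forest_scores(fit, xk[!tr, , drop = FALSE])
    }
    thr <- youden_threshold(oof, labels)
    cm <- confusion_metrics(as.integer(oof >= thr$threshold), labels)
    tibble(k = k, feature_ids = list(feats),
           auc = roc_auc(oof, labels),
           threshold = thr$threshold, youden_j = thr$youden_j,
           sensitivity = thr$sensitivity, specificity = thr$specificity,
           acc = if (balanced) cm$balanced_accuracy else cm$accuracy)
  })
  out <- bind_rows(rows)
  class(out) <- c("model_family", class(out))
  out
}

#' Weights of the parsimony-weighted model score
#'
#' Performance and complexity are combined as
#' `score = w1 * scaled_AUC + w2 * scaled_complexity` with `w1 = 0.35` and
#' `w2 = 0.65`, emphasizing less complex models in a 2:1 ratio.
#'
#' @param w1 Performance weight, default 0.35.
#' @param w2 Complexity weight, default 0.65.
#' @return A list of class `selection_weights`.
#' @export
selection_weights <- function(w1 = 0.35, w2 = 0.65) {
  if (abs(w1 + w2 - 1) > 1e-8) abort("w1 and w2 must sum to 1")
  structure(list(w1 = w1, w2 = w2), class = "selection_weights")
}

#' Score the model family and identify the optimal model
#'
#' Scales each model's AUC to the unit interval over the family
#' (`(auc - min) / (max - min)`; all 1 when the family's AUCs are all
#' equal) and its complexity so that FEWER features score HIGHER
#' (`1 - (k - 1)/(n - 1)`; 1 for a singleton family), then combines them
#' with [selection_weights()]. The "optimal model" is the score argmax,
#' ties resolved toward fewer features.
#'
#' @param records A `model_family` from [train_reduced_models()].
#' @param weights A [selection_weights()].
#' @return A tibble: `k`, `auc`, `scaled_auc`, `scaled_complexity`,
#'   `score`, `optimal` (logical, exactly one `TRUE`).
#' @export
#' @examples
#' fam <- tibble::tibble(k = 1:3, auc = c(0.70, 0.80, 0.82))
#' weighted_scores(fam)  # optimal k = 1
weighted_scores <- function(records, weights = selection_weights()) {
  if (nrow(records) == 0L) abort("empty model family")
  auc <- records$auc
  rng <- range(auc)
  scaled_auc <- if (diff(rng) == 0) rep(1, length(auc)) else {
    (auc - rng[1]) / diff(rng)
  }
  k <- records$k
  scaled_complexity <- if (length(k) == 1L || diff(range(k)) == 0) {
    rep(1, length(k))
  } else {
    (max(k) - k) / (max(k) - min(k))
  }
  score <- weights$w1 * scaled_auc + weights$w2 * scaled_complexity
  best <- k[score >= max(score) - 1e-12]
  tibble(k = k, auc = auc, scaled_auc = scaled_auc,
         scaled_complexity = scaled_complexity, score = score,
         optimal = k == min(best))
}
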