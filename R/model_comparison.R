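#' Evaluate reduced-feature models on the held-out validation set
#'
#' Step 3 of the procedure. Each family member is retrained on the full
#' training partition with its feature set, scored on the hitherto unseen
#' validation subjects, and thresholded at the decision threshold frozen
#' during training. A warning is emitted if any validation subject also
#' appears in the training partition (leakage guard).
#'
#' @param records A `model_family` from [train_reduced_models()].
#' @param train The recoded training `item_tbl` the family was built on.
#' @param validation The recoded validation `item_tbl`.
#' @param config The [forest_config()] used for training.
#' @return A tibble of class `validation_report`: per `k`, `auc`, `acc`
#'   (balanced), `sensitivity`, `specificity`, `threshold`, `n_subjects`,
#'   and list-columns `scores` and `correct` (per-subject correctness at
#'   the frozen threshold, in validation subject order).
#' @export
evaluate_on_validation <- function(records, train, validation,
                                   config = forest_config()) {
  if (any(validation$subject_id %in% train$subject_id)) {
    warn("validation subjects overlap the training partition")
  }
  enc_tr <- encode_for_forest(train)
  enc_va <- encode_for_forest(validation)
  missing_items <- setdiff(unlist(records$feature_ids), enc_va$item_ids)
  if (length(missing_items)) {
    abort(paste0("validation table lacks feature column(s): ",
                 paste(missing_items, collapse = ", ")))
  }
  labels_va <- as.integer(enc_va$y == "pos")

  rows <- purrr::map2(records$k, seq_len(nrow(records)), function(k, i) {
    feats <- records$feature_ids[[i]]
    fit <- fit_forest(enc_tr$x[feats], enc_tr$y, config,
                      derive_seed(config$seed, 15485863, k))
    sc <- forest_scores(fit, enc_va$x[feats])
    thr <- records$threshold[i]
    pred <- as.integer(sc >= thr)
    cm <- confusion_metrics(pred, labels_va)
    tibble(k = k, auc = roc_auc(sc, labels_va), acc = cm$balanced_accuracy,
           sensitivity = cm$sensitivity, specificity = cm$specificity,
           threshold = thr, n_subjects = length(labels_va),
           scores = list(sc), correct = list(pred == labels_va))
  })
  out <- bind_rows(rows)
  class(out) <- c("validation_report", class(out))
  out
}

#' McNemar test for paired classifier comparison
#'
#' Compares two classifiers on the same subjects through their discordant
#' counts: `b` subjects classified correctly by A only and `c` by B only.
#' The statistic is the uncorrected `chi2 = (b - c)^2 / (b + c)` referred
#' to the upper tail of a chi-squared distribution with 1 df. When
#' `b + c = 0` the classifiers never disagree and `chi2 = 0`, `p = 1` by
#' convention.
#'
#' @param correct_a,correct_b Logical vectors: per-subject correctness of
#'   classifiers A and B, paired on the same subjects.
#' @return A one-row tibble: `b`, `c`, `chi2`, `df` (1), `p`.
#' @export
#' @examples
#' mcnemar_test(rep(c(TRUE, FALSE), c(10, 2)), rep(c(FALSE, TRUE), c(10, 2)))
mcnemar_test <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b)) {
    abort("paired vectors must have equal length")
  }
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  chi2 <- if (b + cc == 0L) 0 else (b - cc)^2 / (b + cc)
  tibble(b = b, c = cc, chi2 = chi2, df = 1L,
         p = if (b + cc == 0L) 1 else pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Identify the minimal model by McNemar comparison to the full model
#'
#' Step 4 of the procedure. Every family member's validation-set
#' correctness is compared to the full-feature model's; scanning `k`
#' upward, the minimal model is the smallest feature count whose
#' classification errors do NOT differ significantly from the full model
#' (`p > alpha`). If no `k` below the full model qualifies, the full model
#' is its own minimal model and `minimal_is_full` is set.
#'
#' @param report A `validation_report` from [evaluate_on_validation()]
#'   covering the full-feature model (largest `k`).
#' @param optimal_k The optimal model's feature count (from
#'   [weighted_scores()]); its McNemar comparison is reported alongside.
#' @param alpha Significance level, default 0.05.
#' @return A list of class `selection_result`: `optimal_k`, `minimal_k`,
#'   `minimal_is_full`, `alpha`, `optimal_test` (one-row McNemar tibble)
#'   and `mcnemar` (per-`k` tibble `k`, `b`, `c`, `chi2`, `p`).
#' @export
find_minimal_model <- function(report, optimal_k = NULL, alpha = 0.05) {
  full_k <- max(report$k)
  full_correct <- report$correct[[which(report$k == full_k)]]
  per_k <- purrr::map2(report$k, report$correct, function(k, corr) {
    dplyr::bind_cols(tibble(k = k), mcnemar_test(corr, full_correct))
  }) |> bind_rows() |> arrange(.data$k)
  below <- per_k[per_k$k < full_k, ]
  passing <- below$k[below$p > alpha]
  minimal_is_full <- length(passing) == 0L
  minimal_k <- if (minimal_is_full) full_k else min(passing)
  optimal_test <- if (!is.null(optimal_k) && optimal_k %in% per_k$k) {
    per_k[per_k$k == optimal_k, ]
  }
  structure(
    list(optimal_k = optimal_k, minimal_k = minimal_k,
         minimal_is_full = minimal_is_full, alpha = alpha,
         optimal_test = optimal_test, mcnemar = per_k),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> optimal k = %s, minimal k = %d%s (alpha = %g)\n",
              x$optimal_k %||% "?", x$minimal_k,
              if (x$minimal_is_full) " (= full model)" else "", x$alpha))
  if (!is.null(x$optimal_test)) {
    cat(sprintf("optimal vs full: chi2 = %.3f, p = %.3g\n",
                x$optimal_test$chi2, x$optimal_test$p))
  }
  invisible(x)
}
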