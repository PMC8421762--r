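#' Tidy a fitted reduction result
#'
#' Returns the model-family table (one row per nested model) without
#' list-columns, in the spirit of broom tidiers.
#'
#' @param x A `reduction_result`.
#' @param ... Unused.
#' @return A tibble: `k`, `n_features`, training ("test") and validation
#'   ("blind") performance columns, Youden's J, frozen threshold, McNemar
#'   p and `optimal`/`minimal` flags.
#' @export
tidy.reduction_result <- function(x, ...) {
  x$models |>
    mutate(n_features = .data$k,
           optimal = .data$k == x$selection$optimal_k,
           minimal = .data$k == x$selection$minimal_k) |>
    select(-"feature_ids") |>
    select("k", "n_features", dplyr::everything())
}

#' One-row summary of a fitted reduction result
#'
#' @param x A `reduction_result`.
#' @param ... Unused.
#' @return A one-row tibble: family size, optimal/minimal `k`, the full
#'   model's training and validation AUC, the optimal model's McNemar
#'   statistic and p against the full model, and `alpha`.
#' @export
glance.reduction_result <- function(x, ...) {
  n <- max(x$models$k)
  full <- x$models[x$models$k == n, ]
  ot <- x$selection$optimal_test
  tibble(
    n_features = n,
    optimal_k = x$selection$optimal_k,
    minimal_k = x$selection$minimal_k,
    minimal_is_full = x$selection$minimal_is_full,
    auc_full_test = full$auc_test,
    auc_full_blind = full$auc_blind,
    optimal_chi2 = if (is.null(ot)) NA_real_ else ot$chi2,
    optimal_p = if (is.null(ot)) NA_real_ else ot$p,
    alpha = x$selection$alpha
  )
}
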