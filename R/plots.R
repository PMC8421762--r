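#' Plot an aggregated feature-importance hierarchy
#'
#' Horizontal bars of mean permutation importance (mean decrease in
#' accuracy), most important item at the top.
#'
#' @param object A `feature_ranking` from [aggregate_ranking()].
#' @param top_n Show at most this many items, default all.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_ranking <- function(object, top_n = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(top_n)) d <- head(d, top_n)
  d$item_id <- factor(d$item_id, levels = rev(d$item_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_importance,
                                  y = .data$item_id)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "importance score (mean decrease in accuracy)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.feature_ranking
#' @param ranking A `feature_ranking`.
#' @export
plot_importance <- function(ranking, top_n = NULL) {
  autoplot(ranking, top_n = top_n)
}

#' Plot the nested model family's performance curve
#'
#' AUC against the number of features, on the cross-validated training
#' ("test") scores and, when available, the held-out validation ("blind")
#' scores, with the optimal and minimal models marked.
#'
#' @param object A `reduction_result` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reduction_result <- function(object, ...) {
  d <- object$models |>
    select("k", test = "auc_test", blind = "auc_blind") |>
    tidyr::pivot_longer(c("test", "blind"), names_to = "set",
                        values_to = "auc")
  marks <- tibble(
    k = c(object$selection$optimal_k, object$selection$minimal_k),
    model = c("optimal", "minimal"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$auc,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$k,
                                     linetype = .data$model),
                        colour = "grey40") +
    ggplot2::labs(x = "number of features", y = "AUC",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.reduction_result
#' @param result A `reduction_result`.
#' @export
plot_model_family <- function(result) autoplot(result)
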