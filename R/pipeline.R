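#' Run the full item-reduction pipeline
#'
#' One call chains every stage: recode special/top codes, restrict to
#' algorithm items, split off a stratified validation fraction, rank items
#' by repeated cross-validated permutation importance, train the nested
#' reduced-feature family with Youden thresholds, pick the parsimony-
#' weighted optimal model, evaluate every model on the validation set and
#' identify the minimal model by McNemar comparison against the
#' full-feature model. Identical input, configuration and seeds give
#' identical results.
#'
#' @param x The cohort: an `item_tbl`, a [cohort_spec()], or the name of a
#'   [module_preset()].
#' @param validation_fraction Stratified holdout fraction, default 0.25.
#' @param config A [forest_config()]; its seed drives every stochastic
#'   stage (the split uses a derived substream unless `split_seed` is
#'   given).
#' @param weights [selection_weights()] for the optimal-model score.
#' @param alpha McNemar significance level, default 0.05.
#' @param split_seed Optional explicit seed for the train/validation split.
#' @param balanced Report balanced (default) or plain accuracy.
#' @param verbose Print structured stage-boundary log lines.
#'
#' @return A list of class `reduction_result` with elements `ranking`,
#'   `runs`, `models` (family table with training and validation columns
#'   plus McNemar p), `scores`, `selection`, `validation`, `truth` (ground
#'   truth when `x` was synthetic, else `NULL`) and `log` (seeds, flags,
#'   versions, stage counts).
#' @export
run_pipeline <- function(x, validation_fraction = 0.25,
                         config = forest_config(),
                         weights = selection_weights(), alpha = 0.05,
                         split_seed = NULL, balanced = TRUE,
                         verbose = FALSE) {
  truth <- NULL
  if (is.character(x) && length(x) == 1L) x <- module_preset(x)
  if (inherits(x, "cohort_spec")) {
    gen <- generate_cohort(x)
    truth <- gen$truth
    x <- gen$table
  }
  if (!inherits(x, "item_tbl")) abort("x must be an item_tbl, cohort_spec or preset name")

  log <- list(
    package_version = as.character(utils::packageVersion("itemreduce")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    split_seed = split_seed %||% derive_seed(config$seed, 42),
    n_trees = config$n_trees, n_runs = config$n_runs,
    n_folds = config$n_folds, n_perm = config$n_perm,
    independent_runs = config$independent_runs,
    validation_fraction = validation_fraction,
    weights = c(w1 = weights$w1, w2 = weights$w2),
    alpha = alpha, balanced_accuracy = balanced,
    stages = list()
  )
  say <- function(stage, fmt, ...) {
    msg <- sprintf(fmt, ...)
    log$stages[[stage]] <<- msg
    if (verbose) message("[", stage, "] ", msg)
  }

  x <- recode_item_codes(select_algorithm_items(x))
  say("prepare", "%d subjects x %d items, %d ASD / %d non-ASD",
      nrow(x), length(item_ids(x)), sum(x$label == 1L), sum(x$label == 0L))

  split <- train_validation_split(x, validation_fraction, log$split_seed)
  say("split", "train %d (%d ASD) / validation %d (%d ASD)",
      nrow(split$train), sum(split$train$label == 1L),
      nrow(split$validation), sum(split$validation$label == 1L))

  runs <- run_cv_importance(split$train, config)
  ranking <- aggregate_ranking(runs)
  say("ranking", "%d items ranked over %d runs", nrow(ranking), config$n_runs)

  records <- train_reduced_models(split$train, ranking, config,
                                  balanced = balanced)
  scores <- weighted_scores(records, weights)
  optimal_k <- scores$k[scores$optimal]
  say("nested_models", "%d nested models; optimal k = %d",
      nrow(records), optimal_k)

  report <- evaluate_on_validation(records, split$train, split$validation,
                                   config)
  selection <- find_minimal_model(report, optimal_k = optimal_k,
                                  alpha = alpha)
  say("selection", "minimal k = %d%s", selection$minimal_k,
      if (selection$minimal_is_full) " (full model)" else "")

  models <- records |>
    select("k", "feature_ids", auc_test = "auc", acc_test = "acc",
           sens_test = "sensitivity", spec_test = "specificity",
           "youden_j", "threshold") |>
    left_join(report |>
                select("k", auc_blind = "auc", acc_blind = "acc",
                       sens_blind = "sensitivity",
                       spec_blind = "specificity"),
              by = "k") |>
    left_join(selection$mcnemar |> select("k", mcnemar_p = "p"), by = "k")

  structure(
    list(ranking = ranking, runs = runs, models = models, scores = scores,
         selection = selection, validation = report, split = split,
         truth = truth, config = config, weights = weights, log = log),
    class = "reduction_result"
  )
}

#' @export
print.reduction_result <- function(x, ...) {
  n <- max(x$models$k)
  full <- x$models[x$models$k == n, ]
  opt <- x$models[x$models$k == x$selection$optimal_k, ]
  min_m <- x$models[x$models$k == x$selection$minimal_k, ]
  cat(sprintf("<reduction_result> %d-feature family\n", n))
  cat(sprintf("  full    (k=%2d): AUC test %.2f / blind %.2f\n",
              n, full$auc_test, full$auc_blind))
  cat(sprintf("  optimal (k=%2d): AUC test %.2f / blind %.2f, McNemar p = %.3g\n",
              opt$k, opt$auc_test, opt$auc_blind, opt$mcnemar_p))
  cat(sprintf("  minimal (k=%2d): AUC test %.2f / blind %.2f, McNemar p = %.3g\n",
              min_m$k, min_m$auc_test, min_m$auc_blind, min_m$mcnemar_p))
  invisible(x)
}

#' Selected features of a fitted reduction result
#'
#' @param result A `reduction_result`.
#' @param which `"optimal"` (default) or `"minimal"`.
#' @return A tibble `rank`, `item_id`, `instrument` for the chosen model's
#'   features, in importance order.
#' @export
selected_features <- function(result, which = c("optimal", "minimal")) {
  which <- match.arg(which)
  k <- if (which == "optimal") result$selection$optimal_k else {
    result$selection$minimal_k
  }
  feats <- result$models$feature_ids[[match(k, result$models$k)]]
  defs <- result$ranking |>
    filter(.data$item_id %in% feats)
  instr <- item_instrument_lookup(result)
  tibble(rank = seq_along(feats), item_id = feats,
         instrument = instr[feats])
}

item_instrument_lookup <- function(result) {
  defs <- attr(result$split$train, "items")
  setNames(defs$instrument, defs$item_id)
}
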