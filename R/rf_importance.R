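#' Random-forest configuration for the ranking and model stages
#'
#' Defaults follow the procedure's setting: 20 forests of 400 trees under a
#' 20-fold cross-validation (each run holds out one fold, i.e. trains on
#' 95% and tests on 5%). `mtry` defaults to the rounded square root of the
#' feature count and leaves grow to purity, the standard random-forest
#' practice.
#'
#' @param n_trees Trees per forest, default 400.
#' @param n_runs Number of repeated runs, default 20.
#' @param n_folds Cross-validation folds, default 20.
#' @param mtry Features tried per split; `NULL` means `round(sqrt(p))`.
#' @param min_leaf Minimal terminal-node size, default 1.
#' @param n_perm Permutations per item when measuring held-fold importance,
#'   default 5 (averaging smooths the coarse accuracy granularity of a
#'   small held fold).
#' @param independent_runs If `TRUE`, each run draws its own fold
#'   partition (20 independent CVs) instead of the default one-partition /
#'   one-fold-per-run scheme.
#' @param seed Master seed; all per-run and per-item randomness is derived
#'   from it.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 400, n_runs = 20, n_folds = 20,
                          mtry = NULL, min_leaf = 1, n_perm = 5,
                          independent_runs = FALSE, seed = 1L) {
  if (n_trees < 1 || n_folds < 2 || n_runs < 1) {
    abort("need n_trees >= 1, n_folds >= 2, n_runs >= 1")
  }
  structure(list(n_trees = as.integer(n_trees), n_runs = as.integer(n_runs),
                 n_folds = as.integer(n_folds), mtry = mtry,
                 min_leaf = as.integer(min_leaf), n_perm = as.integer(n_perm),
                 independent_runs = isTRUE(independent_runs),
                 seed = as.integer(seed)),
            class = "forest_config")
}

# Deterministic small-integer stream derivation. Seeds stay below 2^31.
.SEED_MOD <- 2147483647
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  s <- 12582917
  for (p in parts) s <- (s * 69069 + p) %% .SEED_MOD
  as.integer(s)
}

# Stable per-item stream key from the item id itself, so permutation
# randomness follows the item, not its column position.
string_seed <- function(s) {
  vapply(s, function(one) {
    h <- 5381
    for (ch in utf8ToInt(one)) h <- (h * 33 + ch) %% .SEED_MOD
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Class-stratified fold assignment.
make_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

#' Encode a recoded item table for forest training
#'
#' Missing codes are kept as valid values: they become the sentinel
#' category `-1`, so no subject is ever dropped. Columns follow the
#' table's schema order regardless of the physical column order of the
#' data, which keeps every downstream result invariant to column
#' permutations.
#'
#' @param table A recoded `item_tbl` (codes in {0, 1, 2, NA}).
#' @return A list with `x` (data frame of integer features, schema order),
#'   `y` (factor with levels `neg`/`pos`), and `item_ids`.
#' @export
encode_for_forest <- function(table) {
  ids <- item_ids(table)
  m <- code_matrix(table)
  bad <- !is.na(m) & !m %in% c(0L, 1L, 2L)
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "code %d (item %s) outside {0,1,2}: run recode_item_codes() first",
      m[bad][1], ids[j[["col"]]]))
  }
  m[is.na(m)] <- -1L
  list(x = as.data.frame(m),
       y = factor(table$label, levels = c(0L, 1L), labels = c("neg", "pos")),
       item_ids = ids)
}

fit_forest <- function(x, y, config, seed) {
  p <- ncol(x)
  ranger::ranger(
    x = x, y = y,
    num.trees = config$n_trees,
    mtry = config$mtry %||% max(1L, round(sqrt(p))),
    min.node.size = config$min_leaf,
    seed = seed,
    num.threads = 1
  )
}

# Positive-class score = fraction of trees voting "pos". Per-tree votes
# are returned raw, so no tie-breaking randomness is involved; the fixed
# predict seed guards against any residual RNG use.
forest_scores <- function(fit, x) {
  all_preds <- stats::predict(fit, data = x, predict.all = TRUE,
                              num.threads = 1, seed = 1L)$predictions
  pos_value <- which(fit$forest$levels == "pos")
  rowMeans(all_preds == pos_value)
}

#' Repeated cross-validated permutation importance
#'
#' Step 1 of the procedure. A class-stratified `n_folds`-fold partition is
#' drawn; run *i* trains a forest on all folds but the *i*-th and measures,
#' on the held-out fold, the mean decrease in accuracy when each item's
#' column is permuted (averaged over `n_perm` permutations). Each run's
#' importance scores are converted to ranks (1 = most important; ties
#' broken by item id), giving one importance hierarchy per run.
#'
#' @param train A recoded `item_tbl` (the training partition).
#' @param config A [forest_config()].
#' @return A tibble with one row per run x item: `run`, `item_id`,
#'   `importance` (mean decrease in accuracy), `rank`.
#' @export
run_cv_importance <- function(train, config = forest_config()) {
  enc <- encode_for_forest(train)
  cls_n <- table(enc$y)
  if (any(cls_n < config$n_folds)) {
    abort(sprintf("need >= %d subjects per class for %d-fold stratification",
                  config$n_folds, config$n_folds))
  }
  base_folds <- make_folds(enc$y, config$n_folds, derive_seed(config$seed, 1))
  item_keys <- string_seed(enc$item_ids)

  runs <- purrr::map(seq_len(config$n_runs), function(run) {
    run_seed <- derive_seed(config$seed, 7919, run)
    folds <- if (config$independent_runs) {
      make_folds(enc$y, config$n_folds, derive_seed(run_seed, 2))
    } else {
      base_folds
    }
    held <- ((run - 1L) %% config$n_folds) + 1L
    tr <- folds != held
    if (length(unique(enc$y[tr])) < 2L) {
      abort(sprintf("run %d: a class is absent from the training folds", run))
    }
    fit <- fit_forest(enc$x[tr, , drop = FALSE], enc$y[tr], config, run_seed)
    x_held <- enc$x[!tr, , drop = FALSE]
    y_held <- enc$y[!tr]
    # predict() seeds are fixed: ranger breaks tied majority votes randomly
    baseline <- mean(stats::predict(fit, data = x_held, num.threads = 1,
                                    seed = run_seed)$predictions == y_held)
    imp <- vapply(seq_along(enc$item_ids), function(j) {
      accs <- vapply(seq_len(config$n_perm), function(perm) {
        perm_seed <- derive_seed(run_seed, item_keys[j], perm)
        xp <- x_held
        xp[[j]] <- withr::with_seed(perm_seed, sample(xp[[j]]))
        mean(stats::predict(fit, data = xp, num.threads = 1,
                            seed = perm_seed)$predictions == y_held)
      }, numeric(1))
      baseline - mean(accs)
    }, numeric(1))
    ord <- order(-imp, enc$item_ids)
    rk <- integer(length(imp))
    rk[ord] <- seq_along(imp)
    tibble(run = run, item_id = enc$item_ids, importance = imp, rank = rk)
  })
  bind_rows(runs)
}

#' Aggregate per-run importance hierarchies into one ranking
#'
#' Each item's rank is averaged across runs; the hierarchy orders items by
#' mean rank ascending, breaking ties by mean importance descending and
#' then item id.
#'
#' @param runs Output of [run_cv_importance()].
#' @return A tibble of class `feature_ranking`: `item_id`, `mean_rank`,
#'   `mean_importance`, ordered best-first.
#' @export
aggregate_ranking <- function(runs) {
  sets <- runs |> group_by(.data$run) |>
    summarise(key = paste(sort(.data$item_id), collapse = "\r"))
  if (length(unique(sets$key)) != 1L) {
    abort("runs cover inconsistent item sets")
  }
  out <- runs |>
    group_by(.data$item_id) |>
    summarise(mean_rank = mean(.data$rank),
              mean_importance = mean(.data$importance)) |>
    arrange(.data$mean_rank, desc(.data$mean_importance), .data$item_id)
  class(out) <- c("feature_ranking", class(out))
  out
}
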