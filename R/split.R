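#' Stratified train/validation split
#'
#' Holds out a class-stratified fraction of subjects as a validation set the
#' model-building stages never see; the default 25% holdout mirrors common
#' practice for blind validation of diagnostic classifiers. Within each
#' class, `round(fraction * n_class)` subjects are sampled without
#' replacement, so overall prevalence is preserved to within one subject per
#' class and the validation size equals `round(fraction * N)` within +/- 1.
#'
#' @param table An `item_tbl`.
#' @param fraction Proportion held out, in `[0, 1)`. Default 0.25.
#' @param seed Integer seed; the split is deterministic given the seed.
#'
#' @return A list of class `split_result` with elements `train` and
#'   `validation` (both `item_tbl`), `fraction` and `seed`.
#' @export
train_validation_split <- function(table, fraction = 0.25, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1) {
    abort("fraction must be a single number in [0, 1)")
  }
  defs <- item_info(table)
  tag <- attr(table, "subsample_tag")
  n <- nrow(table)
  if (fraction > 0 && (!any(table$label == 1L) || !any(table$label == 0L))) {
    abort("both classes must be present to stratify a non-trivial split")
  }
  val_idx <- integer(0)
  if (fraction > 0) {
    val_idx <- withr::with_seed(seed, {
      unlist(lapply(c(0L, 1L), function(cl) {
        idx <- which(table$label == cl)
        sample(idx, round(fraction * length(idx)))
      }))
    })
  }
  val_idx <- sort(val_idx)
  train_idx <- setdiff(seq_len(n), val_idx)
  structure(
    list(
      train = new_item_table(table[train_idx, ], defs, tag),
      validation = new_item_table(table[val_idx, ], defs, tag),
      fraction = fraction,
      seed = as.integer(seed)
    ),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf(
    "<split_result> train %d (%d ASD) / validation %d (%d ASD), fraction %.2f, seed %d\n",
    nrow(x$train), sum(x$train$label == 1L),
    nrow(x$validation), sum(x$validation$label == 1L),
    x$fraction, x$seed))
  invisible(x)
}
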