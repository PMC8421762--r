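#' Write the pipeline's report bundle
#'
#' Exports a fitted [run_pipeline()] result as plain-text artefacts:
#' \describe{
#'   \item{`importance_ranking.tsv`}{aggregated hierarchy (`item_id`,
#'     `mean_rank`, `mean_importance`) — the data behind an importance
#'     plot.}
#'   \item{`model_family.tsv`}{one row per nested model with training
#'     ("test") and validation ("blind") AUC/ACC/sensitivity/specificity,
#'     Youden's J and McNemar p.}
#'   \item{`selection.json`}{optimal/minimal model identities and the
#'     per-`k` McNemar table.}
#'   \item{`selected_features.tsv`}{the optimal model's feature list.}
#'   \item{`run_log.json`}{seeds, configuration flags, versions and stage
#'     counts.}
#' }
#' Outputs are byte-identical across reruns with the same configuration
#' and seeds.
#'
#' @param result A `reduction_result`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(as_tibble(result$ranking),
                   file.path(dir, "importance_ranking.tsv"))
  fam <- result$models |>
    mutate(features = purrr::map_chr(.data$feature_ids, paste,
                                     collapse = ",")) |>
    select(-"feature_ids")
  readr::write_tsv(fam, file.path(dir, "model_family.tsv"))
  sel <- result$selection
  jsonlite::write_json(
    list(optimal_k = sel$optimal_k, minimal_k = sel$minimal_k,
         minimal_is_full = sel$minimal_is_full, alpha = sel$alpha,
         per_k = sel$mcnemar),
    file.path(dir, "selection.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(selected_features(result, "optimal"),
                   file.path(dir, "selected_features.tsv"))
  jsonlite::write_json(result$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Generate cohort fixture files from a specification
#'
#' Materializes a [cohort_spec()] (or a YAML file holding one) as
#' plain-text fixtures: the cohort CSV (via [write_item_table()]), the
#' item-schema sidecar, the ground truth JSON and the spec itself.
#'
#' @param spec A `cohort_spec` or path to a spec YAML.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
generate_fixtures <- function(spec, dir) {
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_cohort(spec)
  write_item_table(gen$table, file.path(dir, "cohort.csv"))
  write_item_schema(spec$items, file.path(dir, "schema.yaml"))
  jsonlite::write_json(gen$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_cohort_spec(spec, file.path(dir, "spec.yaml"))
  invisible(dir)
}
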