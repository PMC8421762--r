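#' Read a subject-by-item table from delimited text
#'
#' Expects a header row `subject_id,label,<item_id>...`. Labels may be the
#' internal 0/1 coding or arbitrary strings mapped through `label_values`
#' (e.g. `c(positive = "ASD", negative = "non-ASD")`). Any item column not
#' declared in `items` is an error, as is a label outside the two mapped
#' values.
#'
#' @param path File to read.
#' @param items Item definitions ([item_defs()] tibble) or a path to a
#'   schema sidecar readable by [read_item_schema()]. `NULL` treats every
#'   item column as ADOS.
#' @param delim Field delimiter, default comma.
#' @param missing_token String standing for a missing code, default `"NA"`.
#' @param label_values Length-2 named character vector mapping the file's
#'   label strings to the positive (ASD) and negative (non-ASD) class.
#' @param subsample_tag Optional subsample tag to attach.
#'
#' @return An `item_tbl`.
#' @export
read_item_table <- function(path, items = NULL, delim = ",",
                            missing_token = "NA",
                            label_values = c(positive = "1", negative = "0"),
                            subsample_tag = NULL) {
  if (is.character(items) && length(items) == 1L) {
    items <- read_item_schema(items)
  }
  raw <- readr::read_delim(path, delim = delim, na = missing_token,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (!all(c("subject_id", "label") %in% names(raw))) {
    abort("header must contain 'subject_id' and 'label'")
  }
  lab <- raw$label
  known <- lab %in% label_values
  if (any(!known)) {
    abort(paste0("Unmapped label value(s): ",
                 paste(unique(lab[!known]), collapse = ", ")))
  }
  raw$label <- ifelse(lab == label_values[["positive"]], 1L, 0L)
  item_cols <- setdiff(names(raw), c("subject_id", "label"))
  for (id in item_cols) {
    v <- suppressWarnings(as.integer(raw[[id]]))
    bad <- is.na(v) & !is.na(raw[[id]])
    if (any(bad)) {
      abort(sprintf("Non-integer code '%s' in column %s", raw[[id]][bad][1], id))
    }
    raw[[id]] <- v
  }
  item_table(raw, items, subsample_tag = subsample_tag)
}

#' Write a subject-by-item table as delimited text
#'
#' Inverse of [read_item_table()]: `read_item_table(write_item_table(t))`
#' reproduces `t` exactly, including missing entries.
#'
#' @param table An `item_tbl`.
#' @param path Output file.
#' @inheritParams read_item_table
#' @return `path`, invisibly.
#' @export
write_item_table <- function(table, path, delim = ",", missing_token = "NA",
                             label_values = c(positive = "1", negative = "0")) {
  out <- as_tibble(as.data.frame(table))
  out$label <- ifelse(out$label == 1L, label_values[["positive"]],
                      label_values[["negative"]])
  readr::write_delim(out, path, delim = delim, na = missing_token)
  invisible(path)
}

#' Read / write an item-schema sidecar
#'
#' The sidecar declares, per item, the instrument, algorithm membership and
#' domain tag, as YAML or JSON: a list of records with fields `item_id`,
#' `instrument`, `in_algorithm`, `domain_tag`.
#'
#' @param path Schema file (`.yaml`/`.yml` or `.json`).
#' @return [read_item_schema()]: an item-definition tibble.
#' @export
read_item_schema <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    bind_rows(lapply(yaml::read_yaml(path), as_tibble))
  }
  recs <- as_tibble(recs)
  if (!"in_algorithm" %in% names(recs)) recs$in_algorithm <- TRUE
  if (!"domain_tag" %in% names(recs)) recs$domain_tag <- NA_character_
  item_defs(recs$item_id, recs$instrument, recs$in_algorithm, recs$domain_tag)
}

#' @rdname read_item_schema
#' @param items An item-definition tibble.
#' @return [write_item_schema()]: `path`, invisibly.
#' @export
write_item_schema <- function(items, path) {
  recs <- purrr::pmap(items, function(item_id, instrument, in_algorithm,
                                      domain_tag) {
    r <- list(item_id = item_id, instrument = instrument,
              in_algorithm = in_algorithm)
    if (!is.na(domain_tag)) r$domain_tag <- domain_tag
    r
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(recs, path)
  }
  invisible(path)
}

#' Write a train/validation split manifest
#'
#' Two-column TSV (`subject_id`, `part`) recording which partition each
#' subject fell into.
#'
#' @param split A split from [train_validation_split()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  manifest <- bind_rows(
    tibble(subject_id = split$train$subject_id, part = "train"),
    tibble(subject_id = split$validation$subject_id, part = "validation")
  )
  readr::write_tsv(manifest, path)
  invisible(path)
}
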