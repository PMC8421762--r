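#' Define the items of a subject-by-item table
#'
#' An item definition records, for each instrument item, which instrument it
#' belongs to, whether it is part of that instrument's diagnostic algorithm,
#' and (for ADI-R items) its algorithm domain. Item filtering
#' ([select_algorithm_items()]) is driven entirely by this metadata.
#'
#' @param item_id Character vector of unique short item codes (e.g. `"QSOV"`,
#'   `"EXPE"`).
#' @param instrument Character vector, each `"ADOS"` or `"ADIR"`, recycled.
#' @param in_algorithm Logical; whether the item belongs to the instrument's
#'   diagnostic algorithm. ADOS items are always algorithm-eligible and
#'   default to `TRUE`.
#' @param domain_tag Optional character; ADI-R algorithm domain (`"A"`,
#'   `"B"`, `"C"`, `"D"`), `NA` otherwise.
#'
#' @return A tibble with columns `item_id`, `instrument`, `in_algorithm`,
#'   `domain_tag`.
#' @export
#' @examples
#' item_defs(c("QSOV", "EXPE"), instrument = "ADOS")
item_defs <- function(item_id, instrument = "ADOS", in_algorithm = TRUE,
                      domain_tag = NA_character_) {
  if (anyDuplicated(item_id)) {
    abort(paste0("Duplicate item_id: ",
                 paste(unique(item_id[duplicated(item_id)]), collapse = ", ")))
  }
  defs <- tibble(
    item_id      = as.character(item_id),
    instrument   = rep_len(as.character(instrument), length(item_id)),
    in_algorithm = rep_len(as.logical(in_algorithm), length(item_id)),
    domain_tag   = rep_len(as.character(domain_tag), length(item_id))
  )
  bad <- !defs$instrument %in% c("ADOS", "ADIR")
  if (any(bad)) {
    abort(paste0("instrument must be 'ADOS' or 'ADIR'; offending item(s): ",
                 paste(defs$item_id[bad], collapse = ", ")))
  }
  defs
}

# Codes an un-recoded table may contain; MISSING is NA and always allowed.
.allowed_raw_codes <- c(0L, 1L, 2L, 3L, 7L, 8L)

new_item_table <- function(data, items, subsample_tag = NULL) {
  structure(
    as_tibble(data),
    items = items,
    subsample_tag = subsample_tag,
    class = c("item_tbl", class(as_tibble(data)))
  )
}

#' Construct a subject-by-item table
#'
#' The universal input of the pipeline: one row per subject, a binary
#' best-estimate clinical label (1 = ASD, the positive class; 0 = non-ASD),
#' and one column of ordinal codes per item. Codes may be 0--3 (increasing
#' severity), the special codes 7/8, or `NA` (missing). Item metadata is
#' carried alongside the data and consulted by downstream stages.
#'
#' @param data A data frame with columns `subject_id`, `label`, and one
#'   integer column per item in `items`.
#' @param items An item-definition tibble from [item_defs()]. Defaults to
#'   treating every non-id column as an ADOS item.
#' @param subsample_tag Optional tag naming the subsample (e.g.
#'   `"children_m3"` or `"adults_m4"`).
#'
#' @return An `item_tbl`: a tibble carrying `items` and `subsample_tag`
#'   attributes.
#' @export
item_table <- function(data, items = NULL, subsample_tag = NULL) {
  data <- as_tibble(data)
  if (!all(c("subject_id", "label") %in% names(data))) {
    abort("data must have 'subject_id' and 'label' columns")
  }
  if (anyDuplicated(data$subject_id)) {
    abort(paste0("Duplicate subject_id: ",
                 paste(unique(data$subject_id[duplicated(data$subject_id)]),
                       collapse = ", ")))
  }
  if (anyNA(data$label) || !all(data$label %in% c(0L, 1L))) {
    abort("label must be 0 (non-ASD) or 1 (ASD) for every subject")
  }
  item_cols <- setdiff(names(data), c("subject_id", "label"))
  if (is.null(items)) {
    items <- item_defs(item_cols)
  }
  missing_cols <- setdiff(items$item_id, item_cols)
  if (length(missing_cols)) {
    abort(paste0("Items defined but absent from data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra_cols <- setdiff(item_cols, items$item_id)
  if (length(extra_cols)) {
    abort(paste0("Data columns not declared in items: ",
                 paste(extra_cols, collapse = ", ")))
  }
  data <- data[c("subject_id", "label", items$item_id)]
  data$subject_id <- as.character(data$subject_id)
  data$label <- as.integer(data$label)
  for (id in items$item_id) data[[id]] <- as.integer(data[[id]])
  new_item_table(data, items, subsample_tag)
}

#' @export
print.item_tbl <- function(x, ...) {
  defs <- item_info(x)
  cat(sprintf("<item_tbl> %d subjects x %d items (%d ADOS, %d ADIR), %d ASD / %d non-ASD\n",
              nrow(x), nrow(defs),
              sum(defs$instrument == "ADOS"), sum(defs$instrument == "ADIR"),
              sum(x$label == 1L), sum(x$label == 0L)))
  if (!is.null(attr(x, "subsample_tag"))) {
    cat("subsample:", attr(x, "subsample_tag"), "\n")
  }
  NextMethod()
}

#' Item metadata of an `item_tbl`
#' @param table An `item_tbl`.
#' @return The item-definition tibble carried by the table.
#' @export
item_info <- function(table) {
  defs <- attr(table, "items")
  if (is.null(defs)) abort("not an item_tbl: no item metadata attached")
  defs
}

#' Item identifiers of an `item_tbl`, in schema order
#' @inheritParams item_info
#' @export
item_ids <- function(table) item_info(table)$item_id

# subjects x items integer matrix, schema column order
code_matrix <- function(table) {
  m <- as.matrix(table[item_ids(table)])
  rownames(m) <- table$subject_id
  m
}

#' Recode special and top-severity item codes
#'
#' Applies the instrument-manual remapping used before any modelling:
#' special codes 7 and 8 (peculiar/abnormal behaviour, not severity) become
#' 0, and the top severity code 3 collapses into 2. Codes 0, 1, 2 and
#' missing entries pass through unchanged, so the operation is idempotent
#' and its image is {0, 1, 2, NA}.
#'
#' @param table An `item_tbl`.
#' @return A new `item_tbl` with recoded codes.
#' @export
#' @examples
#' tbl <- item_table(data.frame(subject_id = c("a", "b"), label = c(1, 0),
#'                              QSOV = c(3L, 7L)))
#' recode_item_codes(tbl)$QSOV  # 2, 0
recode_item_codes <- function(table) {
  defs <- item_info(table)
  for (id in defs$item_id) {
    v <- table[[id]]
    bad <- !is.na(v) & !v %in% .allowed_raw_codes
    if (any(bad)) {
      abort(sprintf("Invalid code %s for item %s, subject %s",
                    v[bad][1], id, table$subject_id[bad][1]))
    }
    v[v %in% c(7L, 8L)] <- 0L
    v[v == 3L] <- 2L
    table[[id]] <- v
  }
  new_item_table(table, defs, attr(table, "subsample_tag"))
}

#' Restrict a table to the items entering the analysis
#'
#' Keeps every ADOS item and, among ADI-R items, only diagnostic-algorithm
#' items outside domain D (abnormality of development evident at or before
#' 36 months), which do not address ASD symptomatology itself.
#'
#' @param table An `item_tbl`.
#' @return A new `item_tbl` containing the retained items only.
#' @export
select_algorithm_items <- function(table) {
  defs <- item_info(table)
  adir <- defs$instrument == "ADIR"
  if (any(adir & is.na(defs$in_algorithm))) {
    abort(paste0("ADI-R item(s) lack algorithm-membership metadata: ",
                 paste(defs$item_id[adir & is.na(defs$in_algorithm)],
                       collapse = ", ")))
  }
  keep <- defs$instrument == "ADOS" |
    (adir & defs$in_algorithm & (is.na(defs$domain_tag) | defs$domain_tag != "D"))
  kept <- defs[keep, ]
  new_item_table(table[c("subject_id", "label", kept$item_id)], kept,
                 attr(table, "subsample_tag"))
}
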