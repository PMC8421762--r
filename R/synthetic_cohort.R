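#' Specify a synthetic diagnostic cohort
#'
#' Describes a latent-Gaussian (graded/probit) generator for subject-by-item
#' ordinal tables with known ground truth. Each subject's class is Bernoulli
#' with the given prevalence; each item has a standard-normal latent
#' severity, shifted by `delta` (a standardized mean difference) in the
#' positive class for planted informative items; ordinal codes 0--3 arise by
#' thresholding the latent value at `cutpoints`. Special codes 7/8 are then
#' injected class-independently and entries masked missing completely at
#' random. The latent-scale single-item AUC has the closed form
#' `pnorm(delta / sqrt(2))`, which is what makes the generator usable as an
#' oracle for the ranking stages.
#'
#' @param items Item definitions ([item_defs()] tibble).
#' @param n_subjects Number of subjects.
#' @param prevalence Proportion in the positive (ASD) class, in (0, 1).
#' @param informative Named numeric vector of latent shifts `delta >= 0`,
#'   names being item ids; items not named are uninformative (`delta = 0`).
#' @param cutpoints Strictly increasing thresholds mapping latent values to
#'   codes 0/1/2/3. The default `qnorm(c(0.5, 0.75, 0.9))` puts roughly
#'   50/25/15/10% of the negative class on codes 0/1/2/3.
#' @param special_code_rate Probability an observed code is replaced by a
#'   special code (7 or 8, equiprobable), independent of class.
#' @param missing_rate Probability an entry is missing (MCAR).
#' @param missing_rate_positive Optional distinct missingness rate for the
#'   positive class (class-dependent missingness stress tests); default
#'   equal to `missing_rate`.
#' @param exact_prevalence If `TRUE`, draw exactly `round(prevalence * n)`
#'   positives instead of Bernoulli sampling.
#' @param seed Integer seed; generation is fully reproducible from it.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(items, n_subjects, prevalence = 0.46,
                        informative = numeric(0),
                        cutpoints = qnorm(c(0.5, 0.75, 0.9)),
                        special_code_rate = 0, missing_rate = 0,
                        missing_rate_positive = NULL,
                        exact_prevalence = FALSE, seed = 1L) {
  if (nrow(items) == 0L) abort("items must be non-empty")
  if (prevalence <= 0 || prevalence >= 1) abort("prevalence must be in (0, 1)")
  if (length(informative)) {
    if (is.null(names(informative)) || !all(names(informative) %in% items$item_id)) {
      abort("informative must be named by item ids present in items")
    }
    if (any(informative < 0)) abort("latent shifts delta must be >= 0")
  }
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    abort("cutpoints must be strictly increasing")
  }
  rates <- c(special_code_rate, missing_rate,
             missing_rate_positive %||% missing_rate)
  if (any(rates < 0 | rates >= 1)) abort("rates must lie in [0, 1)")
  structure(
    list(
      items = items,
      n_subjects = as.integer(n_subjects),
      prevalence = prevalence,
      informative = informative,
      cutpoints = cutpoints,
      special_code_rate = special_code_rate,
      missing_rate = missing_rate,
      missing_rate_positive = missing_rate_positive %||% missing_rate,
      exact_prevalence = isTRUE(exact_prevalence),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n=%d, prevalence=%.2f, %d items (%d informative), seed=%d\n",
    x$n_subjects, x$prevalence, nrow(x$items), length(x$informative), x$seed))
  cat(sprintf("special codes %.1f%%, missing %.1f%%\n",
              100 * x$special_code_rate, 100 * x$missing_rate))
  invisible(x)
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param spec A [cohort_spec()].
#' @param keep_latent If `TRUE`, the pre-thresholding latent matrix is
#'   returned as well (used by oracle tests of the closed-form latent AUC).
#'
#' @return A list with elements `table` (an `item_tbl` of raw, un-recoded
#'   codes), `truth` (a tibble of planted items ranked by `delta`
#'   descending, with the theoretical latent AUC `pnorm(delta / sqrt(2))`),
#'   and, when requested, `latent` (subjects x items numeric matrix).
#' @export
generate_cohort <- function(spec, keep_latent = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  p <- nrow(spec$items)
  ids <- spec$items$item_id
  delta <- setNames(numeric(p), ids)
  delta[names(spec$informative)] <- spec$informative

  out <- withr::with_seed(spec$seed, {
    label <- if (spec$exact_prevalence) {
      pos <- sample.int(n, round(spec$prevalence * n))
      as.integer(seq_len(n) %in% pos)
    } else {
      rbinom(n, 1L, spec$prevalence)
    }
    z <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, ids))
    z <- z + outer(as.numeric(label), delta)
    codes <- matrix(findInterval(z, spec$cutpoints), n, p,
                    dimnames = list(NULL, ids))
    if (spec$special_code_rate > 0) {
      hit <- runif(n * p) < spec$special_code_rate
      codes[hit] <- sample(c(7L, 8L), sum(hit), replace = TRUE)
    }
    miss_rate <- ifelse(label == 1L, spec$missing_rate_positive,
                        spec$missing_rate)
    gone <- matrix(runif(n * p), n, p) < miss_rate
    codes[gone] <- NA_integer_
    list(label = label, z = z, codes = codes)
  })

  data <- as_tibble(out$codes)
  data <- tibble(subject_id = sprintf("S%0*d", nchar(n), seq_len(n)),
                 label = as.integer(out$label)) |>
    dplyr::bind_cols(data)
  truth <- tibble(item_id = ids, delta = unname(delta)) |>
    filter(.data$delta > 0) |>
    mutate(latent_auc = pnorm(.data$delta / sqrt(2))) |>
    arrange(desc(.data$delta), .data$item_id)
  res <- list(table = item_table(data, spec$items), truth = truth)
  if (keep_latent) res$latent <- out$z
  res
}

#' Read / write a cohort specification as YAML
#'
#' @param path YAML file.
#' @return [read_cohort_spec()]: a `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  items <- bind_rows(lapply(y$items, as_tibble))
  if (!"domain_tag" %in% names(items)) items$domain_tag <- NA_character_
  cohort_spec(
    items = item_defs(items$item_id, items$instrument, items$in_algorithm,
                      items$domain_tag),
    n_subjects = y$n_subjects,
    prevalence = y$prevalence,
    informative = unlist(y$informative) %||% numeric(0),
    cutpoints = unlist(y$cutpoints),
    special_code_rate = y$special_code_rate %||% 0,
    missing_rate = y$missing_rate %||% 0,
    missing_rate_positive = y$missing_rate_positive,
    exact_prevalence = y$exact_prevalence %||% FALSE,
    seed = y$seed %||% 1L
  )
}

#' @rdname read_cohort_spec
#' @param spec A `cohort_spec`.
#' @return [write_cohort_spec()]: `path`, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  items <- purrr::pmap(spec$items, function(item_id, instrument, in_algorithm,
                                            domain_tag) {
    r <- list(item_id = item_id, instrument = instrument,
              in_algorithm = in_algorithm)
    if (!is.na(domain_tag)) r$domain_tag <- domain_tag
    r
  })
  y <- list(
    n_subjects = spec$n_subjects,
    prevalence = spec$prevalence,
    items = items,
    informative = as.list(spec$informative),
    cutpoints = as.numeric(spec$cutpoints),
    special_code_rate = spec$special_code_rate,
    missing_rate = spec$missing_rate,
    missing_rate_positive = spec$missing_rate_positive,
    exact_prevalence = spec$exact_prevalence,
    seed = spec$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
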