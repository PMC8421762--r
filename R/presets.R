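# Item vocabularies for the four emulated subsample/instrument layouts.
# Abbreviations follow the instruments' published short names where a
# well-known one exists; the cohorts built on them are synthetic.

ados_m3_item_ids <- function() {
  c(
    # language & communication
    "OLANG", "SPAB", "IECHO", "STER", "ORINF", "ASKINF", "REPRT", "CONV",
    "DGES",
    # reciprocal social interaction
    "EYE", "EXPE", "LNVC", "SHRNJ", "EMO", "INS", "QSOV", "QSR", "ARSC",
    "QRAP",
    # imagination
    "IMAG",
    # stereotyped behaviours & restricted interests
    "USEN", "MAN", "SELFINJ", "EXIN", "COMP",
    # other behaviours
    "OVERA", "AGG", "ANX"
  )
}

ados_m4_item_ids <- function() {
  c(ados_m3_item_ids(), "EMPGES", "RESP", "DLIFE")
}

adir_algorithm_item_ids <- function() {
  list(
    A = c("DIRGAZ", "SOCSMI", "RANGEX", "INTCHI", "RESPCH", "GRPLAY",
          "FRNDS", "SHOATT", "OFFCOM", "SEEKSH", "OFFSEE", "QSOCOV",
          "APPSOC", "IMSOPL", "USEBOD", "INAPPF"),
    B = c("PTRINT", "NODHED", "SHAKHD", "CONGES", "SPONIM", "IMGPLY",
          "IMGPEE", "RECCON", "SOCVOC", "SOCCHT", "STERUT", "IDIOPH",
          "VERRIT"),
    C = c("CIRINT", "UNPREO", "COMPUL", "HANDFM", "COMPLM", "REPOBJ",
          "SENSIN", "UNDGES")
  )
}

adir_item_defs <- function() {
  doms <- adir_algorithm_item_ids()
  item_defs(unlist(doms, use.names = FALSE), instrument = "ADIR",
            in_algorithm = TRUE,
            domain_tag = rep(names(doms), lengths(doms)))
}

#' Preset cohort specifications for the four model families
#'
#' Returns a ready-made [cohort_spec()] emulating one of the four
#' subsample/instrument layouts: ADOS module 3 alone (28 items), ADOS
#' module 4 alone (31 items), or either module combined with the 37 ADI-R
#' algorithm items outside domain D (65 and 68 items). Defaults plant seven
#' informative ADOS items with latent shifts `delta` falling from 2.0 to
#' 0.8 (and, for combined presets, four ADI-R items at 1.2 down to 0.6),
#' prevalence 0.46, 5% special codes and 10% missingness — a cohort with a
#' strong but tapering signal concentrated in few items.
#'
#' @param name One of `"children_m3_ados"`, `"adults_m4_ados"`,
#'   `"children_m3_combined"`, `"adults_m4_combined"`.
#' @param n_subjects Cohort size, default 1500.
#' @param prevalence Positive-class proportion, default 0.46.
#' @param special_code_rate,missing_rate Injection rates, defaults 0.05 and
#'   0.10.
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
#' @examples
#' nrow(module_preset("children_m3_ados")$items)  # 28
module_preset <- function(name, n_subjects = 1500, prevalence = 0.46,
                          special_code_rate = 0.05, missing_rate = 0.10,
                          seed = 1L) {
  name <- match.arg(name, c("children_m3_ados", "adults_m4_ados",
                            "children_m3_combined", "adults_m4_combined"))
  children <- grepl("children", name)
  ados <- item_defs(if (children) ados_m3_item_ids() else ados_m4_item_ids(),
                    instrument = "ADOS")
  planted_ados <- if (children) {
    c("QSOV", "ARSC", "STER", "CONV", "EXPE", "INS", "SPAB")
  } else {
    c("QSR", "EMO", "QSOV", "ARSC", "EYE", "EXPE", "SPAB")
  }
  informative <- setNames(seq(2.0, 0.8, length.out = 7), planted_ados)
  items <- ados
  if (grepl("combined", name)) {
    items <- bind_rows(ados, adir_item_defs())
    planted_adir <- if (children) {
      c("RECCON", "IMSOPL", "INTCHI", "SHOATT")
    } else {
      c("SHOATT", "PTRINT", "RECCON", "INTCHI")
    }
    informative <- c(informative,
                     setNames(seq(1.2, 0.6, length.out = 4), planted_adir))
  }
  cohort_spec(
    items = items, n_subjects = n_subjects, prevalence = prevalence,
    informative = informative, special_code_rate = special_code_rate,
    missing_rate = missing_rate, seed = seed
  )
}
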