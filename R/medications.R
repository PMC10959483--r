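#' Built-in anti-seizure medication dictionary
#'
#' Generic drug names with a putative main mechanism-of-action class and
#' a rescue (benzodiazepine) flag. Site formularies differ, so this ships
#' as an editable table: pass your own to the analysis functions.
#'
#' @return Tibble `drug`, `drug_class`, `is_asm`, `is_rescue`.
#' @export
asm_dictionary <- function() {
  tibble::tribble(
    ~drug,             ~drug_class,          ~is_asm, ~is_rescue,
    "levetiracetam",   "sv2a",               TRUE,    FALSE,
    "brivaracetam",    "sv2a",               TRUE,    FALSE,
    "valproic acid",   "broad_spectrum",     TRUE,    FALSE,
    "topiramate",      "broad_spectrum",     TRUE,    FALSE,
    "zonisamide",      "broad_spectrum",     TRUE,    FALSE,
    "lamotrigine",     "sodium_channel",     TRUE,    FALSE,
    "oxcarbazepine",   "sodium_channel",     TRUE,    FALSE,
    "carbamazepine",   "sodium_channel",     TRUE,    FALSE,
    "lacosamide",      "sodium_channel",     TRUE,    FALSE,
    "phenytoin",       "sodium_channel",     TRUE,    FALSE,
    "rufinamide",      "sodium_channel",     TRUE,    FALSE,
    "phenobarbital",   "gaba_a",             TRUE,    FALSE,
    "vigabatrin",      "gaba_transaminase",  TRUE,    FALSE,
    "felbamate",       "nmda",               TRUE,    FALSE,
    "perampanel",      "ampa",               TRUE,    FALSE,
    "ethosuximide",    "t_type_calcium",     TRUE,    FALSE,
    "cannabidiol",     "other",              TRUE,    FALSE,
    "clobazam",        "benzodiazepine",     TRUE,    TRUE,
    "clonazepam",      "benzodiazepine",     TRUE,    TRUE,
    "diazepam",        "benzodiazepine",     TRUE,    TRUE,
    "lorazepam",       "benzodiazepine",     TRUE,    TRUE,
    "midazolam",       "benzodiazepine",     TRUE,    TRUE
  )
}

#' Filter drugs by cohort prevalence
#'
#' Retains drugs prescribed to at least `threshold` of the cohort,
#' counting distinct exposed persons against `ceiling(threshold *
#' cohort_size)`. With the default 1% and a cohort of 503, a drug needs
#' 6 exposed persons (5 is 0.99%).
#'
#' @param prescriptions Data frame `person_id`, `drug`.
#' @param cohort_size Number of persons in the study cohort.
#' @param threshold Minimum exposed fraction (default 0.01).
#' @return Character vector of retained drug names.
#' @export
filter_asm_by_prevalence <- function(prescriptions, cohort_size,
                                     threshold = 0.01) {
  stopifnot(cohort_size > 0)
  need <- ceiling(threshold * cohort_size)
  prescriptions |>
    dplyr::distinct(.data$drug, .data$person_id) |>
    dplyr::count(.data$drug) |>
    dplyr::filter(.data$n >= need) |>
    dplyr::pull("drug")
}

#' Unique anti-seizure medications per person
#'
#' Number of distinct ASM generic names ever prescribed per person, with
#' a Welch t-test case-control contrast. Persons on the roster without
#' prescriptions count 0.
#'
#' @param prescriptions Data frame `person_id`, `drug`, `is_asm`.
#' @param persons Data frame `person_id`, `group`.
#' @return List: `per_person` (tibble `person_id`, `group`,
#'   `n_unique_asm`), `contrast` (one-row [welch_t_test()] tibble,
#'   cases as `x`).
#' @export
unique_asm_count <- function(prescriptions, persons) {
  counts <- prescriptions |>
    dplyr::filter(.data$is_asm) |>
    dplyr::distinct(.data$person_id, .data$drug) |>
    dplyr::count(.data$person_id, name = "n_unique_asm")
  per_person <- persons |>
    dplyr::select("person_id", "group") |>
    dplyr::left_join(counts, by = "person_id") |>
    dplyr::mutate(n_unique_asm = dplyr::coalesce(.data$n_unique_asm, 0L))
  list(per_person = per_person,
       contrast = group_contrast(per_person, "n_unique_asm"))
}

#' Rescue-medication prescriptions per person
#'
#' Number of prescription events (not distinct drugs) in the
#' benzodiazepine/rescue class per person, with a Welch t-test contrast.
#'
#' @param prescriptions Data frame `person_id`, `drug_class` (rescue
#'   events have `drug_class == "benzodiazepine"`) or a logical
#'   `is_rescue` column.
#' @param persons Data frame `person_id`, `group`.
#' @return List: `per_person` (tibble `person_id`, `group`, `n_rescue`),
#'   `contrast`.
#' @export
rescue_prescription_count <- function(prescriptions, persons) {
  is_rescue <- if ("is_rescue" %in% names(prescriptions)) {
    prescriptions$is_rescue
  } else {
    prescriptions$drug_class == "benzodiazepine"
  }
  counts <- prescriptions[is_rescue, ] |>
    dplyr::count(.data$person_id, name = "n_rescue")
  per_person <- persons |>
    dplyr::select("person_id", "group") |>
    dplyr::left_join(counts, by = "person_id") |>
    dplyr::mutate(n_rescue = dplyr::coalesce(.data$n_rescue, 0L))
  list(per_person = per_person,
       contrast = group_contrast(per_person, "n_rescue"))
}

#' Age-binned prescription enrichment scan
#'
#' For each age bin and each drug passing the prevalence filter, builds
#' the 2x2 table of any-exposure in that bin by group and applies
#' Fisher's exact test with per-bin Bonferroni correction over the drugs
#' tested in the bin. Output rows are grouped by mechanism class for
#' heatmap display.
#'
#' @param prescriptions Data frame `person_id`, `age_years`, `drug`,
#'   `drug_class`.
#' @param persons Data frame `person_id`, `group`.
#' @param threshold Cohort-prevalence filter passed to
#'   [filter_asm_by_prevalence()] (default 0.01).
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `drug_class`, `drug`, `bin`, `a`, `b`, `c`, `d`,
#'   `or`, `ci_low`, `ci_high`, `p`, `p_adj`.
#' @export
binned_prescription_scan <- function(prescriptions, persons,
                                     threshold = 0.01, alpha = 0.05) {
  keep <- filter_asm_by_prevalence(prescriptions, nrow(persons), threshold)
  rx <- prescriptions |>
    dplyr::filter(.data$drug %in% keep) |>
    dplyr::mutate(bin = assign_age_bin(.data$age_years))
  grp <- dplyr::select(persons, "person_id", "group")
  n_case <- sum(grp$group == "case")
  n_ctrl <- sum(grp$group == "control")
  classes <- dplyr::distinct(rx, .data$drug, .data$drug_class)
  exposure <- rx |>
    dplyr::distinct(.data$bin, .data$drug, .data$person_id) |>
    dplyr::inner_join(grp, by = "person_id") |>
    dplyr::count(.data$bin, .data$drug, .data$group) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L)
  for (col in c("case", "control")) {
    if (!col %in% names(exposure)) exposure[[col]] <- 0L
  }
  res <- exposure |>
    dplyr::mutate(a = .data$case, b = n_case - .data$case,
                  c = .data$control, d = n_ctrl - .data$control) |>
    dplyr::mutate(purrr::pmap_dfr(
      list(.data$a, .data$b, .data$c, .data$d),
      function(a, b, c, d) {
        r <- fisher_core(a, b, c, d)
        tibble::tibble(or = r$or, ci_low = r$ci_low, ci_high = r$ci_high,
                       p = r$p)
      }
    )) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(p_adj = bonferroni_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::left_join(classes, by = "drug") |>
    dplyr::select("drug_class", "drug", "bin", "a", "b", "c", "d",
                  "or", "ci_low", "ci_high", "p", "p_adj") |>
    dplyr::arrange(.data$drug_class, .data$drug, .data$bin)
  res
}

# Welch contrast of a per-person column, cases as x; NULL when a group
# has fewer than 2 persons
group_contrast <- function(per_person, col) {
  x <- per_person[[col]][per_person$group == "case"]
  y <- per_person[[col]][per_person$group == "control"]
  if (length(x) < 2 || length(y) < 2) return(NULL)
  welch_t_test(x, y)
}
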