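#' Eligibility screen for childhood-onset epilepsy
#'
#' A person is eligible when they have (i) any epilepsy billing code
#' (ICD-10 `G40*` or ICD-9 `345*`), (ii) any EEG procedure (CPT) code,
#' and (iii) an age at the first epilepsy billing code inside
#' `diagnosis_age_range` (half-open `[lo, hi]` treated as inclusive at
#' both ends, default 0-5 years). EEG CPT codes are site-specific and
#' supplied as a configuration list.
#'
#' @param events Data frame of coded events: `person_id`, `age_years`,
#'   `code_system` (`ICD10`, `ICD9`, `CPT`, `UMLS`), `code`.
#' @param eeg_codes Character vector of CPT codes counted as EEG.
#' @param diagnosis_age_range Numeric length-2; age window (years) for
#'   the first epilepsy code.
#' @return Tibble, one row per person appearing in `events`:
#'   `person_id`, `has_epilepsy_code`, `has_eeg`, `age_first_epilepsy`
#'   (NA when no epilepsy code), `eligible`.
#' @export
apply_eligibility <- function(events, eeg_codes,
                              diagnosis_age_range = c(0, 5)) {
  stopifnot(all(c("person_id", "age_years", "code_system", "code") %in%
                  names(events)),
            length(diagnosis_age_range) == 2)
  is_epi <- (events$code_system == "ICD10" &
               startsWith(events$code, "G40")) |
    (events$code_system == "ICD9" & startsWith(events$code, "345"))
  is_eeg <- events$code_system == "CPT" & events$code %in% eeg_codes
  epi <- events[is_epi, ] |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(age_first_epilepsy = min(.data$age_years),
                     .groups = "drop")
  out <- tibble::tibble(person_id = unique(events$person_id)) |>
    dplyr::left_join(epi, by = "person_id") |>
    dplyr::mutate(
      has_epilepsy_code = !is.na(.data$age_first_epilepsy),
      has_eeg = .data$person_id %in% events$person_id[is_eeg],
      eligible = .data$has_epilepsy_code & .data$has_eeg &
        .data$age_first_epilepsy >= diagnosis_age_range[1] &
        .data$age_first_epilepsy <= diagnosis_age_range[2]
    ) |>
    dplyr::relocate("age_first_epilepsy", .after = "has_eeg")
  out$eligible[is.na(out$eligible)] <- FALSE
  out
}

#' Exclude persons with undated encounters
#'
#' Persons with any encounter missing an age/date annotation are removed
#' outright (no imputation), mirroring conservative handling of
#' encounter-date quality problems.
#'
#' @param persons Data frame with a `person_id` column.
#' @param encounters Data frame with `person_id` and `age_years` columns.
#' @return List: `persons` and `encounters` restricted to retained
#'   persons, and `exclusions`, a tibble `person_id`, `n_missing` of the
#'   removed persons and their undated-encounter counts.
#' @export
drop_missing_dates <- function(persons, encounters) {
  stopifnot("person_id" %in% names(persons),
            all(c("person_id", "age_years") %in% names(encounters)))
  excl <- encounters |>
    dplyr::filter(is.na(.data$age_years)) |>
    dplyr::count(.data$person_id, name = "n_missing")
  keep_p <- dplyr::filter(persons, !.data$person_id %in% excl$person_id)
  keep_e <- dplyr::filter(encounters, !.data$person_id %in% excl$person_id)
  list(persons = keep_p, encounters = keep_e,
       exclusions = tibble::as_tibble(excl))
}

#' Collapse repeated codes within a time window
#'
#' Exact duplicate events are removed, then, within each (person, code),
#' events are merged transitively whenever consecutive occurrences are at
#' most `window_days` apart; each merged run keeps its earliest age.
#' This absorbs billing artefacts where the same concept is re-coded over
#' a short period (late documentation, lab results) — the one-month
#' grouping rule.
#'
#' @param events Data frame with `person_id`, `age_years`, `code` (other
#'   columns are preserved from the earliest event of each run).
#' @param window_days Merge window in days (default 30; must be >= 0).
#' @return Tibble with the same columns, one row per retained event.
#' @export
collapse_events <- function(events, window_days = 30) {
  if (window_days < 0) stop("window_days must be >= 0", call. = FALSE)
  stopifnot(all(c("person_id", "age_years", "code") %in% names(events)))
  window_years <- window_days / 365.25
  events |>
    dplyr::distinct() |>
    dplyr::arrange(.data$person_id, .data$code, .data$age_years) |>
    dplyr::group_by(.data$person_id, .data$code) |>
    dplyr::mutate(
      gap = .data$age_years - dplyr::lag(.data$age_years),
      run = cumsum(is.na(.data$gap) | .data$gap > window_years)
    ) |>
    dplyr::group_by(.data$person_id, .data$code, .data$run) |>
    dplyr::slice_min(.data$age_years, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"gap", -"run")
}

#' Person-by-term indicator matrix
#'
#' Builds the binary presence/absence matrix consumed by
#' [phenome_scan()]. Columns are ordered lexicographically by term id,
#' rows follow the person roster; a person annotated at any age counts as
#' a carrier.
#'
#' @param annotations Data frame `person_id`, `term` (typically
#'   propagated; see [propagate_annotations()]).
#' @param persons Data frame with `person_id`, the full roster (persons
#'   without annotations get all-zero rows).
#' @return Sparse logical-pattern matrix (`Matrix::sparseMatrix`) with
#'   person ids as row names, term ids as column names.
#' @export
person_term_matrix <- function(annotations, persons) {
  stopifnot(all(c("person_id", "term") %in% names(annotations)),
            "person_id" %in% names(persons))
  roster <- persons$person_id
  extra <- setdiff(unique(annotations$person_id), roster)
  if (length(extra) > 0) {
    stop("annotations for persons absent from the roster: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  terms <- sort(unique(annotations$term))
  ann <- dplyr::distinct(annotations, .data$person_id, .data$term)
  Matrix::sparseMatrix(
    i = match(ann$person_id, roster),
    j = match(ann$term, terms),
    x = 1,
    dims = c(length(roster), length(terms)),
    dimnames = list(roster, terms)
  )
}

#' Propensity-score case-control matching
#'
#' Estimates the propensity of case status by logistic regression on the
#' matching covariates, then performs greedy 1:1 nearest-neighbour
#' matching without replacement on the propensity score. Cases are
#' processed in descending propensity order (hardest-to-match first);
#' distance ties between candidate controls, and propensity ties between
#' cases, are broken by person id, which makes the result invariant to
#' input row order.
#'
#' @param persons Data frame with `person_id`, `group`
#'   (`"case"`/`"control"`) and the covariate columns.
#' @param covariates Character vector of covariate column names (default
#'   sex, encounter-median age, ancestry).
#' @return Object of class `matched_cohort`: list with `pairs` (tibble
#'   `case_id`, `control_id`, `distance`), `propensity` (tibble
#'   `person_id`, `propensity`), `balance` (tibble of standardized mean
#'   differences before/after matching per covariate level),
#'   `covariates`, and `unmatched_cases` (character). A control shortage
#'   produces partial matching with a warning.
#' @export
match_cohorts <- function(persons,
                          covariates = c("sex", "age_median", "ancestry")) {
  stopifnot(all(c("person_id", "group") %in% names(persons)),
            all(covariates %in% names(persons)))
  df <- persons |>
    dplyr::filter(.data$group %in% c("case", "control")) |>
    dplyr::arrange(.data$person_id) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(covariates),
      \(x) if (is.character(x)) factor(x) else x
    ))
  if (sum(df$group == "case") < 1 || sum(df$group == "control") < 1) {
    stop("need at least one case and one control", call. = FALSE)
  }
  # covariates without variation carry no information and break the glm
  informative <- covariates[vapply(covariates, function(v) {
    length(unique(df[[v]])) > 1
  }, logical(1))]
  if (length(informative) == 0) {
    df$propensity <- mean(df$group == "case")
  } else {
    form <- stats::as.formula(
      paste("I(group == 'case') ~", paste(informative, collapse = " + ")))
    fit <- stats::glm(form, family = stats::binomial(), data = df)
    df$propensity <- stats::fitted(fit)
  }
  cases <- df[df$group == "case", ] |>
    dplyr::arrange(dplyr::desc(.data$propensity), .data$person_id)
  controls <- df[df$group == "control", ]
  avail <- stats::setNames(controls$propensity, controls$person_id)
  avail <- avail[order(names(avail))]
  pairs <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    if (length(avail) == 0) break
    dist <- abs(avail - cases$propensity[i])
    j <- which(dist == min(dist))[1]  # names sorted: id tie-break
    pairs[[i]] <- tibble::tibble(case_id = cases$person_id[i],
                                 control_id = names(avail)[j],
                                 distance = unname(dist[j]))
    avail <- avail[-j]
  }
  pairs <- dplyr::bind_rows(pairs)
  unmatched <- setdiff(cases$person_id, pairs$case_id)
  if (length(unmatched) > 0) {
    warning(length(unmatched), " case(s) left unmatched: fewer controls ",
            "than cases")
  }
  matched_ids <- c(pairs$case_id, pairs$control_id)
  balance <- covariate_balance(df, covariates, matched_ids)
  structure(
    list(pairs = pairs,
         propensity = tibble::tibble(person_id = df$person_id,
                                     propensity = df$propensity),
         balance = balance,
         covariates = covariates,
         unmatched_cases = unmatched),
    class = "matched_cohort"
  )
}

# standardized mean differences (binary indicators for factor levels)
covariate_balance <- function(df, covariates, matched_ids) {
  expand <- function(data) {
    cols <- lapply(covariates, function(v) {
      x <- data[[v]]
      if (is.factor(x) || is.character(x)) {
        lv <- levels(factor(df[[v]]))
        out <- lapply(lv, function(l) as.numeric(x == l))
        stats::setNames(out, paste0(v, ":", lv))
      } else {
        stats::setNames(list(as.numeric(x)), v)
      }
    })
    tibble::as_tibble(c(list(group = data$group), unlist(cols,
                                                         recursive = FALSE)))
  }
  smd <- function(data) {
    ex <- expand(data)
    vars <- setdiff(names(ex), "group")
    purrr::map_dbl(vars, function(v) {
      x <- ex[[v]][ex$group == "case"]
      y <- ex[[v]][ex$group == "control"]
      s <- sqrt((stats::var(x) + stats::var(y)) / 2)
      if (is.na(s) || s == 0) {
        if (isTRUE(all.equal(mean(x), mean(y)))) 0 else Inf
      } else {
        (mean(x) - mean(y)) / s
      }
    }) |> stats::setNames(vars)
  }
  pre <- smd(df)
  post <- smd(dplyr::filter(df, .data$person_id %in% matched_ids))
  tibble::tibble(covariate = names(pre), smd_pre = unname(pre),
                 smd_post = unname(post))
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("<matched_cohort> ", nrow(x$pairs), " matched pairs on ",
      paste(x$covariates, collapse = ", "), "\n", sep = "")
  if (length(x$unmatched_cases) > 0) {
    cat("  unmatched cases: ", length(x$unmatched_cases), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.matched_cohort <- function(x, ...) x$pairs

#' @export
glance.matched_cohort <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_unmatched_cases = length(x$unmatched_cases),
    max_abs_smd_pre = max(abs(x$balance$smd_pre)),
    max_abs_smd_post = max(abs(x$balance$smd_post))
  )
}

#' Add encounter-median age to a person table
#'
#' The matching covariate "median age" is the median of the person's
#' encounter ages.
#'
#' @param persons Data frame with `person_id`.
#' @param encounters Data frame with `person_id`, `age_years`.
#' @return `persons` with an `age_median` column (NA for persons without
#'   encounters).
#' @export
add_median_age <- function(persons, encounters) {
  med <- encounters |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(age_median = stats::median(.data$age_years),
                     .groups = "drop")
  dplyr::left_join(persons, med, by = "person_id")
}

#' Follow-up summary
#'
#' Per-person first/last encounter age, follow-up span and encounter
#' count. Persons on the roster with no encounters get NA span.
#'
#' @param encounters Data frame with `person_id`, `age_years`.
#' @param persons Optional roster data frame with `person_id`.
#' @return Tibble `person_id`, `first_age`, `last_age`, `span`,
#'   `n_encounters`.
#' @export
followup_summary <- function(encounters, persons = NULL) {
  fs <- encounters |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(first_age = min(.data$age_years),
                     last_age = max(.data$age_years),
                     span = max(.data$age_years) - min(.data$age_years),
                     n_encounters = dplyr::n(),
                     .groups = "drop")
  if (!is.null(persons)) {
    fs <- tibble::tibble(person_id = persons$person_id) |>
      dplyr::left_join(fs, by = "person_id") |>
      dplyr::mutate(n_encounters = dplyr::coalesce(.data$n_encounters, 0L))
  }
  fs
}

#' Cohort-level follow-up aggregates
#'
#' @param fs Output of [followup_summary()].
#' @return One-row tibble: mean/median/SD of span, cumulative
#'   person-years (sum of spans), mean and median encounters per person.
#' @export
followup_aggregates <- function(fs) {
  tibble::tibble(
    n_persons = nrow(fs),
    mean_span = mean(fs$span, na.rm = TRUE),
    median_span = stats::median(fs$span, na.rm = TRUE),
    sd_span = stats::sd(fs$span, na.rm = TRUE),
    person_years = sum(fs$span, na.rm = TRUE),
    mean_encounters = mean(fs$n_encounters),
    median_encounters = stats::median(fs$n_encounters)
  )
}
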