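events_row <- function(id, age, system, code) {
  tibble::tibble(person_id = id, age_years = age, code_system = system,
                 code = code)
}

test_that("eligibility needs epilepsy code, EEG and early first diagnosis", {
  ev <- dplyr::bind_rows(
    events_row("ok", 3.0, "ICD10", "G40.9"),
    events_row("ok", 3.1, "CPT", "EEG1"),
    events_row("late", 7.0, "ICD10", "G40.1"),
    events_row("late", 7.1, "CPT", "EEG1"),
    events_row("noeeg", 2.0, "ICD10", "G40.9"),
    events_row("icd9", 4.0, "ICD9", "345.1"),
    events_row("icd9", 4.5, "CPT", "EEG1"))
  el <- apply_eligibility(ev, eeg_codes = "EEG1")
  elig <- el$person_id[el$eligible]
  expect_setequal(elig, c("ok", "icd9"))
  expect_equal(el$age_first_epilepsy[el$person_id == "ok"], 3.0)

  # monotone: adding events never removes eligibility
  more <- dplyr::bind_rows(ev, events_row("noeeg", 4.9, "CPT", "EEG1"))
  el2 <- apply_eligibility(more, eeg_codes = "EEG1")
  expect_true(all(elig %in% el2$person_id[el2$eligible]))
})

test_that("persons with undated encounters are dropped and reported", {
  persons <- tibble::tibble(person_id = sprintf("p%d", 1:10))
  enc <- tibble::tibble(
    person_id = c(sprintf("p%d", 1:10), "p3"),
    age_years = c(rep(1, 10), NA))
  out <- drop_missing_dates(persons, enc)
  expect_equal(nrow(out$persons), 9)
  expect_false("p3" %in% out$persons$person_id)
  expect_equal(out$exclusions$n_missing, 1)

  clean <- drop_missing_dates(persons, enc[1:10, ])
  expect_equal(clean$persons, persons)
  expect_equal(nrow(clean$exclusions), 0)

  all_na <- drop_missing_dates(
    persons, tibble::tibble(person_id = persons$person_id,
                            age_years = NA_real_))
  expect_equal(nrow(all_na$persons), 0)
  expect_equal(nrow(all_na$exclusions), 10)
})

test_that("collapse_events merges transitively within the window", {
  d <- 1 / 365.25
  ev <- function(ages) tibble::tibble(person_id = "p", code = "X",
                                      code_system = "UMLS",
                                      age_years = ages * d)
  expect_equal(nrow(collapse_events(ev(c(0, 10)))), 1)
  expect_equal(collapse_events(ev(c(0, 10)))$age_years, 0)
  expect_equal(nrow(collapse_events(ev(c(0, 40)))), 2)
  # transitive chain: 0-25-50 merges although 0 and 50 are > 30 d apart
  expect_equal(nrow(collapse_events(ev(c(0, 25, 50)))), 1)
  # duplicates removed first
  expect_equal(nrow(collapse_events(ev(c(0, 0, 40, 40)))), 2)
  expect_error(collapse_events(ev(0), window_days = -1), ">= 0")
})

test_that("collapse_events matches a brute-force interval-union oracle", {
  oracle_runs <- function(days, window) {
    days <- sort(unique(days))
    sum(c(TRUE, diff(days) > window))
  }
  set.seed(42)
  for (i in 1:25) {
    days <- sort(sample(0:400, sample(2:12, 1), replace = TRUE))
    ev <- tibble::tibble(person_id = "p", code = "X",
                         age_years = days / 365.25)
    got <- collapse_events(ev, window_days = 30)
    expect_equal(nrow(got), oracle_runs(days, 30))
    # idempotent, never grows
    again <- collapse_events(got, window_days = 30)
    expect_equal(nrow(again), nrow(got))
    expect_lte(nrow(got), length(unique(days)))
  }
})

test_that("person_term_matrix is binary with lexicographic columns", {
  persons <- tibble::tibble(person_id = c("p1", "p2", "p3"))
  ann <- tibble::tibble(
    person_id = c("p1", "p1", "p1", "p2"),
    term = c("T:B", "T:A", "T:root", "T:A"))
  m <- person_term_matrix(ann, persons)
  expect_equal(dim(m), c(3, 3))
  expect_equal(colnames(m), sort(unique(ann$term)))
  expect_equal(sum(m["p1", ]), 3)
  expect_equal(sum(m["p3", ]), 0)
  # column sums equal independent tallies
  tally <- table(dplyr::distinct(ann)$term)
  expect_equal(as.numeric(Matrix::colSums(m)[names(tally)]),
               as.numeric(tally))
  expect_error(
    person_term_matrix(tibble::tibble(person_id = "px", term = "T:A"),
                       persons), "absent")
})

test_that("matching balances covariates and respects shortages", {
  # identical covariates -> all matched, zero post-match SMD
  p <- tibble::tibble(
    person_id = sprintf("p%02d", 1:20),
    group = rep(c("case", "control"), each = 10),
    sex = "female", age_median = 5, ancestry = "x")
  mc <- suppressWarnings(match_cohorts(p))
  expect_equal(nrow(mc$pairs), 10)
  expect_true(all(mc$balance$smd_post == 0))

  # 2 cases, 1 control -> partial matching with warning
  p2 <- tibble::tibble(
    person_id = c("c1", "c2", "k1"),
    group = c("case", "case", "control"),
    sex = c("f", "m", "f"), age_median = c(1, 2, 1), ancestry = "x")
  expect_warning(mc2 <- match_cohorts(p2), "unmatched")
  expect_equal(nrow(mc2$pairs), 1)
  expect_equal(length(mc2$unmatched_cases), 1)
})

test_that("matching reduces imbalance and ignores row order", {
  set.seed(9)
  p <- tibble::tibble(
    person_id = sprintf("p%02d", 1:40),
    group = rep(c("case", "control"), each = 20),
    sex = sample(c("f", "m"), 40, TRUE),
    age_median = c(rnorm(20, 6, 2), rnorm(20, 4, 2)),
    ancestry = sample(c("x", "y"), 40, TRUE))
  mc <- match_cohorts(p)
  expect_lte(max(abs(mc$balance$smd_post)) - 1e-9,
             max(abs(mc$balance$smd_pre)))
  shuffled <- p[sample(nrow(p)), ]
  mc2 <- match_cohorts(shuffled)
  expect_equal(dplyr::arrange(mc$pairs, case_id),
               dplyr::arrange(mc2$pairs, case_id))
})

test_that("follow-up summaries conserve person-years", {
  enc <- tibble::tibble(
    person_id = c("p1", "p1", "p2"),
    age_years = c(1, 3, 2))
  fs <- followup_summary(enc)
  expect_equal(fs$span[fs$person_id == "p1"], 2)
  expect_equal(fs$span[fs$person_id == "p2"], 0)
  agg <- followup_aggregates(fs)
  expect_equal(agg$person_years, sum(fs$span))

  roster <- tibble::tibble(person_id = c("p1", "p2", "p3"))
  fs2 <- followup_summary(enc, roster)
  expect_true(is.na(fs2$span[fs2$person_id == "p3"]))
  expect_equal(fs2$n_encounters[fs2$person_id == "p3"], 0)
})
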