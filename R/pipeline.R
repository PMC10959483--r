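#' Run the full phenome analysis pipeline
#'
#' Executes the end-to-end workflow on a directory of input tables (the
#' [write_fixtures()] dialect): cohort assembly (missing-date exclusion,
#' eligibility screen, one-month concept collapsing), propensity
#' matching, ontology mapping and propagation, the cross-sectional
#' phenome scan with inflation diagnostics, the age-binned longitudinal
#' scan and trajectory clustering, utilization and transition-window
#' analytics, and the medication analyses. All stage tables are written
#' as tab-separated text with a JSON run manifest; re-running with an
#' identical config reproduces identical tables.
#'
#' @param config Named list or path to a YAML file with entries:
#'   `input_dir` (directory holding `persons.csv`, `events.csv`,
#'   `encounters.csv`, optional `prescriptions.csv`, `toy.obo`,
#'   `concept_map.tsv`), `output_dir`, and optional `alpha` (0.05),
#'   `window_days` (30), `min_carriers` (1), `eeg_codes` (`"EEG1"`),
#'   `transition_range` (`c(12, 22)`), `match_covariates`
#'   (`c("sex", "age_median", "ancestry")`), `seed` (1).
#' @return Invisibly, a named list of the stage results; tables and
#'   `manifest.json` are written under `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(alpha = 0.05, window_days = 30, min_carriers = 1,
                   eeg_codes = "EEG1", transition_range = c(12, 22),
                   match_covariates = c("sex", "age_median", "ancestry"),
                   seed = 1)
  cfg <- utils::modifyList(defaults, config)
  for (key in c("input_dir", "output_dir")) {
    if (is.null(cfg[[key]])) stop("config misses '", key, "'", call. = FALSE)
  }
  for (f in c("persons.csv", "events.csv", "encounters.csv", "toy.obo",
              "concept_map.tsv")) {
    if (!file.exists(file.path(cfg$input_dir, f))) {
      stop("missing input file: ", file.path(cfg$input_dir, f),
           call. = FALSE)
    }
  }
  set.seed(cfg$seed)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- read_cohort_files(cfg$input_dir)
  g <- parse_obo(file.path(cfg$input_dir, "toy.obo"))
  cm <- read_concept_map(file.path(cfg$input_dir, "concept_map.tsv"), g)

  # cohort stage
  dropped <- drop_missing_dates(inputs$persons, inputs$encounters)
  persons <- dropped$persons
  elig <- apply_eligibility(
    dplyr::semi_join(inputs$events, persons, by = "person_id"),
    eeg_codes = cfg$eeg_codes)
  persons <- dplyr::semi_join(
    persons, dplyr::filter(elig, .data$eligible), by = "person_id")
  encounters <- dplyr::semi_join(dropped$encounters, persons,
                                 by = "person_id")
  events <- inputs$events |>
    dplyr::semi_join(persons, by = "person_id") |>
    dplyr::filter(!is.na(.data$age_years)) |>
    collapse_events(window_days = cfg$window_days)

  # matching
  matched <- match_cohorts(add_median_age(persons, encounters),
                           covariates = cfg$match_covariates)
  matched_ids <- c(matched$pairs$case_id, matched$pairs$control_id)
  persons <- dplyr::filter(persons, .data$person_id %in% matched_ids)
  encounters <- dplyr::semi_join(encounters, persons, by = "person_id")
  events <- dplyr::semi_join(events, persons, by = "person_id")

  # ontology stage
  ann_raw <- map_concepts(
    dplyr::filter(events, .data$code_system == "UMLS"), cm, g)
  ann <- propagate_annotations(ann_raw, g)
  mat <- person_term_matrix(ann, persons)

  # cross-sectional scan
  scan <- phenome_scan(mat, persons, min_carriers = cfg$min_carriers,
                       term_names = g$labels, alpha = cfg$alpha)
  infl <- inflation_lambda(scan$p, alpha = cfg$alpha)

  # longitudinal stage
  bscan <- binned_scan(ann, persons, persons,
                       min_carriers = cfg$min_carriers,
                       term_names = g$labels, alpha = cfg$alpha)
  tm <- trajectory_matrix(bscan, significant_only = TRUE,
                          alpha = cfg$alpha)
  clusters <- if (nrow(tm) >= 2) cluster_trajectories(tm) else NULL
  fu <- followup_summary(encounters, persons)
  util <- utilization_metrics(persons, encounters, ann_raw)
  trans <- transition_window(persons, encounters,
                             age_range = cfg$transition_range)
  enrich <- window_concept_enrichment(
    ann_raw, persons, window = unlist(trans$best[, c("lo", "hi")]),
    followup = fu)

  # medications
  meds <- NULL
  if (!is.null(inputs$prescriptions) && nrow(inputs$prescriptions) > 0) {
    rx <- dplyr::semi_join(inputs$prescriptions, persons, by = "person_id")
    meds <- list(
      unique_asm = unique_asm_count(rx, persons),
      rescue = rescue_prescription_count(rx, persons),
      bin_scan = binned_prescription_scan(rx, persons, alpha = cfg$alpha)
    )
  }

  results <- list(persons = persons, matched = matched, scan = scan,
                  inflation = infl, binned_scan = bscan,
                  trajectory = tm, clusters = clusters, followup = fu,
                  utilization = util, transition = trans,
                  window_enrichment = enrich, medications = meds,
                  exclusions = dropped$exclusions)

  write_stage_tables(results, cfg)
  invisible(results)
}

write_stage_tables <- function(results, cfg) {
  out <- cfg$output_dir
  wt <- function(df, name) {
    df <- dplyr::mutate(tibble::as_tibble(df), dplyr::across(
      dplyr::where(is.numeric), \(x) signif(x, 6)))
    readr::write_tsv(df, file.path(out, name))
  }
  wt(results$matched$pairs, "matched_pairs.tsv")
  wt(results$matched$balance, "matching_balance.tsv")
  wt(results$exclusions, "exclusions.tsv")
  wt(results$followup, "followup.tsv")
  wt(tibble::as_tibble(results$scan), "associations.tsv")
  wt(tibble::as_tibble(results$inflation), "inflation.tsv")
  wt(tibble::as_tibble(results$binned_scan), "binned_associations.tsv")
  tm <- results$trajectory
  if (nrow(tm) > 0) {
    tm_df <- tibble::as_tibble(tm, rownames = "term")
    if (!is.null(results$clusters)) {
      tm_df$cluster <- unname(
        results$clusters$clusters[tm_df$term])
    }
    wt(tm_df, "trajectory_matrix.tsv")
  }
  wt(results$utilization$contrasts, "utilization.tsv")
  wt(results$transition$windows, "transition_report.tsv")
  wt(results$window_enrichment, "transition_enrichment.tsv")
  if (!is.null(results$medications)) {
    wt(dplyr::bind_rows(
      dplyr::mutate(results$medications$unique_asm$contrast,
                    metric = "unique_asm", .before = 1),
      dplyr::mutate(results$medications$rescue$contrast,
                    metric = "rescue_prescriptions", .before = 1)),
      "asm_summary.tsv")
    wt(results$medications$bin_scan, "asm_bin_matrix.tsv")
  }
  manifest <- list(
    config = cfg[setdiff(names(cfg), c())],
    n_persons = nrow(results$persons),
    n_pairs = nrow(results$matched$pairs),
    n_terms_tested = attr(results$scan, "n_tests"),
    lambda = results$inflation$lambda,
    package_version = as.character(utils::packageVersion("epiphenome")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

#' Plot-ready tables from scan results
#'
#' Emits the coordinate tables behind the standard figures: QQ plot of
#' observed versus expected -log10 p (expected quantiles `(i - 0.5) / n`),
#' a frequency/effect scatter (per-term carrier frequencies by group with
#' significance flag), the trajectory heatmap matrix in long form, and
#' per-group annual encounter curves.
#'
#' @param scan A [phenome_scan()] result (optional).
#' @param binned A [binned_scan()] result (optional).
#' @param utilization A [utilization_metrics()] result (optional).
#' @param alpha Significance level for flags (default 0.05).
#' @return Named list of tibbles: any of `qq`, `scatter`, `heatmap`,
#'   `annual_curves`.
#' @export
make_figure_data <- function(scan = NULL, binned = NULL,
                             utilization = NULL, alpha = 0.05) {
  out <- list()
  if (!is.null(scan)) {
    p <- sort(scan$p)
    n <- length(p)
    out$qq <- tibble::tibble(
      expected = -log10((seq_len(n) - 0.5) / n),
      observed = -log10(p)
    )
    out$scatter <- tibble::as_tibble(scan) |>
      dplyr::mutate(
        freq_case = .data$a / (.data$a + .data$b),
        freq_control = .data$c / (.data$c + .data$d),
        significant = .data$p_adj < alpha
      ) |>
      dplyr::select("term", "name", "freq_case", "freq_control", "or",
                    "p_adj", "significant")
  }
  if (!is.null(binned)) {
    tm <- trajectory_matrix(binned, significant_only = TRUE, alpha = alpha)
    out$heatmap <- tibble::as_tibble(tm, rownames = "term") |>
      tidyr::pivot_longer(-"term", names_to = "bin",
                          values_to = "log_or")
  }
  if (!is.null(utilization)) {
    out$annual_curves <- utilization$annual |>
      dplyr::group_by(.data$group, .data$age_year) |>
      dplyr::summarise(mean_encounters = mean(.data$n_encounters),
                       n_persons = dplyr::n(), .groups = "drop")
  }
  out
}

#' Cross-sectional scan of a simulated cohort
#'
#' Convenience path used by calibration and recovery studies: maps the
#' simulated coded events to ontology annotations, propagates them,
#' builds the person-by-term matrix and runs [phenome_scan()].
#'
#' @param sim A [simulate_cohort()] result.
#' @param ... Passed to [phenome_scan()].
#' @return A `phenome_scan` tibble.
#' @export
scan_simulation <- function(sim, ...) {
  ann <- sim_annotations(sim) |>
    dplyr::distinct(.data$person_id, .data$term)
  pro <- propagate_annotations(ann, sim$ontology)
  mat <- person_term_matrix(pro, sim$persons)
  phenome_scan(mat, sim$persons, ...)
}
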