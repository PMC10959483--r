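#' ILAE-style age bins
#'
#' The four observation age bins used throughout the longitudinal
#' analyses: neonatal/infantile `[0, 2)`, childhood `[2, 12)`, juvenile
#' `[12, 18)` and adult `[18, Inf)`. Intervals are half-open with the
#' boundary assigned upward (age 2.0 is childhood, 18.0 adult).
#'
#' @return Tibble `bin` (factor, bin order), `lo`, `hi`.
#' @export
age_bins <- function() {
  tibble::tibble(
    bin = factor(c("neonatal_infantile", "childhood", "juvenile", "adult"),
                 levels = c("neonatal_infantile", "childhood", "juvenile",
                            "adult")),
    lo = c(0, 2, 12, 18),
    hi = c(2, 12, 18, Inf)
  )
}

#' Assign ages to age bins
#'
#' @param age Numeric vector of non-negative ages in years.
#' @return Factor with levels `neonatal_infantile`, `childhood`,
#'   `juvenile`, `adult`.
#' @export
assign_age_bin <- function(age) {
  if (any(age < 0, na.rm = TRUE)) stop("ages must be >= 0", call. = FALSE)
  bins <- age_bins()
  cut(age, breaks = c(bins$lo, Inf), labels = as.character(bins$bin),
      right = FALSE)
}

#' Age-binned phenome scan
#'
#' Runs one [phenome_scan()] per age bin on the bin-restricted
#' person-by-term matrix: a person carries a term in a bin iff any
#' (possibly propagated) observation of that term falls in the bin.
#' Bonferroni correction is applied per bin over the terms tested in
#' that bin.
#'
#' @param annotations Propagated annotations with `person_id`, `term`,
#'   `age_years`.
#' @param groups Person-group table or named vector (see
#'   [phenome_scan()]).
#' @param persons Roster data frame with `person_id`.
#' @param ... Passed to [phenome_scan()] (`min_carriers`, `conf_int`,
#'   `term_names`, `alpha`).
#' @return Tibble of class `binned_scan`: the per-bin scan rows bound
#'   together with a leading `bin` column.
#' @export
binned_scan <- function(annotations, groups, persons, ...) {
  stopifnot(all(c("person_id", "term", "age_years") %in% names(annotations)))
  ann <- dplyr::mutate(annotations, bin = assign_age_bin(.data$age_years))
  res <- ann |>
    dplyr::group_by(.data$bin) |>
    dplyr::group_map(function(chunk, key) {
      scan <- phenome_scan(person_term_matrix(chunk, persons), groups, ...)
      dplyr::mutate(tibble::as_tibble(scan), bin = key$bin, .before = 1)
    }) |>
    dplyr::bind_rows()
  class(res) <- c("binned_scan", class(res))
  res
}

#' Term-by-age-bin trajectory matrix
#'
#' Reshapes a [binned_scan()] result into a term-by-bin matrix of log
#' odds ratios for trajectory clustering and heatmaps. By default only
#' Bonferroni-significant cells are kept (others set to NA), matching
#' heatmaps that blank non-significant tiles.
#'
#' @param bs A `binned_scan` result.
#' @param significant_only Keep only cells with `p_adj < alpha`
#'   (default `TRUE`).
#' @param alpha Significance level (default 0.05).
#' @param cap Absolute cap applied to log ORs so that boundary tables
#'   (`or` of 0 or Inf) appear as large finite values (default `log(100)`).
#' @return Numeric matrix, rows = terms (all terms with at least one
#'   retained cell), columns = the 4 bins; NA marks missing cells.
#' @export
trajectory_matrix <- function(bs, significant_only = TRUE, alpha = 0.05,
                              cap = log(100)) {
  df <- tibble::as_tibble(bs)
  if (significant_only) df <- dplyr::filter(df, .data$p_adj < alpha)
  df <- df |>
    dplyr::mutate(log_or = pmax(pmin(log(.data$or), cap), -cap)) |>
    dplyr::select("term", "bin", "log_or")
  wide <- tidyr::pivot_wider(df, names_from = "bin",
                             values_from = "log_or")
  bins <- as.character(age_bins()$bin)
  for (b in setdiff(bins, names(wide))) wide[[b]] <- NA_real_
  m <- as.matrix(wide[, bins])
  rownames(m) <- wide$term
  m
}

#' Hierarchical clustering of term trajectories
#'
#' Agglomerative (Ward) clustering of the rows of a trajectory matrix
#' using Euclidean distance on log ORs, with missing cells treated as 0
#' (no enrichment). Rows that are entirely missing are excluded with a
#' warning. The heatmap row order is the dendrogram leaf order.
#'
#' @param tm Trajectory matrix from [trajectory_matrix()].
#' @param k Number of clusters to cut the tree into (default 4, capped
#'   at the number of rows).
#' @return List: `clusters` (named integer vector), `order` (row names
#'   in leaf order), `hclust` (the dendrogram object).
#' @export
cluster_trajectories <- function(tm, k = 4) {
  all_na <- apply(tm, 1, function(r) all(is.na(r)))
  if (any(all_na)) {
    warning(sum(all_na), " all-missing row(s) excluded from clustering")
    tm <- tm[!all_na, , drop = FALSE]
  }
  if (nrow(tm) < 2) stop("need at least 2 rows to cluster", call. = FALSE)
  tm[is.na(tm)] <- 0
  hc <- stats::hclust(stats::dist(tm, method = "euclidean"),
                      method = "ward.D2")
  k <- min(k, nrow(tm))
  list(clusters = stats::cutree(hc, k = k),
       order = rownames(tm)[hc$order],
       hclust = hc)
}

#' Healthcare-utilization metrics
#'
#' Per-person utilization summaries with case-control contrasts: mean
#' concepts per encounter, annual encounter counts by age-year, emergency
#' and inpatient admission counts (contrasted among persons with at least
#' one such admission, since never-admitted persons say nothing about
#' admission frequency), and cost summaries (per outpatient encounter and
#' annual) compared by Wilcoxon rank-sum.
#'
#' @param persons Data frame `person_id`, `group`.
#' @param encounters Data frame `person_id`, `age_years`, `setting`
#'   (`outpatient`/`inpatient`/`emergency`), optional `cost`.
#' @param annotations Data frame `person_id`, `age_years`, one row per
#'   concept annotation (pre-propagation), used for concepts/encounter.
#' @return List of tibbles: `per_person`, `annual` (person x age-year
#'   encounter counts), `contrasts` (one row per metric with group means,
#'   SDs, test statistic and p).
#' @export
utilization_metrics <- function(persons, encounters, annotations = NULL) {
  grp <- dplyr::select(persons, "person_id", "group")
  enc <- dplyr::inner_join(encounters, grp, by = "person_id")
  per_person <- enc |>
    dplyr::group_by(.data$person_id, .data$group) |>
    dplyr::summarise(
      n_encounters = dplyr::n(),
      n_emergency = sum(.data$setting == "emergency"),
      n_inpatient = sum(.data$setting == "inpatient"),
      .groups = "drop"
    )
  if (!is.null(annotations)) {
    cpe <- annotations |>
      dplyr::count(.data$person_id, .data$age_years) |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(concepts_per_encounter = mean(.data$n),
                       .groups = "drop")
    per_person <- dplyr::left_join(per_person, cpe, by = "person_id")
  }
  annual <- enc |>
    dplyr::mutate(age_year = floor(.data$age_years)) |>
    dplyr::count(.data$person_id, .data$group, .data$age_year,
                 name = "n_encounters")
  contrasts <- list()
  pull2 <- function(df, col) {
    list(x = df[[col]][df$group == "case"],
         y = df[[col]][df$group == "control"])
  }
  both_groups <- function(s) length(s$x) >= 2 && length(s$y) >= 2
  if ("concepts_per_encounter" %in% names(per_person)) {
    s <- pull2(dplyr::filter(per_person,
                             !is.na(.data$concepts_per_encounter)),
               "concepts_per_encounter")
    if (both_groups(s)) contrasts$concepts_per_encounter <- welch_t_test(s$x, s$y)
  }
  ed <- dplyr::filter(per_person, .data$n_emergency >= 1)
  s <- pull2(ed, "n_emergency")
  if (both_groups(s)) contrasts$emergency_admissions <- welch_t_test(s$x, s$y)
  ip <- dplyr::filter(per_person, .data$n_inpatient >= 1)
  s <- pull2(ip, "n_inpatient")
  if (both_groups(s)) contrasts$inpatient_admissions <- welch_t_test(s$x, s$y)
  if ("cost" %in% names(enc)) {
    outp <- dplyr::filter(enc, .data$setting == "outpatient",
                          !is.na(.data$cost))
    if (length(unique(outp$group)) == 2) {
      s <- list(x = outp$cost[outp$group == "case"],
                y = outp$cost[outp$group == "control"])
      contrasts$outpatient_cost <- wilcoxon_rank_sum(s$x, s$y) |>
        dplyr::rename(statistic = "W")
    }
    ann_cost <- enc |>
      dplyr::filter(!is.na(.data$cost)) |>
      dplyr::mutate(age_year = floor(.data$age_years)) |>
      dplyr::group_by(.data$person_id, .data$group, .data$age_year) |>
      dplyr::summarise(cost = sum(.data$cost), .groups = "drop")
    if (length(unique(ann_cost$group)) == 2) {
      s <- list(x = ann_cost$cost[ann_cost$group == "case"],
                y = ann_cost$cost[ann_cost$group == "control"])
      contrasts$annual_cost <- wilcoxon_rank_sum(s$x, s$y) |>
        dplyr::rename(statistic = "W")
    }
  }
  contrast_tbl <- purrr::imap(contrasts, function(df, nm) {
    dplyr::mutate(df, metric = nm, .before = 1)
  }) |> dplyr::bind_rows()
  list(per_person = per_person, annual = annual, contrasts = contrast_tbl)
}

#' Detect the peak case/control encounter-ratio window
#'
#' Slides a window of `window_years` over integer age-years in
#' `age_range`, computes the ratio of case to control mean annual
#' encounter counts (among persons observed in the window), and returns
#' the window with the largest ratio together with a Welch t-test of
#' per-person annual counts inside it. Ties go to the earliest window;
#' windows with no control encounters are skipped with a warning. The
#' default range 12-22 brackets the paediatric-to-adult care transition.
#'
#' @param persons Data frame `person_id`, `group`.
#' @param encounters Data frame `person_id`, `age_years`.
#' @param age_range Integer ages scanned (default `c(12, 22)`, the upper
#'   bound exclusive).
#' @param window_years Window width in years (default 2).
#' @param followup Optional [followup_summary()] output used to decide
#'   who is observed in a window (first/last age overlap). Defaults to
#'   computing it from `encounters`.
#' @return List: `windows` (tibble `lo`, `hi`, `mean_case`,
#'   `mean_control`, `ratio`), `best` (one-row tibble for the argmax
#'   window with `t`, `p` appended), class `transition_window`.
#' @export
transition_window <- function(persons, encounters, age_range = c(12, 22),
                              window_years = 2, followup = NULL) {
  grp <- dplyr::select(persons, "person_id", "group")
  fu <- followup %||% followup_summary(encounters)
  fu <- dplyr::inner_join(fu, grp, by = "person_id")
  enc <- dplyr::inner_join(encounters, grp, by = "person_id")
  starts <- seq(age_range[1], age_range[2] - window_years)
  rows <- purrr::map(starts, function(lo) {
    hi <- lo + window_years
    obs <- dplyr::filter(fu, .data$first_age < hi, .data$last_age >= lo)
    if (sum(obs$group == "case") < 2 || sum(obs$group == "control") < 2) {
      return(NULL)  # too few observed persons to contrast this window
    }
    counts <- enc |>
      dplyr::filter(.data$age_years >= lo, .data$age_years < hi) |>
      dplyr::count(.data$person_id, name = "n")
    obs <- dplyr::left_join(obs, counts, by = "person_id") |>
      dplyr::mutate(annual = dplyr::coalesce(.data$n, 0L) / window_years)
    mc <- mean(obs$annual[obs$group == "case"])
    mk <- mean(obs$annual[obs$group == "control"])
    if (mk == 0) {
      warning("window [", lo, ",", hi, ") has no control encounters; skipped")
      return(NULL)
    }
    tibble::tibble(lo = lo, hi = hi, n_case = sum(obs$group == "case"),
                   n_control = sum(obs$group == "control"),
                   mean_case = mc, mean_control = mk, ratio = mc / mk)
  })
  windows <- dplyr::bind_rows(rows)
  if (nrow(windows) == 0) stop("no evaluable windows", call. = FALSE)
  best_i <- which(windows$ratio == max(windows$ratio))[1]
  best <- windows[best_i, ]
  obs <- dplyr::filter(fu, .data$first_age < best$hi,
                       .data$last_age >= best$lo)
  counts <- enc |>
    dplyr::filter(.data$age_years >= best$lo, .data$age_years < best$hi) |>
    dplyr::count(.data$person_id, name = "n")
  obs <- dplyr::left_join(obs, counts, by = "person_id") |>
    dplyr::mutate(annual = dplyr::coalesce(.data$n, 0L) / window_years)
  tt <- welch_t_test(obs$annual[obs$group == "case"],
                     obs$annual[obs$group == "control"])
  best <- dplyr::bind_cols(best, dplyr::select(tt, "t", "p"))
  structure(list(windows = windows, best = best),
            class = "transition_window")
}

#' @export
print.transition_window <- function(x, ...) {
  cat("<transition_window> peak at [", x$best$lo, ", ", x$best$hi,
      "): ratio ", signif(x$best$ratio, 4), ", p = ",
      signif(x$best$p, 3), "\n", sep = "")
  invisible(x)
}

#' Concept enrichment in an age window versus before it
#'
#' Within each group separately, compares concept presence during a
#' window (e.g. the care-transition years) against presence before the
#' window, among persons observed in both periods, via a 2x2 Fisher test
#' per concept: rows = in-window vs pre-window person-presence.
#'
#' @param annotations Data frame `person_id`, `term`, `age_years`.
#' @param persons Data frame `person_id`, `group`.
#' @param window Numeric length-2, `[lo, hi)` in years.
#' @param followup [followup_summary()]-style tibble for observation
#'   spans; computed from the annotations if omitted.
#' @param top_k Keep the `top_k` concepts by OR per group (default 10;
#'   `Inf` keeps all).
#' @return Tibble: `group`, `term`, `in_window`, `pre_window` (carrier
#'   counts), `n_obs` (persons observed in both periods), `or`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
window_concept_enrichment <- function(annotations, persons, window,
                                      followup = NULL, top_k = 10) {
  grp <- dplyr::select(persons, "person_id", "group")
  fu <- followup %||% (annotations |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(first_age = min(.data$age_years),
                     last_age = max(.data$age_years), .groups = "drop"))
  observed_both <- fu |>
    dplyr::filter(.data$first_age < window[1], .data$last_age >= window[1]) |>
    dplyr::pull("person_id")
  ann <- annotations |>
    dplyr::filter(.data$person_id %in% observed_both,
                  .data$age_years < window[2]) |>
    dplyr::inner_join(grp, by = "person_id") |>
    dplyr::mutate(period = ifelse(.data$age_years >= window[1],
                                  "in_window", "pre_window"))
  n_obs <- ann |>
    dplyr::distinct(.data$group, .data$person_id) |>
    dplyr::count(.data$group, name = "n_obs")
  counts <- ann |>
    dplyr::distinct(.data$group, .data$term, .data$period,
                    .data$person_id) |>
    dplyr::count(.data$group, .data$term, .data$period) |>
    tidyr::pivot_wider(names_from = "period", values_from = "n",
                       values_fill = 0L) |>
    dplyr::left_join(n_obs, by = "group")
  for (col in c("in_window", "pre_window")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  res <- counts |>
    dplyr::mutate(purrr::pmap_dfr(
      list(.data$in_window, .data$n_obs - .data$in_window,
           .data$pre_window, .data$n_obs - .data$pre_window),
      function(a, b, c, d) {
        r <- fisher_core(a, b, c, d)
        tibble::tibble(or = r$or, ci_low = r$ci_low, ci_high = r$ci_high,
                       p = r$p)
      }
    )) |>
    dplyr::arrange(.data$group, dplyr::desc(.data$or), .data$term)
  if (is.finite(top_k)) {
    res <- res |>
      dplyr::group_by(.data$group) |>
      dplyr::slice_head(n = top_k) |>
      dplyr::ungroup()
  }
  res
}
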