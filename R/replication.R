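#' Convert an odds ratio to a point-biserial correlation
#'
#' Two-step conversion: the log odds ratio becomes a standardized mean
#' difference (Cohen's d) via `d = ln(OR) * sqrt(3) / pi` (the logistic
#' latent-variable argument), and d becomes a correlation via the
#' equal-group-size form `d / sqrt(d^2 + 4)`. The result is bounded
#' in (-1, 1); boundary odds ratios of 0 and `Inf` map to -1 and 1. The
#' map is odd in `ln(OR)` and strictly increasing.
#'
#' @param or Positive odds ratio(s); 0 and `Inf` allowed.
#' @return Numeric vector of correlations in `[-1, 1]`.
#' @examples
#' or_to_pointbiserial(1)                  # 0
#' or_to_pointbiserial(exp(2 * pi / sqrt(3)))  # d = 2 -> r = 0.7071
#' @export
or_to_pointbiserial <- function(or) {
  if (any(or < 0, na.rm = TRUE)) {
    stop("odds ratios must be positive", call. = FALSE)
  }
  d <- log(or) * sqrt(3) / pi
  r <- ifelse(is.infinite(d), sign(d), d / sqrt(d^2 + 4))
  ifelse(or == 0, -1, r)
}

#' Pair two association scans for replication analysis
#'
#' Inner-joins a discovery (stage 1) and a validation (stage 2) scan on
#' a key column; keys untested in either stage are excluded (not
#' imputed). Effect sizes and CI endpoints are converted to the bounded
#' point-biserial scale.
#'
#' @param stage1,stage2 Association tables with at least `or`, `ci_low`,
#'   `ci_high`, `p` and the key column(s).
#' @param key Character vector of key column names (default `"term"`).
#' @return Tibble of class `stage_pairs`: key columns plus `or1`, `p1`,
#'   `r1`, `or2`, `p2`, `r2`, `r2_low`, `r2_high`.
#' @export
pair_stages <- function(stage1, stage2, key = "term") {
  s1 <- tibble::as_tibble(stage1) |>
    dplyr::select(dplyr::all_of(key), or1 = "or", p1 = "p")
  s2 <- tibble::as_tibble(stage2) |>
    dplyr::select(dplyr::all_of(key), or2 = "or", p2 = "p",
                  ci_low2 = "ci_low", ci_high2 = "ci_high")
  out <- dplyr::inner_join(s1, s2, by = key) |>
    dplyr::mutate(
      r1 = or_to_pointbiserial(.data$or1),
      r2 = or_to_pointbiserial(.data$or2),
      r2_low = or_to_pointbiserial(.data$ci_low2),
      r2_high = or_to_pointbiserial(.data$ci_high2)
    ) |>
    dplyr::select(-"ci_low2", -"ci_high2")
  class(out) <- c("stage_pairs", class(out))
  out
}

#' Effect-direction concordance between stages
#'
#' Among keys nominally significant in stage 1 (`p1 < alpha`), counts
#' those whose stage-2 odds ratio points the same way
#' (`sign(ln OR1) == sign(ln OR2)`); an OR of exactly 1 in either stage
#' is not a match. The percentage is reported to 2 decimals.
#'
#' @param pairs A [pair_stages()] table.
#' @param alpha Nominal significance level (default 0.05).
#' @return One-row tibble: `n_matched`, `n_nominal`, `pct`.
#' @export
direction_concordance <- function(pairs, alpha = 0.05) {
  nom <- dplyr::filter(pairs, .data$p1 < alpha,
                       !is.na(.data$or1), !is.na(.data$or2))
  matched <- sign(log(nom$or1)) != 0 &
    sign(log(nom$or1)) == sign(log(nom$or2))
  tibble::tibble(
    n_matched = sum(matched),
    n_nominal = nrow(nom),
    pct = pct(sum(matched), nrow(nom))
  )
}

#' Stage-1 effect coverage by stage-2 confidence intervals
#'
#' Counts pairs whose stage-1 point estimate lies inside the stage-2
#' 95% CI, evaluated on the bounded point-biserial scale (CI endpoints
#' converted alongside). Pairs with a missing stage-2 CI are excluded
#' from the denominator with a warning.
#'
#' @param pairs A [pair_stages()] table.
#' @return One-row tibble: `n_within`, `n_total`, `pct`.
#' @export
ci_coverage <- function(pairs) {
  has_ci <- !is.na(pairs$r2_low) & !is.na(pairs$r2_high)
  if (any(!has_ci)) {
    warning(sum(!has_ci), " pair(s) without a stage-2 CI excluded")
  }
  ok <- pairs[has_ci, ]
  within <- ok$r1 >= ok$r2_low & ok$r1 <= ok$r2_high
  tibble::tibble(
    n_within = sum(within),
    n_total = nrow(ok),
    pct = pct(sum(within), nrow(ok))
  )
}

#' Correlation of effect sizes across stages
#'
#' Pearson product-moment correlation of the point-biserial effect sizes
#' (`r1`, `r2`) over pairs nominally significant in stage 1, with a
#' two-sided p-value from the t-distribution.
#'
#' @param pairs A [pair_stages()] table.
#' @param alpha Nominal significance level for stage-1 selection
#'   (default 0.05).
#' @return One-row tibble: `pearson_r`, `p`, `n`. Zero variance in
#'   either coordinate yields NA with a warning.
#' @export
effectsize_correlation <- function(pairs, alpha = 0.05) {
  nom <- dplyr::filter(pairs, .data$p1 < alpha,
                       is.finite(.data$r1), is.finite(.data$r2))
  if (nrow(nom) < 3) stop("need >= 3 nominal pairs", call. = FALSE)
  if (stats::sd(nom$r1) == 0 || stats::sd(nom$r2) == 0) {
    warning("zero variance in one stage; correlation undefined")
    return(tibble::tibble(pearson_r = NA_real_, p = NA_real_,
                          n = nrow(nom)))
  }
  ct <- stats::cor.test(nom$r1, nom$r2, method = "pearson")
  tibble::tibble(pearson_r = unname(ct$estimate), p = ct$p.value,
                 n = nrow(nom))
}

#' Two-stage replication summary
#'
#' Bundles direction concordance, CI coverage, per-stage effect-size
#' summaries and the cross-stage Pearson correlation into a single
#' object.
#'
#' @param pairs A [pair_stages()] table.
#' @param alpha Nominal significance level (default 0.05).
#' @return Object of class `replication_summary` (list with `pairs`,
#'   `direction`, `coverage`, `correlation`, `effect_sizes`).
#' @export
replication_summary <- function(pairs, alpha = 0.05) {
  es <- tibble::tibble(
    stage = c("stage1", "stage2"),
    mean_r = c(mean(pairs$r1, na.rm = TRUE), mean(pairs$r2, na.rm = TRUE)),
    sd_r = c(stats::sd(pairs$r1, na.rm = TRUE),
             stats::sd(pairs$r2, na.rm = TRUE)),
    median_r = c(stats::median(pairs$r1, na.rm = TRUE),
                 stats::median(pairs$r2, na.rm = TRUE))
  )
  corr <- tryCatch(effectsize_correlation(pairs, alpha),
                   error = function(e) {
                     tibble::tibble(pearson_r = NA_real_, p = NA_real_,
                                    n = NA_integer_)
                   })
  structure(
    list(pairs = pairs,
         direction = direction_concordance(pairs, alpha),
         coverage = ci_coverage(pairs),
         correlation = corr,
         effect_sizes = es,
         alpha = alpha),
    class = "replication_summary"
  )
}

#' @export
print.replication_summary <- function(x, ...) {
  cat("<replication_summary> ", nrow(x$pairs), " paired keys\n", sep = "")
  cat("  direction concordance: ", x$direction$n_matched, "/",
      x$direction$n_nominal, " (", x$direction$pct, "%)\n", sep = "")
  cat("  stage-1 effects within stage-2 CI: ", x$coverage$n_within, "/",
      x$coverage$n_total, " (", x$coverage$pct, "%)\n", sep = "")
  cat("  Pearson R over nominal pairs: ",
      signif(x$correlation$pearson_r, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.replication_summary <- function(x, ...) x$pairs

#' @export
glance.replication_summary <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_nominal = x$direction$n_nominal,
    pct_direction = x$direction$pct,
    n_within_ci = x$coverage$n_within,
    n_ci_total = x$coverage$n_total,
    pct_within_ci = x$coverage$pct,
    pearson_r = x$correlation$pearson_r,
    pearson_p = x$correlation$p,
    mean_r_stage1 = x$effect_sizes$mean_r[1],
    mean_r_stage2 = x$effect_sizes$mean_r[2]
  )
}

#' Percentage to two decimals
#'
#' `round(100 * numerator / denominator, 2)`, the convention used for
#' all reported replication and chart-review proportions.
#'
#' @param numerator,denominator Counts.
#' @return Numeric percentage (NA when the denominator is 0).
#' @export
pct <- function(numerator, denominator) {
  ifelse(denominator == 0, NA_real_,
         round(100 * numerator / denominator, 2))
}
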