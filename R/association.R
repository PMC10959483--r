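#' Fisher's exact test with conditional-MLE odds ratio
#'
#' Exact inference for a 2x2 case-control table under the noncentral
#' hypergeometric model, conditioning on both margins. The two-sided
#' p-value sums the point probabilities of all tables sharing the margins
#' whose probability does not exceed that of the observed table. The odds
#' ratio is the conditional maximum-likelihood estimate, which is 0 or
#' `Inf` at boundary tables (no Haldane-style continuity correction), and
#' the confidence interval inverts one-sided exact tests at
#' `(1 - conf_level) / 2` each — the convention that yields one-sided
#' intervals with an infinite endpoint for tables where a cell is empty.
#'
#' @param a Cases with the feature.
#' @param b Cases without.
#' @param c Controls with the feature.
#' @param d Controls without.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param estimate Compute the conditional-MLE OR and CI? Scans that only
#'   need p-values can skip this for speed.
#' @return One-row tibble: `p`, `or`, `ci_low`, `ci_high`, plus the
#'   counts. A table with an empty row or column margin is degenerate:
#'   `p = 1` and the OR and CI are `NA` (undefined).
#' @examples
#' fisher_exact(5, 0, 0, 5)   # p = 2/252, OR = Inf
#' @export
fisher_exact <- function(a, b, c, d, conf_level = 0.95, estimate = TRUE) {
  stopifnot(length(a) == 1, a >= 0, b >= 0, c >= 0, d >= 0)
  core <- fisher_core(a, b, c, d, conf_level, estimate)
  tibble::tibble(
    p = core$p, or = core$or, ci_low = core$ci_low, ci_high = core$ci_high,
    a = a, b = b, c = c, d = d
  )
}

# scalar workhorse returning a plain list; shared by fisher_exact and scans
fisher_core <- function(a, b, c, d, conf_level = 0.95, estimate = TRUE) {
  m <- a + b          # cases
  n <- c + d          # controls
  K <- a + c          # feature carriers
  if (m == 0 || n == 0 || K == 0 || K == m + n) {
    return(list(p = 1, or = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  lo <- max(0L, K - n)
  hi <- min(K, m)
  support <- lo:hi
  logp <- stats::dhyper(support, m, n, K, log = TRUE)
  obs <- logp[a - lo + 1L]
  # point-probability rule with the classical relative tolerance
  p <- min(1, sum(exp(logp)[exp(logp) <= exp(obs) * (1 + 1e-7)]))
  if (!estimate) {
    return(list(p = p, or = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  alpha <- (1 - conf_level) / 2
  or <- cmle_or(a, support, logp, lo, hi)
  ci_low <- if (a == lo) 0 else
    invert_tail(a, support, logp, lower_tail = FALSE, alpha = alpha)
  ci_high <- if (a == hi) Inf else
    invert_tail(a, support, logp, lower_tail = TRUE, alpha = alpha)
  list(p = p, or = or, ci_low = ci_low, ci_high = ci_high)
}

# conditional density over the support at log-odds-ratio theta
cond_logdens <- function(theta, support, logp) {
  w <- logp + support * theta
  w - log_sum_exp(w)
}

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# conditional MLE of the odds ratio: the conditional expectation of the
# count is increasing in theta, so solve E_theta[X] = a by monotone root
cmle_or <- function(a, support, logp, lo, hi) {
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  score <- function(theta) {
    dens <- exp(cond_logdens(theta, support, logp))
    sum(support * dens) - a
  }
  bound <- 1
  while (score(-bound) > 0 || score(bound) < 0) {
    bound <- bound * 2
    if (bound > 500) break
  }
  exp(stats::uniroot(score, c(-bound, bound), tol = 1e-10)$root)
}

# exact tail inversion: find theta where P_theta(X >= a) = alpha
# (lower_tail = FALSE gives the lower CI bound) or P_theta(X <= a) = alpha
# (upper bound)
invert_tail <- function(a, support, logp, lower_tail, alpha) {
  tail_p <- function(theta) {
    dens <- exp(cond_logdens(theta, support, logp))
    if (lower_tail) sum(dens[support <= a]) else sum(dens[support >= a])
  }
  f <- function(theta) tail_p(theta) - alpha
  bound <- 1
  # lower bound: tail P(X >= a) increases in theta; upper: P(X <= a) decreases
  while (f(-bound) * f(bound) > 0 && bound < 500) bound <- bound * 2
  exp(stats::uniroot(f, c(-bound, bound), tol = 1e-10)$root)
}

#' Bonferroni adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of hypotheses in the family; defaults to `length(p)`.
#'   Must be at least `length(p)`.
#' @return `pmin(1, p * m)`, in input order.
#' @export
bonferroni_adjust <- function(p, m = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- m %||% length(p)
  if (m < length(p)) {
    stop("family size m (", m, ") is smaller than the number of p-values (",
         length(p), ")", call. = FALSE)
  }
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Whole-phenome association scan
#'
#' Tests every term column of a person-by-term indicator matrix for
#' association with binary case-control status by Fisher's exact test,
#' reporting exact conditional odds ratios with confidence intervals and
#' Bonferroni-adjusted p-values. The Bonferroni family is the number of
#' terms actually tested in this scan, so separate vocabularies (e.g.
#' clinical concepts vs phenotype terms) form separate families.
#'
#' @param mat Binary person-by-term matrix (base or `Matrix` sparse),
#'   with person ids as row names and term ids as column names. See
#'   [person_term_matrix()].
#' @param groups Data frame with columns `person_id` and `group`
#'   (`"case"`/`"control"`), or a named character vector.
#' @param min_carriers Minimum total carrier count for a term to be
#'   tested (default 1: every observed term).
#' @param conf_int Compute conditional-MLE ORs and exact CIs (default
#'   `TRUE`); with `FALSE` only p-values and the sample log-OR direction
#'   are reported, which is considerably faster for calibration studies.
#' @param term_names Optional named character vector of term labels.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Tibble of class `phenome_scan`, one row per tested term,
#'   sorted by `p` then term id: `term`, `name`, `a`, `b`, `c`, `d`,
#'   `or`, `ci_low`, `ci_high`, `p`, `p_adj`, `direction`
#'   (`"enriched"`/`"depleted"`/`"null"`, the sign of the sample log OR).
#'   Attributes: `n_tests`, `alpha`, `bonferroni_threshold`, `n_cases`,
#'   `n_controls`.
#' @export
phenome_scan <- function(mat, groups, min_carriers = 1, conf_int = TRUE,
                         term_names = NULL, alpha = 0.05) {
  grp <- as_group_vector(groups)
  persons <- rownames(mat)
  stopifnot(!is.null(persons), !is.null(colnames(mat)))
  missing <- setdiff(persons, names(grp))
  if (length(missing) > 0) {
    stop("matrix rows without a group label: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  is_case <- grp[persons] == "case"
  n_cases <- sum(is_case)
  n_controls <- sum(!is_case)
  carriers_case <- as.numeric(Matrix::colSums(mat[is_case, , drop = FALSE]))
  carriers_ctrl <- as.numeric(Matrix::colSums(mat[!is_case, , drop = FALSE]))
  keep <- (carriers_case + carriers_ctrl) >= min_carriers
  terms <- colnames(mat)[keep]
  a <- carriers_case[keep]
  c_ <- carriers_ctrl[keep]
  b <- n_cases - a
  d <- n_controls - c_
  res <- purrr::pmap(list(a, b, c_, d), function(a, b, c, d) {
    fisher_core(a, b, c, d, estimate = conf_int)
  })
  sample_logor <- log(a) + log(d) - log(b) - log(c_)  # sign only; -Inf/Inf ok
  direction <- dplyr::case_when(
    a * d > b * c_ ~ "enriched",
    a * d < b * c_ ~ "depleted",
    TRUE ~ "null"
  )
  out <- tibble::tibble(
    term = terms,
    name = if (is.null(term_names)) NA_character_ else
      unname(term_names[terms]),
    a = as.integer(a), b = as.integer(b),
    c = as.integer(c_), d = as.integer(d),
    or = purrr::map_dbl(res, "or"),
    ci_low = purrr::map_dbl(res, "ci_low"),
    ci_high = purrr::map_dbl(res, "ci_high"),
    p = purrr::map_dbl(res, "p"),
    direction = direction
  )
  out$p_adj <- bonferroni_adjust(out$p)
  out <- dplyr::relocate(out, "p_adj", .after = "p") |>
    dplyr::arrange(.data$p, .data$term)
  structure(
    out,
    n_tests = length(terms),
    alpha = alpha,
    bonferroni_threshold = alpha / max(1L, length(terms)),
    n_cases = n_cases,
    n_controls = n_controls,
    class = c("phenome_scan", class(out))
  )
}

as_group_vector <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("person_id", "group") %in% names(groups)))
    grp <- stats::setNames(as.character(groups$group), groups$person_id)
  } else {
    grp <- stats::setNames(as.character(groups), names(groups))
  }
  bad <- setdiff(unique(grp), c("case", "control"))
  if (length(bad) > 0) {
    stop("group labels must be 'case'/'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  grp
}

#' Genomic-control inflation factor
#'
#' Converts p-values to 1-df chi-square quantiles and compares their
#' median to the null median 0.4549364 (the genomic-control lambda). A
#' well-calibrated scan has lambda near 1.
#'
#' @param p Non-empty vector of p-values in `(0, 1]`; exact zeros are
#'   clipped to the smallest representable positive value with a warning.
#' @param alpha Significance level used for the Bonferroni threshold
#'   (default 0.05).
#' @return Object of class `inflation_stat`: a one-row tibble with
#'   `lambda`, `n_tests`, `alpha`, `bonferroni_threshold`.
#' @export
inflation_lambda <- function(p, alpha = 0.05) {
  stopifnot(length(p) > 0, all(p >= 0 & p <= 1))
  if (any(p == 0)) {
    warning("p-values of 0 clipped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  structure(
    tibble::tibble(
      lambda = lambda,
      n_tests = length(p),
      alpha = alpha,
      bonferroni_threshold = alpha / length(p)
    ),
    class = c("inflation_stat", "tbl_df", "tbl", "data.frame")
  )
}

#' Welch's two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] (two-sided, unequal variances)
#' returning a tidy one-row tibble; used for continuous group contrasts
#' such as ages, encounter counts, concepts per encounter and medication
#' counts. Two constant samples with equal means return `t = 0, p = 1`
#' rather than an error.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return Tibble: `t`, `df`, `p`, `mean_x`, `mean_y`, `sd_x`, `sd_y`.
#' @export
welch_t_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(tibble::tibble(t = 0, df = NA_real_, p = 1,
                            mean_x = mean(x), mean_y = mean(y),
                            sd_x = 0, sd_y = 0))
    }
    return(tibble::tibble(t = Inf * sign(mean(x) - mean(y)), df = NA_real_,
                          p = 0, mean_x = mean(x), mean_y = mean(y),
                          sd_x = 0, sd_y = 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    mean_x = mean(x), mean_y = mean(y), sd_x = stats::sd(x), sd_y = stats::sd(y)
  )
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test; exact when the combined sample size is at
#' most 20 and there are no ties, otherwise the tie-corrected normal
#' approximation with continuity correction. Used for cost comparisons,
#' which are heavily skewed.
#'
#' @param x,y Non-empty numeric samples.
#' @return Tibble: `W`, `p`, `median_x`, `median_y`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  exact <- length(x) + length(y) <= 20
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  tibble::tibble(W = unname(wt$statistic), p = wt$p.value,
                 median_x = stats::median(x), median_y = stats::median(y))
}

#' @export
glance.phenome_scan <- function(x, ...) {
  infl <- inflation_lambda(x$p, alpha = attr(x, "alpha"))
  tibble::tibble(
    n_tests = attr(x, "n_tests"),
    n_cases = attr(x, "n_cases"),
    n_controls = attr(x, "n_controls"),
    lambda = infl$lambda,
    alpha = attr(x, "alpha"),
    bonferroni_threshold = attr(x, "bonferroni_threshold"),
    n_significant = sum(x$p_adj < attr(x, "alpha"))
  )
}

#' @export
tidy.phenome_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a fitted result
#'
#' Generic re-exported in the broom style: `tidy()` returns the per-unit
#' result table, `glance()` a one-row model-level summary.
#'
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
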