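#' QQ plot of a phenome scan
#'
#' Observed versus expected -log10 p-values with the identity line and
#' the Bonferroni threshold, annotated with the genomic-control lambda.
#'
#' @param object A [phenome_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phenome_scan <- function(object, ...) {
  fd <- make_figure_data(scan = object, alpha = attr(object, "alpha"))
  lam <- inflation_lambda(object$p)$lambda
  thr <- -log10(attr(object, "bonferroni_threshold"))
  ggplot2::ggplot(fd$qq, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_hline(yintercept = thr, linetype = "dotted",
                        colour = "firebrick") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      title = sprintf("Phenome scan QQ plot (lambda = %.2f)", lam)
    ) +
    ggplot2::theme_minimal()
}

#' Trajectory heatmap
#'
#' Term-by-age-bin log odds ratios with rows in dendrogram leaf order;
#' blank tiles are non-significant cells.
#'
#' @param tm A [trajectory_matrix()].
#' @param clusters Optional [cluster_trajectories()] result used for row
#'   order.
#' @return A ggplot object.
#' @export
plot_trajectory_heatmap <- function(tm, clusters = NULL) {
  ord <- if (!is.null(clusters)) clusters$order else rownames(tm)
  long <- tibble::as_tibble(tm, rownames = "term") |>
    tidyr::pivot_longer(-"term", names_to = "bin", values_to = "log_or") |>
    dplyr::mutate(
      term = factor(.data$term, levels = rev(ord)),
      bin = factor(.data$bin, levels = as.character(age_bins()$bin))
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$bin, .data$term,
                                     fill = .data$log_or)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", na.value = "grey95") +
    ggplot2::labs(x = "age bin", y = NULL, fill = "log OR") +
    ggplot2::theme_minimal()
}

#' Annual encounter curves by group
#'
#' Mean annual encounter counts per age-year for cases and controls,
#' with the transition window shaded when supplied.
#'
#' @param utilization A [utilization_metrics()] result.
#' @param transition Optional [transition_window()] result.
#' @return A ggplot object.
#' @export
plot_annual_encounters <- function(utilization, transition = NULL) {
  fd <- make_figure_data(utilization = utilization)
  p <- ggplot2::ggplot(fd$annual_curves,
                       ggplot2::aes(.data$age_year, .data$mean_encounters,
                                    colour = .data$group))
  if (!is.null(transition)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = transition$best$lo, xmax = transition$best$hi,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "goldenrod")
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = "age (years)", y = "mean annual encounters") +
    ggplot2::theme_minimal()
}

#' Replication effect-size scatter
#'
#' Stage-1 versus stage-2 point-biserial effect sizes; nominally
#' significant stage-1 pairs are highlighted.
#'
#' @param object A [replication_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.replication_summary <- function(object, ...) {
  df <- dplyr::mutate(object$pairs,
                      nominal = .data$p1 < object$alpha)
  ggplot2::ggplot(df, ggplot2::aes(.data$r1, .data$r2,
                                   colour = .data$nominal)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "stage-1 effect size (r)",
                  y = "stage-2 effect size (r)",
                  colour = "p1 < alpha") +
    ggplot2::theme_minimal()
}

#' Covariate balance (Love) plot
#'
#' Absolute standardized mean differences before and after matching.
#'
#' @param object A [match_cohorts()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.matched_cohort <- function(object, ...) {
  long <- object$balance |>
    tidyr::pivot_longer(c("smd_pre", "smd_post"), names_to = "stage",
                        values_to = "smd") |>
    dplyr::mutate(stage = ifelse(.data$stage == "smd_pre", "before",
                                 "after"))
  ggplot2::ggplot(long, ggplot2::aes(abs(.data$smd), .data$covariate,
                                     colour = .data$stage)) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dotted") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @keywords internal
NULL
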