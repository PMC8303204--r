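# ggplot2 views of the result tables.

#' Volcano plot of bivariate vs multivariate association
#'
#' x: partial correlation with the fitness response; y: negative log10 of
#' the permutation frequency of the rank product; color: major pathway;
#' shape: relevance class.
#'
#' @param volcano A [volcano_table()] tibble.
#' @param alpha Significance cutoff drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_volcano <- function(volcano, alpha = 0.05) {
  ggplot2::ggplot(volcano,
                  ggplot2::aes(x = .data$r, y = .data$neg_log10_perm_frequency,
                               color = .data$pathway, shape = .data$relevant)) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_vline(xintercept = c(-0.25, 0.25), linetype = "dotted",
                        color = "grey70") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "partial correlation with VO2peak (r)",
                  y = "-log10 permutation frequency",
                  color = "major pathway", shape = "relevant") +
    ggplot2::theme_minimal()
}

#' Forest plot of partial correlations
#'
#' Dot-and-interval display of [correlate_all()] results, ordered by r.
#'
#' @param results A [correlate_all()] tibble.
#' @param top Show only the `top` strongest associations (by `|r|`).
#' @return A ggplot object.
#' @export
plot_correlation_forest <- function(results, top = 30) {
  d <- results |>
    dplyr::arrange(dplyr::desc(abs(.data$r))) |>
    utils::head(top) |>
    dplyr::mutate(variable = stats::reorder(.data$variable, .data$r))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$variable,
                                  color = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "partial correlation (r, 95% CI)", y = NULL,
                  color = "CI excludes 0") +
    ggplot2::theme_minimal()
}

#' Relative-mean profile across fitness quarters
#'
#' Line display of the quarter summary's relative means (first quarter = 1),
#' the tabular counterpart of a radar chart.
#'
#' @param quarters A [quarter_summary_table()] tibble.
#' @return A ggplot object.
#' @export
plot_quarter_profile <- function(quarters) {
  d <- dplyr::filter(quarters, !is.na(.data$relative_mean))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quarter, y = .data$relative_mean,
                                  group = .data$variable,
                                  color = .data$variable)) +
    ggplot2::geom_hline(yintercept = 1, color = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "VO2peak quarter", y = "mean relative to 1st quarter",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rank_product_result <- function(object, ...) {
  d <- object$table
  if (is.null(d$perm_frequency)) {
    d <- dplyr::arrange(d, .data$rank_product)
    return(ggplot2::ggplot(utils::head(d, 30),
                           ggplot2::aes(x = .data$rank_product,
                                        y = stats::reorder(.data$analyte,
                                                           -.data$rank_product))) +
             ggplot2::geom_col() +
             ggplot2::labs(x = "rank product", y = NULL) +
             ggplot2::theme_minimal())
  }
  floor_p <- 1 / (object$config$n_permutations + 1)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank_product,
                                  y = -log10(pmax(.data$perm_frequency, floor_p)),
                                  color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha),
                        linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "rank product (log scale)",
                  y = "-log10 permutation frequency",
                  color = "significant") +
    ggplot2::theme_minimal()
}
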