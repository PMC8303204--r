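# Partial Pearson correlations of VO2peak with each analyte, confidence
# intervals via the Fisher z transform, and pathway-level summaries.

#' Fisher-z confidence interval for a correlation
#'
#' `tanh(atanh(r) +/- z * 1/sqrt(n - 3))`. No degrees-of-freedom correction
#' for partial correlations is applied: the interval depends on the sample
#' size only.
#'
#' @param r Correlation coefficient.
#' @param n Sample size.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `ci_low`, `ci_high`.
#' @export
fisher_ci <- function(r, n, conf_level = 0.95) {
  if (any(n < 4)) rlang::abort("need n >= 4 for a Fisher-z interval")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z / sqrt(n - 3)
  tibble::tibble(ci_low = tanh(atanh(r) - half), ci_high = tanh(atanh(r) + half))
}

#' Partial Pearson correlation with CI-based significance
#'
#' Pearson correlation of the least-squares residuals of `x` and `y` on the
#' same covariate set; with an empty covariate set this is the plain Pearson
#' correlation. The association is flagged significant when the confidence
#' interval excludes zero.
#'
#' @param x,y Aligned numeric vectors.
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return One-row tibble: `r`, `ci_low`, `ci_high`, `n`, `n_covariates`,
#'   `significant`.
#' @export
partial_correlation <- function(x, y, covariates = NULL, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  p <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n < 5 + p) rlang::abort("need n >= 5 + number of covariates")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    rlang::abort("zero variance in a residual vector")
  }
  r <- stats::cor(rx, ry)
  ci <- fisher_ci(r, n, conf_level)
  tibble::tibble(r = r, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 n = n, n_covariates = p,
                 significant = ci$ci_low > 0 | ci$ci_high < 0)
}

#' Correlate a response with every variable of a score table
#'
#' Runs [partial_correlation()] of `response` against each column in
#' `variables`, all adjusted for the same covariate set. The two standard
#' adjustment profiles of the analysis are the confounder-only profile
#' (`*`: age, plus menopausal status in females) and the fully adjusted
#' profile (`**`: confounders plus the 21 phenotypical/clinical covariates).
#'
#' @param data Tibble of scores (e.g. from [sex_score_table()]).
#' @param response Name of the response column.
#' @param variables Character vector of variable columns to test.
#' @param covariates Character vector of covariate columns (may be empty).
#' @param conf_level Confidence level.
#' @return Tibble with one row per variable, input order preserved.
#' @export
correlate_all <- function(data, response, variables,
                          covariates = character(), conf_level = 0.95) {
  if (response %in% covariates) rlang::abort("response cannot be its own covariate")
  miss <- setdiff(c(response, variables, covariates), names(data))
  if (length(miss) > 0) rlang::abort(paste0("unknown columns: ", paste(miss, collapse = ", ")))
  C <- if (length(covariates) > 0) as.matrix(data[, covariates, drop = FALSE]) else NULL
  y <- data[[response]]
  purrr::map_dfr(variables, function(v) {
    dplyr::bind_cols(tibble::tibble(variable = v),
                     partial_correlation(data[[v]], y, C, conf_level))
  })
}

#' Count significant correlations per major metabolic pathway
#'
#' Cross-tabulates the confounder-adjusted (`*`) and fully adjusted (`**`)
#' correlation results by major pathway, with a grand-total row.
#'
#' @param star,doublestar Results of [correlate_all()] over the same analytes.
#' @param annotation Annotation tibble covering those analytes.
#' @return Tibble: `pathway`, `n_total`, `n_significant_star`,
#'   `n_significant_doublestar`; last row `pathway == "all"`.
#' @export
summarize_by_pathway <- function(star, doublestar, annotation) {
  if (!setequal(star$variable, doublestar$variable)) {
    rlang::abort("result lists cover different analyte sets")
  }
  miss <- setdiff(star$variable, annotation$analyte_id)
  if (length(miss) > 0) {
    rlang::abort(paste0("annotation missing analytes: ", paste(miss, collapse = ", ")))
  }
  joined <- star |>
    dplyr::select(variable, sig_star = "significant") |>
    dplyr::inner_join(dplyr::select(doublestar, variable,
                                    sig_doublestar = "significant"),
                      by = "variable") |>
    dplyr::inner_join(dplyr::select(annotation, variable = "analyte_id",
                                    pathway = "major_pathway"),
                      by = "variable")
  per <- joined |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_significant_star = sum(.data$sig_star),
                     n_significant_doublestar = sum(.data$sig_doublestar),
                     .groups = "drop")
  total <- dplyr::summarise(per, pathway = "all",
                            n_total = sum(.data$n_total),
                            n_significant_star = sum(.data$n_significant_star),
                            n_significant_doublestar = sum(.data$n_significant_doublestar))
  dplyr::bind_rows(dplyr::arrange(per, .data$pathway), total)
}

#' Top-k positive and negative correlations
#'
#' The top `k` positive (descending r) and top `k` negative (ascending r)
#' results, flagging `|r| >= relevance` as relevant. Short sides truncate;
#' ties in r are broken by variable id.
#'
#' @param results A [correlate_all()] tibble.
#' @param k Number of rows per direction.
#' @param relevance Relevance threshold on `|r|` (default 0.25).
#' @return Tibble with `direction` ("positive"/"negative"), `rank_in_direction`
#'   and `relevant` columns added.
#' @export
top_table <- function(results, k = 10, relevance = 0.25) {
  if (k < 1) rlang::abort("k must be >= 1")
  pos <- results |>
    dplyr::filter(.data$r > 0) |>
    dplyr::arrange(dplyr::desc(.data$r), .data$variable) |>
    utils::head(k) |>
    dplyr::mutate(direction = "positive")
  neg <- results |>
    dplyr::filter(.data$r < 0) |>
    dplyr::arrange(.data$r, .data$variable) |>
    utils::head(k) |>
    dplyr::mutate(direction = "negative")
  dplyr::bind_rows(pos, neg) |>
    dplyr::group_by(.data$direction) |>
    dplyr::mutate(rank_in_direction = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(relevant = abs(.data$r) >= relevance)
}
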