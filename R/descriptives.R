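# Sex-specific VO2peak quartile grouping, Welch ANOVA / chi-squared tests
# across quarters, and relative-mean tables.

#' Assign values to empirical quartile groups
#'
#' Boundaries are the type-7 sample quartiles; a value exactly equal to a
#' boundary falls into the lower quarter.
#'
#' @param values Numeric vector, `n >= 8`, not constant.
#' @return Integer labels 1..4.
#' @export
quartile_groups <- function(values) {
  if (length(values) < 8) rlang::abort("need at least 8 values")
  if (max(values) == min(values)) rlang::abort("constant vector has no quartiles")
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  1L + (values > q[1]) + (values > q[2]) + (values > q[3])
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F with Satterthwaite denominator degrees of freedom
#' (via [stats::oneway.test()] with `var.equal = FALSE`).
#'
#' @param values Numeric vector.
#' @param groups Group labels (each group needs >= 2 members and nonzero
#'   variance).
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p_value`.
#' @export
welch_anova <- function(values, groups) {
  groups <- factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) rlang::abort("need at least 2 groups")
  if (any(sizes < 2)) rlang::abort("every group needs at least 2 members")
  vars <- tapply(values, groups, stats::var)
  if (all(vars == 0)) {
    means <- tapply(values, groups, mean)
    same <- max(means) == min(means)
    return(tibble::tibble(statistic = if (same) 0 else Inf,
                          df1 = length(sizes) - 1, df2 = Inf,
                          p_value = if (same) 1 else 0))
  }
  if (any(vars == 0)) rlang::abort("a group has zero variance")
  ft <- stats::oneway.test(values ~ groups, var.equal = FALSE)
  tibble::tibble(statistic = unname(ft$statistic),
                 df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
                 p_value = ft$p.value)
}

#' Pearson chi-squared test of a category-by-quarter table
#'
#' No continuity correction; a warning (not an error) is emitted when an
#' expected cell count falls below 5.
#'
#' @param categories Categorical labels.
#' @param groups Quarter labels.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_squared_quarters <- function(categories, groups) {
  tab <- table(categories, groups)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || any(dim(tab) < 2)) {
    rlang::abort("degenerate contingency table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) rlang::warn("expected cell count below 5")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

#' Quarter summary of basic cohort characteristics for one sex
#'
#' Participants are grouped by sex-specific VO2peak quartiles; every numeric
#' characteristic is compared across quarters by Welch ANOVA, categorical
#' ones (menopausal status, in females) by chi-squared. Relative means use
#' the first (lowest-fitness) quarter as the reference.
#'
#' @param pheno Completed phenotype tibble (covariates imputed).
#' @param sex `"F"` or `"M"`.
#' @return Tibble: one row per variable and quarter with `n`, `mean`, `sd`,
#'   `relative_mean`, plus the test name and p-value (repeated per quarter).
#' @export
quarter_summary_table <- function(pheno, sex) {
  ph <- dplyr::filter(pheno, .data$sex == !!sex)
  if (nrow(ph) == 0) rlang::abort(paste0("no samples for sex ", sex))
  ph$quarter <- quartile_groups(ph$vo2peak)
  numeric_vars <- c("age", "vo2peak", covariate_names())
  rows <- purrr::map_dfr(numeric_vars, function(v) {
    pv <- welch_anova(ph[[v]], ph$quarter)$p_value
    ph |>
      dplyr::group_by(quarter = .data$quarter) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data[[v]]),
                       sd = stats::sd(.data[[v]]), .groups = "drop") |>
      dplyr::mutate(variable = v, test = "welch_anova",
                    p_value = pv, .before = 1)
  })
  rows <- rows |>
    dplyr::group_by(.data$variable) |>
    dplyr::mutate(relative_mean = .data$mean / .data$mean[.data$quarter == 1]) |>
    dplyr::ungroup()
  if (sex == "F" && dplyr::n_distinct(ph$menopausal_status) > 1) {
    chi <- suppressWarnings(chi_squared_quarters(ph$menopausal_status, ph$quarter))
    men <- ph |>
      dplyr::group_by(quarter = .data$quarter) |>
      dplyr::summarise(n = dplyr::n(),
                       mean = mean(.data$menopausal_status == "post"),
                       sd = NA_real_, .groups = "drop") |>
      dplyr::mutate(variable = "menopause_post_share", test = "chi_squared",
                    p_value = chi$p_value, .before = 1) |>
      dplyr::mutate(relative_mean = NA_real_)
    rows <- dplyr::bind_rows(rows, men)
  }
  rows
}
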