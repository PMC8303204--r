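# broom-style tidy()/glance() methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PLS model
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return Tibble with one row per predictor: `term`, `estimate` (regression
#'   coefficient on the original predictor scale), `abs_rank`.
#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 abs_rank = rank(-abs(x$coefficients), ties.method = "average"))
}

#' @rdname tidy.pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_predictors = length(x$coefficients),
                 intercept = x$intercept)
}

#' Tidy a rank-product result
#' @param x A `rank_product_result`.
#' @param ... Unused.
#' @return The per-analyte table (rank product, permutation frequency and
#'   significance when available).
#' @export
tidy.rank_product_result <- function(x, ...) x$table

#' @rdname tidy.rank_product_result
#' @export
glance.rank_product_result <- function(x, ...) {
  tibble::tibble(n_analytes = nrow(x$table),
                 n_splits = ncol(x$ranks),
                 mean_test_rmse = x$mean_test_rmse,
                 n_permutations = if (is.null(x$perm_mean_test_rmse)) 0L else
                   length(x$perm_mean_test_rmse),
                 perm_mean_test_rmse = if (is.null(x$perm_mean_test_rmse))
                   NA_real_ else mean(x$perm_mean_test_rmse),
                 n_significant = if (is.null(x$table$significant)) NA_integer_ else
                   sum(x$table$significant))
}

#' Tidy a final stepwise model
#' @param x A `crf_final_model`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `selection_frequency` (NA for the
#'   fixed block and the intercept).
#' @export
tidy.crf_final_model <- function(x, ...) {
  freq <- x$frequencies[x$variables]
  tibble::tibble(term = c("(Intercept)", x$variables),
                 estimate = c(x$intercept, unname(x$coefficients[x$variables])),
                 selection_frequency = c(NA_real_, unname(freq)))
}

#' @rdname tidy.crf_final_model
#' @export
glance.crf_final_model <- function(x, ...) {
  tibble::tibble(approach = x$approach, sex = x$sex, n = x$n,
                 n_variables = length(x$variables),
                 r2 = x$r2, adjusted_r2 = x$adjusted_r2)
}
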