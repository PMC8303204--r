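# Multivariate association: nested cross-validated PLS, coefficient rank
# products across random outer splits, and permutation significance.

#' Configuration for the rank-product procedure
#'
#' Defaults follow the analysis design: 20 random 80/20 outer splits, a
#' single random eight-fold inner cross-validation tuning at most ten
#' components, 2500 response permutations, and a 0.05 significance cutoff.
#' `permutation_mode` chooses between re-running the full outer procedure per
#' permutation (`"full_refit"`, faithful but expensive) and reusing the outer
#' splits and tuned component counts (`"fast_reuse"`).
#'
#' @param n_outer_splits,calibration_fraction,inner_folds,max_components
#'   Outer/inner loop sizes.
#' @param n_permutations,alpha Permutation test settings.
#' @param seed Integer seed governing every random draw of the procedure.
#' @param permutation_mode `"fast_reuse"` or `"full_refit"`.
#' @return A list of class `pls_config`.
#' @export
pls_config <- function(n_outer_splits = 20, calibration_fraction = 0.8,
                       inner_folds = 8, max_components = 10,
                       n_permutations = 2500, alpha = 0.05, seed = 1,
                       permutation_mode = c("fast_reuse", "full_refit")) {
  permutation_mode <- match.arg(permutation_mode)
  stopifnot(inner_folds >= 2, max_components >= 1, alpha > 0, alpha < 1,
            calibration_fraction > 0, calibration_fraction < 1,
            n_outer_splits >= 1)
  structure(list(n_outer_splits = n_outer_splits,
                 calibration_fraction = calibration_fraction,
                 inner_folds = inner_folds, max_components = max_components,
                 n_permutations = n_permutations, alpha = alpha, seed = seed,
                 permutation_mode = permutation_mode),
            class = "pls_config")
}

# One pass over the outer splits: rank |coefficients| per split (rank 1 =
# largest, average ranks on ties) and record test RMSE. `ncomps = NULL`
# triggers inner tuning per split.
rank_pass <- function(X, y, splits, config, ncomps = NULL, tune_seed_offset = 0) {
  p <- ncol(X)
  S <- length(splits)
  ranks <- matrix(NA_real_, p, S)
  rmse <- numeric(S)
  used <- integer(S)
  for (s in seq_len(S)) {
    cal <- splits[[s]]
    k <- if (is.null(ncomps)) {
      with_seed(derive_seed(config$seed, tune_seed_offset + s), {
        tune_ncomp(X[cal, , drop = FALSE], y[cal],
                   inner_folds = config$inner_folds,
                   max_components = config$max_components)$n_components
      })
    } else ncomps[s]
    fit <- fit_pls(X[cal, , drop = FALSE], y[cal], k)
    used[s] <- fit$n_components
    ranks[, s] <- rank(-abs(fit$coefficients), ties.method = "average")
    pred <- predict(fit, X[-cal, , drop = FALSE])
    rmse[s] <- sqrt(mean((y[-cal] - pred)^2))
  }
  list(ranks = ranks, rmse = rmse, ncomps = used)
}

geometric_mean_ranks <- function(ranks) exp(rowMeans(log(ranks)))

#' Rank products of PLS coefficients over random outer splits
#'
#' For each outer split, 80% of the samples calibrate a PLS model (unit
#' variance scaling and inner tuning use the calibration data only); each
#' analyte is ranked by the negative absolute value of its regression
#' coefficient (rank 1 = largest magnitude, average ranks on ties). The rank
#' product is the geometric mean of an analyte's ranks across splits. Inputs
#' are expected already confounder-adjusted per sex.
#'
#' @param X Numeric matrix (samples x analytes) of adjusted scores.
#' @param y Adjusted response vector.
#' @param config A [pls_config()].
#' @return An object of class `rank_product_result`: `table` (tibble with
#'   `analyte`, `rank_product`), `ranks` (analytes x splits), `splits`,
#'   `ncomps`, `mean_test_rmse`.
#' @export
outer_rank_products <- function(X, y, config = pls_config()) {
  X <- as.matrix(X)
  if (ncol(X) < 2) rlang::abort("need at least 2 analytes")
  n <- nrow(X)
  n_cal <- floor(config$calibration_fraction * n)
  if (n - n_cal < 1) rlang::abort("calibration fraction leaves no test samples")
  splits <- purrr::map(seq_len(config$n_outer_splits), function(s) {
    with_seed(derive_seed(config$seed, s), sort(sample(n, n_cal)))
  })
  pass <- rank_pass(X, y, splits, config, ncomps = NULL, tune_seed_offset = 5000)
  rp <- geometric_mean_ranks(pass$ranks)
  structure(list(table = tibble::tibble(analyte = colnames(X), rank_product = rp),
                 ranks = pass$ranks, splits = splits, ncomps = pass$ncomps,
                 mean_test_rmse = mean(pass$rmse), config = config),
            class = "rank_product_result")
}

#' @export
print.rank_product_result <- function(x, ...) {
  cat(sprintf("<rank_product_result> %d analytes, %d splits, mean test RMSE %.4f\n",
              nrow(x$table), ncol(x$ranks), x$mean_test_rmse))
  if (!is.null(x$table$perm_frequency)) {
    cat(sprintf("  %d significant at alpha = %.3g (%d permutations)\n",
                sum(x$table$significant), x$config$alpha, x$config$n_permutations))
  }
  invisible(x)
}

#' Permutation significance of rank products
#'
#' The (adjusted) response is permuted `n_permutations` times and the rank
#' products recomputed; an analyte's permutation frequency is the fraction
#' of permutations whose rank product falls strictly below the observed one
#' (ties count as not below). Frequencies at or below `alpha` are flagged
#' significant. The mean test RMSE of every permutation is recorded so the
#' overall model relevance can be checked against the observed RMSE.
#'
#' @param X,y As in [outer_rank_products()].
#' @param observed The result of [outer_rank_products()] on the same data.
#' @param config A [pls_config()]; `permutation_mode` selects whether splits
#'   and tuned component counts are reused (`"fast_reuse"`) or the whole
#'   outer procedure re-run (`"full_refit"`).
#' @return The `rank_product_result` with `perm_frequency` and `significant`
#'   columns added to `table`, plus `perm_mean_test_rmse`.
#' @export
permutation_significance <- function(X, y, observed, config = observed$config) {
  if (config$n_permutations < 1) rlang::abort("n_permutations must be >= 1")
  X <- as.matrix(X)
  n <- nrow(X)
  perms <- with_seed(derive_seed(config$seed, 777),
                     replicate(config$n_permutations, sample.int(n)))
  rp_obs <- observed$table$rank_product
  below <- numeric(length(rp_obs))
  perm_rmse <- numeric(config$n_permutations)
  reuse <- identical(config$permutation_mode, "fast_reuse")
  for (b in seq_len(config$n_permutations)) {
    yp <- y[perms[, b]]
    pass <- rank_pass(X, yp, observed$splits, config,
                      ncomps = if (reuse) observed$ncomps else NULL,
                      tune_seed_offset = 100000 + b * config$n_outer_splits)
    rp_b <- geometric_mean_ranks(pass$ranks)
    below <- below + (rp_b < rp_obs)
    perm_rmse[b] <- mean(pass$rmse)
  }
  freq <- below / config$n_permutations
  out <- observed
  out$table$perm_frequency <- freq
  out$table$significant <- freq <= config$alpha
  out$perm_mean_test_rmse <- perm_rmse
  out$config <- config
  out
}

#' Combine bivariate and multivariate association results for a volcano view
#'
#' One row per analyte: the partial correlation (x-axis), the negative log10
#' permutation frequency (y-axis; frequencies of zero are floored at
#' `1/(n_permutations + 1)` to stay finite), the major pathway, and the
#' relevance class — relevant when `|r| >= 0.25` or when the multivariate
#' contribution is significant.
#'
#' @param bivariate [correlate_all()] result (confounder-adjusted profile).
#' @param multivariate A `rank_product_result` with permutation fields.
#' @param annotation Annotation tibble.
#' @param relevance Threshold on `|r|` (default 0.25).
#' @return Tibble: `analyte`, `r`, `rank_product`, `perm_frequency`,
#'   `neg_log10_perm_frequency`, `pathway`, `relevant`.
#' @export
volcano_table <- function(bivariate, multivariate, annotation, relevance = 0.25) {
  if (!setequal(bivariate$variable, multivariate$table$analyte)) {
    rlang::abort("bivariate and multivariate results cover different analytes")
  }
  if (is.null(multivariate$table$perm_frequency)) {
    rlang::abort("multivariate result lacks permutation frequencies")
  }
  floor_p <- 1 / (multivariate$config$n_permutations + 1)
  multivariate$table |>
    dplyr::inner_join(dplyr::select(bivariate, analyte = "variable", "r"),
                      by = "analyte") |>
    dplyr::left_join(dplyr::select(annotation, analyte = "analyte_id",
                                   pathway = "major_pathway"),
                     by = "analyte") |>
    dplyr::mutate(
      neg_log10_perm_frequency = -log10(pmax(.data$perm_frequency, floor_p)),
      relevant = abs(.data$r) >= relevance | .data$significant) |>
    dplyr::select("analyte", "r", "rank_product", "perm_frequency",
                  "neg_log10_perm_frequency", "pathway", "relevant")
}
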