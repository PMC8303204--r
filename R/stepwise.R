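# Stepwise forward regression ranked by R-squared, repeated cross-validated
# selection with stop-at-first-degradation, and frequency-thresholded final
# models.

# Greedy forward selection by R^2 via incremental Gram-Schmidt: at each step
# the candidate whose calibration residual has the largest squared
# correlation with the current response residual is entered, then the
# remaining candidates and the response are orthogonalized against it. This
# is exact greedy R^2 maximization at O(n p) per step.
forward_engine <- function(y, X_fixed, X_cand, max_steps = Inf, tol = 1e-10) {
  n <- length(y)
  cand_names <- colnames(X_cand)
  ord <- order(cand_names)  # lexicographic tie-break
  X_cand <- X_cand[, ord, drop = FALSE]
  cand_names <- cand_names[ord]
  Z <- cbind(rep(1, n), X_fixed)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) rlang::abort("fixed set is rank deficient")
  ry <- qr.resid(qz, y)
  R <- qr.resid(qz, X_cand)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) rlang::abort("response has zero variance")
  active <- rep(TRUE, length(cand_names))
  skipped <- character()
  steps <- tibble::tibble(variable = character(), cumulative_r2 = numeric())
  r2_fixed <- 1 - sum(ry^2) / tss
  while (sum(active) > 0 && nrow(steps) < max_steps) {
    ss <- colSums(R^2)
    degenerate <- active & ss < tol
    if (any(degenerate)) {   # collinear with current model: skip, log
      skipped <- c(skipped, cand_names[degenerate])
      active[degenerate] <- FALSE
      if (sum(active) == 0) break
    }
    gain <- rep(-Inf, length(cand_names))
    idx <- which(active)
    gain[idx] <- (crossprod(R[, idx, drop = FALSE], ry)^2)[, 1] / ss[idx]
    best <- which.max(gain)   # first max = smallest variable id among ties
    if (!is.finite(gain[best]) || gain[best] <= 0 && sum(ry^2) < tol) break
    u <- R[, best] / sqrt(ss[best])
    ry <- ry - u * sum(u * ry)
    active[best] <- FALSE
    idx <- which(active)
    if (length(idx) > 0) {
      proj <- crossprod(R[, idx, drop = FALSE], u)[, 1]
      R[, idx] <- R[, idx, drop = FALSE] - outer(u, proj)
    }
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      variable = cand_names[best],
      cumulative_r2 = 1 - sum(ry^2) / tss))
  }
  list(steps = steps, r2_fixed = r2_fixed, skipped = skipped)
}

#' Stepwise forward selection maximizing R-squared
#'
#' Starting from the (possibly empty) fixed variable set, each step enters
#' the candidate that maximizes the in-sample coefficient of determination;
#' ties are broken by variable id. Candidates collinear with the current
#' model are skipped and logged. All variables are expected
#' confounder-adjusted.
#'
#' @param data Tibble of scores.
#' @param response Response column name.
#' @param candidates Candidate column names.
#' @param fixed Columns entered before selection (disjoint from candidates).
#' @param max_steps Maximum number of selection steps.
#' @return A `stepwise_path`: tibble with `step`, `variable`,
#'   `cumulative_r2`; attributes `fixed`, `r2_fixed`, `skipped`.
#' @export
stepwise_forward <- function(data, response, candidates, fixed = character(),
                             max_steps = Inf) {
  if (length(intersect(fixed, candidates)) > 0) {
    rlang::abort("fixed and candidate sets must be disjoint")
  }
  miss <- setdiff(c(response, candidates, fixed), names(data))
  if (length(miss) > 0) rlang::abort(paste0("unknown columns: ", paste(miss, collapse = ", ")))
  y <- data[[response]]
  Xf <- if (length(fixed) > 0) as.matrix(data[, fixed, drop = FALSE]) else NULL
  Xc <- as.matrix(data[, candidates, drop = FALSE])
  eng <- forward_engine(y, Xf, Xc, max_steps = max_steps)
  out <- dplyr::mutate(eng$steps, step = dplyr::row_number(), .before = 1)
  attr(out, "fixed") <- fixed
  attr(out, "r2_fixed") <- eng$r2_fixed
  attr(out, "skipped") <- eng$skipped
  class(out) <- c("stepwise_path", class(out))
  out
}

# OLS fit/predict helper on named columns.
ols_fit <- function(data, response, variables) {
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, variables, drop = FALSE]))
  qx <- qr(X)
  coef <- qr.coef(qx, data[[response]])
  coef[is.na(coef)] <- 0
  coef
}

ols_predict <- function(coef, data) {
  vars <- setdiff(names(coef), "(Intercept)")
  as.numeric(coef["(Intercept)"] +
               as.matrix(data[, vars, drop = FALSE]) %*% coef[vars])
}

#' Cross-validated stepwise selection frequencies
#'
#' Repeats `n_repeats` times: draw a random calibration/test split, run
#' forward selection on the calibration set, and after each entered variable
#' evaluate the test-set RMSE; selection stops the first time the test RMSE
#' increases, and the degrading variable is not counted as selected. The
#' selection frequency of a variable is the fraction of repeats in which it
#' was selected.
#'
#' @inheritParams stepwise_forward
#' @param n_repeats Number of random splits (default 1000).
#' @param calibration_fraction Calibration share (default 0.8).
#' @param seed Integer seed.
#' @param max_steps Cap on entered variables per repeat.
#' @return A `selection_frequencies` tibble: `variable`, `frequency`;
#'   attributes `n_repeats` and `selected_sizes` (per-repeat counts).
#' @export
cv_stepwise_frequencies <- function(data, response, candidates,
                                    fixed = character(), n_repeats = 1000,
                                    calibration_fraction = 0.8, seed = 1,
                                    max_steps = Inf) {
  n <- nrow(data)
  n_cal <- floor(calibration_fraction * n)
  if (n - n_cal < 5) rlang::abort("test set must contain at least 5 samples")
  counts <- stats::setNames(numeric(length(candidates)), candidates)
  sizes <- integer(n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    cal_idx <- with_seed(derive_seed(seed, rep_i), sort(sample(n, n_cal)))
    cal <- data[cal_idx, , drop = FALSE]
    test <- data[-cal_idx, , drop = FALSE]
    path <- stepwise_forward(cal, response, candidates, fixed,
                             max_steps = max_steps)
    coef0 <- ols_fit(cal, response, fixed)
    rmse_prev <- sqrt(mean((test[[response]] - ols_predict(coef0, test))^2))
    selected <- character()
    for (v in path$variable) {
      coef <- ols_fit(cal, response, c(fixed, selected, v))
      rmse <- sqrt(mean((test[[response]] - ols_predict(coef, test))^2))
      if (rmse > rmse_prev) break  # first degradation: v excluded, stop
      selected <- c(selected, v)
      rmse_prev <- rmse
    }
    counts[selected] <- counts[selected] + 1
    sizes[rep_i] <- length(selected)
  }
  out <- tibble::tibble(variable = candidates, frequency = counts / n_repeats)
  attr(out, "n_repeats") <- n_repeats
  attr(out, "selected_sizes") <- sizes
  class(out) <- c("selection_frequencies", class(out))
  out
}

#' Final model from selection frequencies
#'
#' All candidates with selection frequency at or above `threshold` (plus the
#' fixed set) are fitted jointly by least squares on all samples; variables
#' are ordered by frequency, descending. An empty selection yields the
#' intercept-only model with R-squared zero.
#'
#' @param data Tibble of scores.
#' @param response Response column name.
#' @param frequencies A [cv_stepwise_frequencies()] result.
#' @param threshold Inclusion threshold (default 0.05; the rule is `>=`).
#' @param fixed Variables always included, listed first.
#' @param approach Optional approach label (1, 2 or 3) carried in the result.
#' @param sex Optional sex label carried in the result.
#' @return A `crf_final_model` with `variables`, `coefficients`, `intercept`,
#'   `r2`, `adjusted_r2`, `frequencies`, `n`.
#' @export
build_final_model <- function(data, response, frequencies, threshold = 0.05,
                              fixed = character(), approach = NA_integer_,
                              sex = NA_character_) {
  if (threshold <= 0 || threshold > 1) rlang::abort("threshold must lie in (0, 1]")
  sel <- frequencies |>
    dplyr::filter(.data$frequency >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$variable)
  vars <- c(fixed, sel$variable)
  y <- data[[response]]
  n <- length(y)
  if (length(vars) == 0) {
    coef <- c(`(Intercept)` = mean(y))
    r2 <- 0
  } else {
    coef <- ols_fit(data, response, vars)
    fitted <- ols_predict(coef, data)
    r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  }
  p <- length(vars)
  adj <- if (n - p - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  freq_map <- stats::setNames(frequencies$frequency, frequencies$variable)
  structure(list(approach = approach, sex = sex, variables = vars,
                 coefficients = coef[setdiff(names(coef), "(Intercept)")],
                 intercept = unname(coef["(Intercept)"]),
                 r2 = r2, adjusted_r2 = adj, n = n,
                 frequencies = freq_map[vars]),
            class = "crf_final_model")
}

#' @export
print.crf_final_model <- function(x, ...) {
  cat(sprintf("<crf_final_model> approach %s, %d variables, R2 = %.3f, adj R2 = %.3f\n",
              ifelse(is.na(x$approach), "?", x$approach),
              length(x$variables), x$r2, x$adjusted_r2))
  if (length(x$variables) > 0) cat("  ", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' Run one of the three model-building approaches
#'
#' Approach 1: only the 21 phenotypical/clinical variables are stepwise
#' selected. Approach 2: all phenotypical/clinical variables are fixed in
#' the model and only metabolites are selected. Approach 3: phenotypical/
#' clinical variables and metabolites compete. Each approach yields the
#' in-sample ranking path, the cross-validated selection frequencies, and
#' the frequency-thresholded final model.
#'
#' @param approach 1, 2 or 3.
#' @param data Confounder-adjusted score tibble.
#' @param response Response column.
#' @param pheno_vars The phenotypical/clinical variable names.
#' @param metabolite_vars The metabolite variable names.
#' @param n_repeats,calibration_fraction,seed,threshold,max_steps Selection
#'   settings (see [cv_stepwise_frequencies()] / [build_final_model()]).
#' @param sex Optional sex label for the final model.
#' @return List with `path`, `frequencies`, `final_model`.
#' @export
run_approach <- function(approach, data, response, pheno_vars, metabolite_vars,
                         n_repeats = 1000, calibration_fraction = 0.8,
                         seed = 1, threshold = 0.05, max_steps = Inf,
                         sex = NA_character_) {
  if (!approach %in% 1:3) rlang::abort("approach must be 1, 2 or 3")
  if (length(intersect(pheno_vars, metabolite_vars)) > 0) {
    rlang::abort("variable sets must be disjoint")
  }
  wiring <- switch(as.character(approach),
    "1" = list(fixed = character(), candidates = pheno_vars),
    "2" = list(fixed = pheno_vars, candidates = metabolite_vars),
    "3" = list(fixed = character(), candidates = c(pheno_vars, metabolite_vars)))
  path <- stepwise_forward(data, response, wiring$candidates, wiring$fixed,
                           max_steps = max_steps)
  freqs <- cv_stepwise_frequencies(data, response, wiring$candidates,
                                   wiring$fixed, n_repeats = n_repeats,
                                   calibration_fraction = calibration_fraction,
                                   seed = seed, max_steps = max_steps)
  final <- build_final_model(data, response, freqs, threshold = threshold,
                             fixed = wiring$fixed, approach = approach,
                             sex = sex)
  list(path = path, frequencies = freqs, final_model = final)
}
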