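# Matrix integration filters, rank-based inverse normal (Van der Waerden)
# scoring, confounder residualization, and random-forest imputation of the
# two imputable covariates.

new_report <- function(n_samples_in, n_samples_out, n_analytes_in, n_analytes_out,
                       removed_duplicates = character(), removed_low_frequency = character(),
                       removed_samples = character(), imputed_cells = tibble::tibble(
                         sample_id = character(), covariate = character())) {
  list(n_samples_in = n_samples_in, n_samples_out = n_samples_out,
       n_analytes_in = n_analytes_in, n_analytes_out = n_analytes_out,
       removed_duplicates = removed_duplicates,
       removed_low_frequency = removed_low_frequency,
       removed_samples = removed_samples,
       imputed_cells = imputed_cells)
}

#' Tabular view of a preprocessing report
#' @param report A report as returned by the preprocessing steps.
#' @return One-row tibble of counts.
#' @export
report_table <- function(report) {
  tibble::tibble(
    n_samples_in = report$n_samples_in, n_samples_out = report$n_samples_out,
    n_analytes_in = report$n_analytes_in, n_analytes_out = report$n_analytes_out,
    n_removed_duplicates = length(report$removed_duplicates),
    n_removed_low_frequency = length(report$removed_low_frequency),
    n_removed_samples = length(report$removed_samples),
    n_imputed_cells = nrow(report$imputed_cells))
}

#' Drop samples from a metabolite matrix
#'
#' Used for cohort exclusions (e.g. missing exercise-test data); bookkeeping
#' is recorded in the report.
#'
#' @param x A `metabolite_matrix`.
#' @param sample_ids Samples to remove.
#' @return List with `matrix` and `report`.
#' @export
drop_samples <- function(x, sample_ids) {
  before <- mm_samples(x)
  unknown <- setdiff(sample_ids, before)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown samples: ", paste(unknown, collapse = ", ")))
  }
  kept <- dplyr::filter(x$values, !(.data$sample_id %in% sample_ids))
  out <- metabolite_matrix(kept, x$annotation)
  list(matrix = out,
       report = new_report(length(before), length(mm_samples(out)),
                           length(mm_analytes(x)), length(mm_analytes(out)),
                           removed_samples = sort(sample_ids)))
}

#' Resolve cross-platform duplicate analytes
#'
#' Where the same chemical species was measured on several platforms
#' (`duplicate_group` shared), only the copy from the most quantitative
#' method is kept: smallest `quantitative_rank`, ties broken by platform
#' order ([platform_levels()]) and then `analyte_id`.
#'
#' @param x A `metabolite_matrix`.
#' @return List with `matrix` and `report` (removed ids recorded).
#' @export
resolve_platform_duplicates <- function(x) {
  ann <- x$annotation
  grouped <- dplyr::filter(ann, .data$duplicate_group != "")
  drop <- character()
  if (nrow(grouped) > 0) {
    ranked <- grouped |>
      dplyr::mutate(platform_ord = match(.data$platform, platform_levels())) |>
      dplyr::arrange(.data$duplicate_group, .data$quantitative_rank,
                     .data$platform_ord, .data$analyte_id)
    drop <- ranked |>
      dplyr::group_by(.data$duplicate_group) |>
      dplyr::slice(-1) |>
      dplyr::ungroup() |>
      dplyr::pull("analyte_id")
  }
  kept <- dplyr::filter(x$values, !(.data$analyte_id %in% drop))
  out <- metabolite_matrix(kept, dplyr::filter(ann, !(.data$analyte_id %in% drop)))
  list(matrix = out,
       report = new_report(length(mm_samples(x)), length(mm_samples(out)),
                           length(mm_analytes(x)), length(mm_analytes(out)),
                           removed_duplicates = sort(drop)))
}

#' Filter analytes by sex-specific detection frequency
#'
#' An analyte is kept only if its detection frequency is at least `min_freq`
#' in both the female and the male subgroup; analytes detected in fewer
#' samples in either subgroup are removed.
#'
#' @param x A `metabolite_matrix`.
#' @param sex Named character vector (or tibble column) of `"F"`/`"M"` labels
#'   aligned to `mm_samples(x)` via names, or a phenotype tibble.
#' @param min_freq Minimum detection frequency (default 0.20).
#' @param count_lod_as_detected Passed to [detection_frequency()].
#' @param subgroups Sexes whose frequencies are checked (default both); a
#'   requested subgroup without samples is an error.
#' @return List with `matrix` and `report`.
#' @export
filter_detection_frequency <- function(x, sex, min_freq = 0.20,
                                       count_lod_as_detected = FALSE,
                                       subgroups = c("F", "M")) {
  if (is.data.frame(sex)) sex <- stats::setNames(sex$sex, sex$sample_id)
  samples <- mm_samples(x)
  if (!all(samples %in% names(sex))) rlang::abort("sex labels must cover every sample")
  sex <- sex[samples]
  freqs <- purrr::map(stats::setNames(subgroups, subgroups), function(s) {
    sub <- samples[sex == s]
    if (length(sub) == 0) rlang::abort(paste0("subgroup ", s, " has no samples"))
    detection_frequency(x, samples = sub,
                        count_lod_as_detected = count_lod_as_detected)$frequency
  })
  low <- Reduce(`|`, purrr::map(freqs, ~ .x < min_freq))
  drop <- detection_frequency(x)$analyte_id[low]
  kept <- dplyr::filter(x$values, !(.data$analyte_id %in% drop))
  out <- metabolite_matrix(kept, dplyr::filter(x$annotation, !(.data$analyte_id %in% drop)))
  list(matrix = out,
       report = new_report(length(samples), length(samples),
                           length(mm_analytes(x)), length(mm_analytes(out)),
                           removed_low_frequency = sort(drop)))
}

#' Van der Waerden (rank-based inverse normal) transform
#'
#' Values are converted to ranks (average ranks on ties), rescaled to
#' rank/(n+1), and mapped through the standard normal quantile function.
#' Below-LOD entries are retained and share the tied minimum rank; missing
#' entries propagate as `NA` and do not consume ranks.
#'
#' @param values Numeric vector; `NA` where not detected.
#' @param lod Logical vector marking below-LOD entries (their `values` are
#'   ignored). Default: none.
#' @param strict Error on a fully tied (degenerate) vector instead of
#'   returning all-zero scores.
#' @return Numeric vector of scores, `NA` where input was missing.
#' @export
vdw_transform <- function(values, lod = NULL, strict = FALSE) {
  if (is.null(lod)) lod <- rep(FALSE, length(values))
  stopifnot(length(lod) == length(values))
  obs <- lod | !is.na(values)
  n <- sum(obs)
  if (n < 3) rlang::abort("need at least 3 non-missing entries")
  work <- values
  finite_min <- suppressWarnings(min(values[obs & !lod], na.rm = TRUE))
  if (!is.finite(finite_min)) finite_min <- 0
  work[lod] <- finite_min - 1  # a common value below every observation
  r <- rank(work[obs], ties.method = "average")
  if (length(unique(r)) == 1) {
    if (strict) rlang::abort("degenerate vector: all values tied")
    scores <- rep(0, n)
  } else {
    scores <- stats::qnorm(r / (n + 1))
  }
  out <- rep(NA_real_, length(values))
  out[obs] <- scores
  out
}

#' Van der Waerden scores for every analyte of a metabolite matrix
#'
#' Applies [vdw_transform()] per analyte over a sample subset (typically one
#' sex), returning a tidy score table.
#'
#' @param x A `metabolite_matrix`.
#' @param samples Optional sample subset.
#' @param strict Passed to [vdw_transform()].
#' @return Tibble: `sample_id` plus one numeric column per analyte.
#' @export
vdw_score_table <- function(x, samples = NULL, strict = FALSE) {
  vals <- mm_value_matrix(x)
  stat <- mm_status_matrix(x)
  if (!is.null(samples)) {
    vals <- vals[samples, , drop = FALSE]
    stat <- stat[samples, , drop = FALSE]
  }
  scored <- vapply(seq_len(ncol(vals)), function(j) {
    vdw_transform(vals[, j], lod = stat[, j] == "below_lod", strict = strict)
  }, numeric(nrow(vals)))
  colnames(scored) <- colnames(vals)
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(vals)),
                   tibble::as_tibble(scored))
}

#' Least-squares residualization on a covariate set
#'
#' Residuals of `y` on an intercept plus the covariate columns; the standard
#' reading of "adjusted for". Residuals have mean zero and are orthogonal to
#' every covariate.
#'
#' @param y Numeric vector, no missing values.
#' @param covariates Numeric matrix/data frame (may have zero columns).
#' @return Numeric vector of residuals.
#' @export
residualize <- function(y, covariates = NULL) {
  if (anyNA(y)) rlang::abort("y contains missing values")
  if (is.null(covariates) || NCOL(covariates) == 0) return(y - mean(y))
  X <- cbind(intercept = 1, as.matrix(covariates))
  if (anyNA(X)) rlang::abort("covariates contain missing values")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[-qr_x$pivot[seq_len(qr_x$rank)]]
    rlang::abort(paste0("rank-deficient covariate set; collinear: ",
                        paste(bad, collapse = ", ")))
  }
  as.numeric(qr.resid(qr_x, y))
}

#' Residualize every column of a score table
#'
#' @param data Tibble of numeric score columns (plus optional `sample_id`).
#' @param covariates Character vector of column names in `data` to adjust
#'   for; removed from the output.
#' @return Tibble with the same non-covariate columns, residualized; the
#'   adjustment set is stored in attribute `"adjustment_set"`.
#' @export
residualize_columns <- function(data, covariates) {
  data <- tibble::as_tibble(data)
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0) rlang::abort(paste0("unknown covariates: ", paste(miss, collapse = ", ")))
  id <- intersect("sample_id", names(data))
  C <- as.matrix(data[, covariates, drop = FALSE])
  targets <- setdiff(names(data), c(id, covariates))
  out <- data[, c(id, targets)]
  for (v in targets) out[[v]] <- residualize(data[[v]], C)
  attr(out, "adjustment_set") <- covariates
  out
}

#' Random-forest imputation of AEE and PWV
#'
#' Missing values in the imputable covariates are predicted by a random
#' forest (500 trees, single pass) trained on the complete cases, using sex,
#' age and the remaining covariates as predictors. Deterministic for a given
#' seed; imputed values lie within the observed range of the target.
#'
#' @param pheno Phenotype tibble.
#' @param targets Covariates to impute (default both imputable ones).
#' @param seed Integer seed.
#' @param num_trees Number of trees (default 500).
#' @return List with `pheno` (completed tibble) and `report`.
#' @export
impute_random_forest <- function(pheno, targets = imputable_covariates(),
                                 seed = 1, num_trees = 500) {
  bad <- setdiff(targets, imputable_covariates())
  if (length(bad) > 0) rlang::abort(paste0("not imputable: ", paste(bad, collapse = ", ")))
  imputed <- tibble::tibble(sample_id = character(), covariate = character())
  out <- pheno
  for (tg in targets) {
    miss <- is.na(out[[tg]])
    if (!any(miss)) next
    if (all(miss)) rlang::abort(paste0(tg, " is entirely missing"))
    preds <- c("sex", "age", setdiff(covariate_names(), tg))
    train <- out[!miss, c(tg, preds)]
    train <- train[stats::complete.cases(train), ]
    if (nrow(train) < 20) rlang::abort(paste0("fewer than 20 complete cases for ", tg))
    train$sex <- factor(train$sex, levels = c("F", "M"))
    test <- out[miss, preds]
    test$sex <- factor(test$sex, levels = c("F", "M"))
    # ranger cannot predict from rows with NA predictors; fill the other
    # imputable column with the training median for prediction only
    for (p in setdiff(preds, c("sex", "age"))) {
      na_p <- is.na(test[[p]])
      if (any(na_p)) test[[p]][na_p] <- stats::median(train[[p]], na.rm = TRUE)
    }
    fit <- with_seed(derive_seed(seed, match(tg, imputable_covariates())), {
      ranger::ranger(stats::as.formula(paste(tg, "~ .")), data = train,
                     num.trees = num_trees, seed = derive_seed(seed, 100 + match(tg, imputable_covariates())))
    })
    pred <- stats::predict(fit, data = test)$predictions
    out[[tg]][miss] <- pred
    imputed <- dplyr::bind_rows(imputed,
                                tibble::tibble(sample_id = out$sample_id[miss],
                                               covariate = tg))
  }
  list(pheno = out,
       report = new_report(nrow(pheno), nrow(out), 0L, 0L, imputed_cells = imputed))
}

#' Sex-stratified score table for one subgroup
#'
#' Builds the per-sex analysis table: Van der Waerden scores of every kept
#' analyte, of VO2peak, and of the 21 covariates, plus the confounder
#' columns (`age` score and, for females, a 0/1 menopause indicator). All
#' downstream statistics run on this table.
#'
#' @param x A preprocessed `metabolite_matrix`.
#' @param pheno Completed phenotype tibble (no missing covariates).
#' @param sex `"F"` or `"M"`.
#' @return Tibble: `sample_id`, `vo2peak`, confounders, covariates, analytes
#'   (all as scores). Attribute `"confounders"` names the confounder columns.
#' @export
sex_score_table <- function(x, pheno, sex) {
  ph <- dplyr::filter(pheno, .data$sex == !!sex)
  ph <- dplyr::arrange(ph, .data$sample_id)
  samples <- intersect(mm_samples(x), ph$sample_id)
  if (length(samples) == 0) rlang::abort(paste0("no samples for sex ", sex))
  ph <- dplyr::filter(ph, .data$sample_id %in% samples)
  scores <- tibble::tibble(sample_id = ph$sample_id,
                           vo2peak = vdw_transform(ph$vo2peak),
                           age = vdw_transform(ph$age))
  confs <- "age"
  if (sex == "F") {
    scores$menopause <- as.numeric(ph$menopausal_status == "post")
    confs <- c("age", "menopause")
  }
  for (v in covariate_names()) scores[[v]] <- vdw_transform(ph[[v]])
  analyte_scores <- vdw_score_table(x, samples = samples)
  out <- dplyr::inner_join(scores, analyte_scores, by = "sample_id")
  attr(out, "confounders") <- confs
  out
}
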