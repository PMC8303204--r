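# Orchestration of the full sex-stratified analysis: preprocessing,
# descriptives, bivariate correlations, PLS rank products, stepwise
# selection, and the volcano table, written as a file bundle.

#' Pipeline configuration
#'
#' @param min_freq Detection-frequency threshold (default 0.20).
#' @param pls A [pls_config()]; its seed is overridden by `seed`.
#' @param n_repeats,threshold,calibration_fraction Stepwise settings.
#' @param stepwise_max_steps Cap on stepwise entries per repeat.
#' @param approaches Which model-building approaches to run (subset of 1:3).
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_freq = 0.20, pls = pls_config(n_permutations = 200),
                            n_repeats = 1000, threshold = 0.05,
                            calibration_fraction = 0.8,
                            stepwise_max_steps = 15, approaches = 1:3,
                            seed = 1) {
  structure(list(min_freq = min_freq, pls = pls, n_repeats = n_repeats,
                 threshold = threshold,
                 calibration_fraction = calibration_fraction,
                 stepwise_max_steps = stepwise_max_steps,
                 approaches = approaches, seed = seed),
            class = "pipeline_config")
}

final_model_table <- function(models) {
  purrr::map_dfr(models, function(fm) {
    tibble::tibble(approach = fm$approach, sex = fm$sex,
                   n = fm$n, n_variables = length(fm$variables),
                   r2 = fm$r2, adjusted_r2 = fm$adjusted_r2,
                   variables = paste(fm$variables, collapse = ";"))
  })
}

#' Run the full sex-stratified association pipeline
#'
#' Per sex: preprocessing report, quarter summaries, confounder-adjusted
#' (`*`) and fully adjusted (`**`) correlation tables, the pathway summary,
#' PLS rank products with permutation significance, the volcano table, and
#' the approach 1-3 final models. All artifacts are written as delimited
#' text under `out_dir` together with a plain-text manifest.
#'
#' @param pheno Phenotype tibble (see [read_phenotype_table()]).
#' @param metabolites A `metabolite_matrix`.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param exclude_samples Optional sample ids to drop before anything else.
#' @return Invisibly, a list with every per-sex result plus the combined
#'   preprocessing report.
#' @export
run_pipeline <- function(pheno, metabolites, out_dir,
                         config = pipeline_config(),
                         exclude_samples = character()) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(sprintf("seed: %d", config$seed),
                sprintf("started: %s", format(t0, "%Y-%m-%d %H:%M:%S")))
  stage <- function(msg) {
    manifest <<- c(manifest, sprintf("%s  [%.1fs]", msg,
                                     as.numeric(Sys.time() - t0, units = "secs")))
  }
  pheno <- validate_phenotype(pheno)
  pheno <- dplyr::filter(pheno, !(.data$sample_id %in% exclude_samples))
  mm <- metabolites
  if (length(exclude_samples) > 0) {
    drop <- intersect(exclude_samples, mm_samples(mm))
    if (length(drop) > 0) mm <- drop_samples(mm, drop)$matrix
  }
  common <- intersect(mm_samples(mm), pheno$sample_id)
  mm <- if (setequal(common, mm_samples(mm))) mm else
    drop_samples(mm, setdiff(mm_samples(mm), common))$matrix
  pheno <- dplyr::filter(pheno, .data$sample_id %in% common)
  n_samples_in <- length(common)
  n_analytes_in <- length(mm_analytes(mm))

  dedup <- resolve_platform_duplicates(mm)
  filt <- filter_detection_frequency(dedup$matrix, pheno, min_freq = config$min_freq,
                                     subgroups = intersect(c("F", "M"),
                                                           unique(pheno$sex)))
  mm <- filt$matrix
  stage("preprocess: duplicates + detection filter")

  imput <- impute_random_forest(pheno, seed = derive_seed(config$seed, 11))
  pheno <- imput$pheno
  stage("preprocess: covariate imputation")

  report <- new_report(n_samples_in, length(mm_samples(mm)),
                       n_analytes_in, length(mm_analytes(mm)),
                       removed_duplicates = dedup$report$removed_duplicates,
                       removed_low_frequency = filt$report$removed_low_frequency,
                       removed_samples = exclude_samples,
                       imputed_cells = imput$report$imputed_cells)
  write_results(report_table(report), file.path(out_dir, "preprocess_report.tsv"))

  sexes <- intersect(c("F", "M"), unique(pheno$sex))
  analytes <- mm_analytes(mm)
  results <- list(report = report, config = config)
  for (sx in sexes) {
    pre <- paste0(tolower(sx), "_")
    quarters <- quarter_summary_table(pheno, sx)
    write_results(quarters, file.path(out_dir, paste0(pre, "quarter_summary.tsv")))
    stage(paste0(sx, ": quarter summaries"))

    scores <- sex_score_table(mm, pheno, sx)
    confs <- attr(scores, "confounders")
    star <- correlate_all(scores, "vo2peak", analytes, covariates = confs)
    doublestar <- correlate_all(scores, "vo2peak", analytes,
                                covariates = c(confs, covariate_names()))
    pathway <- summarize_by_pathway(star, doublestar, mm$annotation)
    write_results(star, file.path(out_dir, paste0(pre, "correlations_star.tsv")))
    write_results(doublestar, file.path(out_dir, paste0(pre, "correlations_doublestar.tsv")))
    write_results(pathway, file.path(out_dir, paste0(pre, "pathway_summary.tsv")))
    stage(paste0(sx, ": bivariate correlations"))

    adj <- residualize_columns(scores[, c("vo2peak", confs, analytes)], confs)
    X <- as.matrix(adj[, analytes, drop = FALSE])
    y <- adj$vo2peak
    plsc <- config$pls
    plsc$seed <- derive_seed(config$seed, 20 + match(sx, c("F", "M")))
    rp <- outer_rank_products(X, y, plsc)
    rp <- permutation_significance(X, y, rp, plsc)
    write_results(rp$table, file.path(out_dir, paste0(pre, "rank_products.tsv")))
    volcano <- volcano_table(star, rp, mm$annotation)
    write_results(volcano, file.path(out_dir, paste0(pre, "volcano.tsv")))
    stage(paste0(sx, ": PLS rank products (", plsc$n_permutations, " permutations)"))

    adj_all <- residualize_columns(
      scores[, c("vo2peak", confs, covariate_names(), analytes)], confs)
    models <- list()
    for (ap in config$approaches) {
      res <- run_approach(ap, adj_all, "vo2peak", covariate_names(), analytes,
                          n_repeats = config$n_repeats,
                          calibration_fraction = config$calibration_fraction,
                          seed = derive_seed(config$seed, 30 + 3 * match(sx, c("F", "M")) + ap),
                          threshold = config$threshold,
                          max_steps = config$stepwise_max_steps, sex = sx)
      models[[as.character(ap)]] <- res$final_model
      write_results(res$frequencies,
                    file.path(out_dir, paste0(pre, "stepwise_frequencies_approach", ap, ".tsv")))
    }
    write_results(final_model_table(models),
                  file.path(out_dir, paste0(pre, "final_models.tsv")))
    stage(paste0(sx, ": stepwise selection"))

    results[[sx]] <- list(quarters = quarters, star = star,
                          doublestar = doublestar, pathway = pathway,
                          rank_products = rp, volcano = volcano,
                          models = models)
  }
  manifest <- c(manifest,
                sprintf("R version: %s", getRversion()),
                sprintf("finished: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(results)
}
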