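#' Analytical platforms and pathway vocabulary
#'
#' Controlled vocabularies used by the annotation table. Platforms are ordered
#' from most to least quantitative for tie-breaking when a metabolite was
#' measured on several platforms; `nmr` and `gcxgc_ms` are the untargeted
#' platforms, the rest are targeted.
#'
#' @return Character vector of levels.
#' @export
platform_levels <- function() {
  c("lcms_p180", "lcms_amino", "lcms_bile", "gc_ms_fa", "nmr", "gcxgc_ms")
}

#' @rdname platform_levels
#' @export
pathway_levels <- function() {
  c("amino_acid", "carbohydrate", "cofactors_vitamins", "energy", "lipid",
    "mammalian_microbial", "nucleotide", "xenobiotics", "unknown")
}

#' @rdname platform_levels
#' @export
untargeted_platforms <- function() c("nmr", "gcxgc_ms")

#' Names of the phenotypical and clinical covariates
#'
#' The 21 body-composition, clinical-biochemistry, cardiovascular, lung
#' function, physical-activity and diet variables recorded per participant.
#' Only `AEE` and `PWV` may carry missing values (they are imputable).
#'
#' @return Character vector of length 21.
#' @export
covariate_names <- function() {
  c("LBM", "FM_pct", "VATM", "BMC", "height", "Hb", "glucose", "insulin",
    "HbA1c", "TGs", "HDL", "LDL", "HR_rest", "BP_sys", "BP_dia", "PWV",
    "VC_max", "FEV1", "AEE", "MET_total", "HEI_NVS")
}

#' @rdname covariate_names
#' @export
imputable_covariates <- function() c("AEE", "PWV")

# ---- annotation ------------------------------------------------------------

#' Validate an analyte annotation table
#'
#' @param annotation Tibble with columns `analyte_id`, `platform`,
#'   `quantitative_rank`, `identified`, `major_pathway`, `specific_pathway`,
#'   `duplicate_group`.
#' @return The annotation tibble, invisibly, after validation.
#' @export
validate_annotation <- function(annotation) {
  errs <- list()
  need <- c("analyte_id", "platform", "quantitative_rank", "identified",
            "major_pathway", "specific_pathway", "duplicate_group")
  miss <- setdiff(need, names(annotation))
  if (length(miss) > 0) {
    rlang::abort(paste0("annotation lacks columns: ", paste(miss, collapse = ", ")))
  }
  dup <- annotation$analyte_id[duplicated(annotation$analyte_id)]
  if (length(dup) > 0) {
    errs <- c(errs, paste0("duplicate analyte_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad_platform <- setdiff(unique(annotation$platform), platform_levels())
  if (length(bad_platform) > 0) {
    errs <- c(errs, paste0("unknown platform: ", paste(bad_platform, collapse = ", ")))
  }
  bad_path <- setdiff(unique(annotation$major_pathway), pathway_levels())
  if (length(bad_path) > 0) {
    errs <- c(errs, paste0("unknown major_pathway: ", paste(bad_path, collapse = ", ")))
  }
  if (any(annotation$quantitative_rank < 1)) {
    errs <- c(errs, "quantitative_rank must be >= 1")
  }
  unid <- !annotation$identified & annotation$major_pathway != "unknown"
  if (any(unid)) {
    errs <- c(errs, paste0("unidentified analytes must have major_pathway 'unknown': ",
                           paste(annotation$analyte_id[unid], collapse = ", ")))
  }
  check_all(errs, "annotation")
  invisible(annotation)
}

# ---- metabolite matrix -----------------------------------------------------

#' Construct a metabolite matrix container
#'
#' Holds sample-by-analyte plasma intensities in long (tidy) form together
#' with the analyte annotation. Each cell carries a `status`: `"detected"`
#' (a nonnegative intensity), `"below_lod"` (present but below the limit of
#' detection; retained and ranked at the tied minimum by the score
#' transform), or `"missing"` (no measurement; propagates as missing).
#'
#' @param values Tibble with columns `sample_id`, `analyte_id`, `value`
#'   (double, `NA` unless detected) and `status`.
#' @param annotation Analyte annotation tibble (see [validate_annotation()]).
#' @return An object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values, annotation) {
  validate_annotation(annotation)
  errs <- list()
  need <- c("sample_id", "analyte_id", "value", "status")
  miss <- setdiff(need, names(values))
  if (length(miss) > 0) rlang::abort(paste0("values lacks columns: ", paste(miss, collapse = ", ")))
  bad_status <- setdiff(unique(values$status), c("detected", "below_lod", "missing"))
  if (length(bad_status) > 0) {
    errs <- c(errs, paste0("unknown status: ", paste(bad_status, collapse = ", ")))
  }
  neg <- values$status == "detected" & (is.na(values$value) | values$value < 0)
  if (any(neg)) {
    errs <- c(errs, paste0(sum(neg), " detected cells are negative or NA"))
  }
  extra <- setdiff(unique(values$analyte_id), annotation$analyte_id)
  if (length(extra) > 0) {
    errs <- c(errs, paste0("annotation missing analytes: ", paste(extra, collapse = ", ")))
  }
  n_s <- dplyr::n_distinct(values$sample_id)
  n_a <- dplyr::n_distinct(values$analyte_id)
  if (nrow(values) != n_s * n_a) {
    errs <- c(errs, "values must form a complete sample x analyte grid")
  }
  check_all(errs, "metabolite matrix")
  values <- dplyr::arrange(tibble::as_tibble(values), .data$analyte_id, .data$sample_id)
  annotation <- dplyr::filter(annotation, .data$analyte_id %in% unique(values$analyte_id))
  structure(list(values = values,
                 annotation = dplyr::arrange(tibble::as_tibble(annotation), .data$analyte_id)),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %d samples x %d analytes\n",
              length(mm_samples(x)), length(mm_analytes(x))))
  st <- table(x$values$status)
  cat("  cells:", paste(names(st), as.integer(st), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Accessors for a metabolite matrix
#' @param x A `metabolite_matrix`.
#' @return `mm_samples()`/`mm_analytes()` return character vectors;
#'   `mm_value_matrix()` a numeric samples-by-analytes matrix with `NA` for
#'   non-detected cells; `mm_status_matrix()` the matching status matrix.
#' @export
mm_samples <- function(x) sort(unique(x$values$sample_id))

#' @rdname mm_samples
#' @export
mm_analytes <- function(x) x$annotation$analyte_id

#' @rdname mm_samples
#' @export
mm_value_matrix <- function(x) {
  wide <- tidyr::pivot_wider(x$values[, c("sample_id", "analyte_id", "value")],
                             names_from = "analyte_id", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m[, mm_analytes(x), drop = FALSE]
}

#' @rdname mm_samples
#' @export
mm_status_matrix <- function(x) {
  wide <- tidyr::pivot_wider(x$values[, c("sample_id", "analyte_id", "status")],
                             names_from = "analyte_id", values_from = "status")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m[, mm_analytes(x), drop = FALSE]
}

#' Per-analyte detection frequency
#'
#' Fraction of samples in which an analyte was detected (a numeric value;
#' below-LOD and missing cells both count as not detected — configurable via
#' `count_lod_as_detected`).
#'
#' @param x A `metabolite_matrix`.
#' @param samples Optional character vector restricting to a sample subset.
#' @param count_lod_as_detected Count below-LOD cells as detected? Default
#'   `FALSE`.
#' @return Tibble with `analyte_id` and `frequency`.
#' @export
detection_frequency <- function(x, samples = NULL, count_lod_as_detected = FALSE) {
  v <- x$values
  if (!is.null(samples)) v <- dplyr::filter(v, .data$sample_id %in% samples)
  ok <- if (count_lod_as_detected) c("detected", "below_lod") else "detected"
  v |>
    dplyr::group_by(.data$analyte_id) |>
    dplyr::summarise(frequency = mean(.data$status %in% ok), .groups = "drop")
}

# ---- readers / writers -----------------------------------------------------

#' Read a metabolite intensity table and its annotation
#'
#' The matrix file is wide delimited text: first column `sample_id`, one
#' column per analyte. Cells are nonnegative numbers, the below-LOD token
#' (default `"<LOD"`), or empty for missing. The annotation file must cover
#' every analyte column.
#'
#' @param matrix_path,annotation_path Paths to delimited-text files.
#' @param delim Field delimiter (default tab).
#' @param lod_token Token marking below-LOD cells.
#' @return A [metabolite_matrix()].
#' @export
read_metabolite_table <- function(matrix_path, annotation_path,
                                  delim = "\t", lod_token = "<LOD") {
  for (p in c(matrix_path, annotation_path)) {
    if (!file.exists(p)) rlang::abort(paste0("file not found: ", p))
  }
  raw <- readr::read_delim(matrix_path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), show_col_types = FALSE)
  ann <- readr::read_delim(annotation_path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(
                             analyte_id = "c", platform = "c", quantitative_rank = "i",
                             identified = "l", major_pathway = "c",
                             specific_pathway = "c", duplicate_group = "c"))
  ann$specific_pathway[is.na(ann$specific_pathway)] <- ""
  ann$duplicate_group[is.na(ann$duplicate_group)] <- ""
  errs <- list()
  if (names(raw)[1] != "sample_id") errs <- c(errs, "first column must be 'sample_id'")
  dup_s <- raw$sample_id[duplicated(raw$sample_id)]
  if (length(dup_s) > 0) {
    errs <- c(errs, paste0("duplicate sample_id: ", paste(unique(dup_s), collapse = ", ")))
  }
  check_all(errs, "metabolite table")
  long <- tidyr::pivot_longer(raw, -"sample_id",
                              names_to = "analyte_id", values_to = "cell")
  long <- dplyr::mutate(
    long,
    status = dplyr::case_when(
      .data$cell == "" | is.na(.data$cell) ~ "missing",
      .data$cell == lod_token ~ "below_lod",
      TRUE ~ "detected"),
    value = dplyr::if_else(.data$status == "detected",
                           suppressWarnings(as.numeric(.data$cell)), NA_real_))
  bad <- long$status == "detected" & is.na(long$value)
  if (any(bad)) {
    rlang::abort(paste0("non-numeric cells: ",
                        paste(utils::head(unique(long$cell[bad]), 5), collapse = ", ")))
  }
  if (any(long$value < 0, na.rm = TRUE)) {
    rlang::abort("negative intensities are not allowed")
  }
  metabolite_matrix(long[, c("sample_id", "analyte_id", "value", "status")], ann)
}

#' Write a metabolite matrix (and annotation) back to delimited text
#'
#' Inverse of [read_metabolite_table()]; a read of the written files
#' round-trips values exactly.
#'
#' @param x A `metabolite_matrix`.
#' @param matrix_path,annotation_path Output paths.
#' @inheritParams read_metabolite_table
#' @return Invisibly, `x`.
#' @export
write_metabolite_table <- function(x, matrix_path, annotation_path,
                                   delim = "\t", lod_token = "<LOD") {
  cells <- dplyr::mutate(
    x$values,
    cell = dplyr::case_when(
      .data$status == "below_lod" ~ lod_token,
      .data$status == "missing" ~ "",
      TRUE ~ readr_num(.data$value)))
  wide <- tidyr::pivot_wider(cells[, c("sample_id", "analyte_id", "cell")],
                             names_from = "analyte_id", values_from = "cell")
  readr::write_delim(wide, matrix_path, delim = delim)
  readr::write_delim(x$annotation, annotation_path, delim = delim)
  invisible(x)
}

# Shortest decimal representation that round-trips a double exactly.
readr_num <- function(x) {
  vapply(x, function(v) if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE),
         character(1))
}

#' Read a phenotype table
#'
#' Expects columns `sample_id`, `sex` (F/M), `age`, `menopausal_status`
#' (pre/post/not_applicable), `vo2peak`, plus the 21 covariates of
#' [covariate_names()]. Empty cells are accepted only for the imputable
#' covariates (AEE, PWV).
#'
#' @param path Delimited-text file.
#' @param delim Field delimiter.
#' @return A validated tibble.
#' @export
read_phenotype_table <- function(path, delim = "\t") {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  ph <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(sample_id = "c", sex = "c",
                                                  menopausal_status = "c",
                                                  .default = "d"))
  validate_phenotype(ph)
}

#' Validate a phenotype table
#' @param ph Tibble as described in [read_phenotype_table()].
#' @return The validated tibble (invisible errors aggregated otherwise).
#' @export
validate_phenotype <- function(ph) {
  errs <- list()
  need <- c("sample_id", "sex", "age", "menopausal_status", "vo2peak", covariate_names())
  miss <- setdiff(need, names(ph))
  if (length(miss) > 0) rlang::abort(paste0("phenotype lacks columns: ", paste(miss, collapse = ", ")))
  dup <- ph$sample_id[duplicated(ph$sample_id)]
  if (length(dup) > 0) errs <- c(errs, paste0("duplicate sample_id: ", paste(unique(dup), collapse = ", ")))
  if (!all(ph$sex %in% c("F", "M"))) errs <- c(errs, "sex must be F or M")
  if (!all(ph$menopausal_status %in% c("pre", "post", "not_applicable"))) {
    errs <- c(errs, "menopausal_status must be pre/post/not_applicable")
  }
  bad_m <- ph$sex == "M" & ph$menopausal_status != "not_applicable"
  if (any(bad_m)) {
    errs <- c(errs, paste0("males with a menopausal status: ",
                           paste(ph$sample_id[bad_m], collapse = ", ")))
  }
  if (any(is.na(ph$vo2peak) | ph$vo2peak <= 0)) errs <- c(errs, "vo2peak must be positive")
  if (any(is.na(ph$age) | ph$age < 18 | ph$age > 80)) errs <- c(errs, "age must lie in [18, 80]")
  hard <- setdiff(covariate_names(), imputable_covariates())
  for (v in hard) {
    if (any(is.na(ph[[v]]))) errs <- c(errs, paste0("missing values in non-imputable covariate ", v))
  }
  check_all(errs, "phenotype table")
  tibble::as_tibble(ph)
}

#' Write / read result tables
#'
#' Result objects are tibbles; serialization is delimited text with a stable
#' column order and full-precision numbers, so a read of the written file
#' reproduces every value (exactly for integers and flags, to better than
#' 1e-12 relative error for reals).
#'
#' @param obj A tibble (any result type).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return Invisibly, `obj`.
#' @export
write_results <- function(obj, path, delim = "\t") {
  if (!is.data.frame(obj)) rlang::abort("write_results expects a data frame")
  readr::write_delim(tibble::as_tibble(obj), path, delim = delim)
  invisible(obj)
}

#' @rdname write_results
#' @export
read_results <- function(path, delim = "\t") {
  readr::read_delim(path, delim = delim, show_col_types = FALSE)
}

#' Summaries of an annotation table
#'
#' Counts identified metabolites, their shares per major pathway (percent),
#' and the identification share among untargeted-platform analytes.
#'
#' @param annotation Annotation tibble.
#' @return A list with `n_analytes`, `n_identified`, `pathway_shares`
#'   (tibble: pathway, n, share_pct among identified), and
#'   `untargeted_identified_share_pct`.
#' @export
annotation_summary <- function(annotation) {
  validate_annotation(annotation)
  ident <- dplyr::filter(annotation, .data$identified)
  shares <- ident |>
    dplyr::count(.data$major_pathway, name = "n") |>
    dplyr::mutate(share_pct = 100 * .data$n / nrow(ident)) |>
    dplyr::arrange(dplyr::desc(.data$n))
  untarg <- dplyr::filter(annotation, .data$platform %in% untargeted_platforms())
  list(n_analytes = nrow(annotation),
       n_identified = nrow(ident),
       pathway_shares = shares,
       untargeted_identified_share_pct =
         if (nrow(untarg) > 0) 100 * mean(untarg$identified) else NA_real_)
}
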