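# Fixtures built in code: tiny matrices with controlled status cells and an
# annotation builder with sensible defaults.

make_annotation <- function(ids, platform = "nmr", quantitative_rank = 1L,
                            identified = TRUE, major_pathway = "lipid",
                            duplicate_group = "") {
  tibble::tibble(analyte_id = ids,
                 platform = rep_len(platform, length(ids)),
                 quantitative_rank = rep_len(as.integer(quantitative_rank), length(ids)),
                 identified = rep_len(identified, length(ids)),
                 major_pathway = rep_len(ifelse(rep_len(identified, length(ids)),
                                                major_pathway, "unknown"), length(ids)),
                 specific_pathway = "", duplicate_group = rep_len(duplicate_group, length(ids)))
}

# values: samples x analytes numeric matrix; NA cells become "missing" unless
# flagged below-LOD in `lod` (same shape logical).
make_mm <- function(values, annotation = NULL, lod = NULL,
                    sample_ids = sprintf("S%02d", seq_len(nrow(values)))) {
  if (is.null(colnames(values))) colnames(values) <- sprintf("A%02d", seq_len(ncol(values)))
  if (is.null(annotation)) annotation <- make_annotation(colnames(values))
  if (is.null(lod)) lod <- matrix(FALSE, nrow(values), ncol(values))
  long <- tidyr::expand_grid(sample_id = sample_ids, analyte_id = colnames(values))
  idx <- cbind(match(long$sample_id, sample_ids), match(long$analyte_id, colnames(values)))
  long$value <- values[idx]
  long$status <- ifelse(lod[idx], "below_lod",
                        ifelse(is.na(long$value), "missing", "detected"))
  long$value[long$status != "detected"] <- NA_real_
  metabolite_matrix(long, annotation)
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Small adjusted regression dataset with two true predictors and noise
# candidates.
make_regression_data <- function(n = 120, n_noise = 10, noise_sd = 0.4, seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  for (j in seq_len(n_noise)) d[[paste0("z", sprintf("%02d", j))]] <- stats::rnorm(n)
  d$y <- d$x1 + d$x2 + stats::rnorm(n, 0, noise_sd)
  d
}
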