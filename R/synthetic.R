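# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes -- two sexes, a wide age range, fat-mass percentage as
# the dominant fitness determinant, sex-specific metabolite blocks with
# modest partial correlations, confounder-driven and covariate-mediated
# analytes, below-LOD censoring, cross-platform duplicates, and sporadic
# missing AEE/PWV values -- together with a ground-truth table.

#' Configuration of the synthetic cohort
#'
#' Defaults encode the study conditions: 102 females and 150 males, pooled
#' VO2peak around 38.9 +/- 11.7 mL kg-1 min-1, fat-mass percentage
#' explaining about 33.5% (F) / 42.3% (M) of the age-adjusted VO2peak
#' variance, and analyte effect sizes (partial correlations) drawn from
#' 0.2-0.4. `p_analytes` defaults to 120 so the full pipeline runs in
#' minutes; block sizes must sum to `p_analytes`.
#'
#' @param n_female,n_male Subgroup sizes.
#' @param p_analytes Number of base analytes (before duplicate injection).
#' @param block_sizes Named counts: `female_specific`, `male_specific`,
#'   `shared`, `confounder_only`, `covariate_mediated`, `null`.
#' @param effect_r Range of planted partial-correlation magnitudes.
#' @param lod_censor_max Per-analyte censoring quantile is drawn uniformly
#'   from `[0, lod_censor_max]`.
#' @param duplicate_fraction Fraction of analytes duplicated on a second
#'   platform.
#' @param missing_aee_pwv_rate Per-cell missingness rate for AEE and PWV.
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_female = 102, n_male = 150, p_analytes = 120,
                             block_sizes = c(female_specific = 15,
                                             male_specific = 15, shared = 10,
                                             confounder_only = 10,
                                             covariate_mediated = 15, null = 55),
                             effect_r = c(0.2, 0.4), lod_censor_max = 0.10,
                             duplicate_fraction = 0.08,
                             missing_aee_pwv_rate = 0.05, seed = 1) {
  if (sum(block_sizes) != p_analytes) {
    rlang::abort("block sizes must sum to p_analytes")
  }
  stopifnot(lod_censor_max >= 0, lod_censor_max <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            missing_aee_pwv_rate >= 0, missing_aee_pwv_rate <= 1)
  structure(list(n_female = n_female, n_male = n_male, p_analytes = p_analytes,
                 block_sizes = block_sizes, effect_r = effect_r,
                 lod_censor_max = lod_censor_max,
                 duplicate_fraction = duplicate_fraction,
                 missing_aee_pwv_rate = missing_aee_pwv_rate, seed = seed),
            class = "synthetic_config")
}

# VO2peak model constants: sex intercepts at the mean age (49) and mean
# fat mass, an age slope, and fat-mass slopes/noise calibrated so fat mass
# explains ~33.5% (F) / ~42.3% (M) of the age-adjusted variance.
vo2_model <- list(
  a = c(F = 34.3, M = 42.0), b_age = 0.45,
  b_fm = c(F = 0.7, M = 0.9), sigma = c(F = 5.92, M = 5.78),
  fm_mean = c(F = 32, M = 22), fm_sd = c(F = 6, M = 5.5), fm_age_trend = 0.08)

# Covariate generator table: value = mean_sex + scale * (w_adj * z_adj +
# w_age * z_age + w_fm * z_fm + w_noise * z_noise), weights normalized to
# unit variance. FM_pct is the generated fat mass itself. The induced
# confounder-adjusted correlation with VO2peak is approximately
# w_adj + w_fm * cor(z_fm, z_adj) with cor(z_fm, z_adj) ~ -0.6; loadings are
# calibrated so those correlations sit near the published sex-specific
# values (HDL ~ +0.4, VATM ~ -0.5, PWV ~ -0.35, TGs ~ -0.3, HR_rest ~ -0.3,
# AEE ~ +0.2) while fat mass stays the single dominant determinant.
covariate_loadings <- function() {
  tibble::tribble(
    ~covariate, ~mean_f, ~mean_m, ~scale, ~w_adj, ~w_age, ~w_fm, ~lower,
    "LBM",       42,  58,  5.0,  0.10, -0.20, -0.30,  20,
    "VATM",     1.0, 2.0,  0.8, -0.10,  0.30,  0.55, 0.05,
    "BMC",      2.4, 3.0,  0.3,  0.00, -0.30,  0.00, 1.0,
    "height",   166, 179,  6.5,  0.00,  0.00,  0.00, 140,
    "Hb",      13.5,  15,  0.9,  0.00,  0.00,  0.00, 9,
    "glucose",  4.9, 5.2,  0.5,  0.00,  0.30,  0.20, 3,
    "insulin",    8,   8,  3.0,  0.00,  0.00,  0.30, 0.5,
    "HbA1c",    5.3, 5.3,  0.3,  0.00,  0.40,  0.00, 4,
    "TGs",      1.1, 1.3,  0.5, -0.10,  0.00,  0.30, 0.3,
    "HDL",      1.6, 1.3,  0.3,  0.18,  0.00, -0.30, 0.5,
    "LDL",      3.0, 3.1,  0.8, -0.15,  0.35,  0.10, 1,
    "HR_rest",   64,  62,  8.0, -0.30,  0.00,  0.00, 40,
    "BP_sys",   120, 128, 12.0,  0.00,  0.40,  0.10, 85,
    "BP_dia",    75,  80,  8.0, -0.20,  0.30,  0.10, 50,
    "PWV",      7.5, 7.8,  1.2, -0.20,  0.60,  0.25, 4,
    "VC_max",   3.6, 4.9,  0.6,  0.20, -0.30,  0.00, 1.5,
    "FEV1",     2.9, 3.9,  0.5,  0.20, -0.35,  0.00, 1.2,
    "AEE",      600, 800,  250,  0.15,  0.00, -0.10, 50,
    "MET_total", 38,  40,  6.0,  0.20,  0.00,  0.00, 20,
    "HEI_NVS",   55,  52, 10.0,  0.00,  0.00,  0.00, 20)
}

#' Generate a synthetic cohort with ground truth
#'
#' Produces a phenotype table, a metabolite matrix with below-LOD and
#' missing semantics, and a truth table assigning every analyte to its
#' generating block. Analyte effects are planted on the confounder-adjusted
#' scale and raw intensities reconstructed through a log-normal marginal, so
#' planted partial correlations are recovered in expectation after the rank
#' transform. Deterministic for a given seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `pheno`, `metabolites` (a `metabolite_matrix`) and
#'   `truth` (tibble: `analyte_id`, `block`, `effect_r`, `sex_of_effect`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  m <- vo2_model
  n <- config$n_female + config$n_male
  sex <- c(rep("F", config$n_female), rep("M", config$n_male))
  id <- sprintf("S%04d", seq_len(n))
  age <- stats::runif(n, 18, 80)
  menop <- ifelse(sex == "M", "not_applicable",
                  ifelse(stats::runif(n) < stats::plogis((age - 50) / 2.5),
                         "post", "pre"))
  z_fm <- stats::rnorm(n)
  fm_c <- z_fm * unname(m$fm_sd[sex])
  fm <- unname(m$fm_mean[sex]) + m$fm_age_trend * (age - 49) + fm_c
  fm <- pmax(fm, 8)
  eps <- stats::rnorm(n, 0, unname(m$sigma[sex]))
  adj_signal <- -unname(m$b_fm[sex]) * fm_c + eps  # age-adjusted part of VO2peak
  vo2 <- pmax(unname(m$a[sex]) - m$b_age * (age - 49) + adj_signal, 5)
  z_age <- (age - 49) / sqrt((80 - 18)^2 / 12)
  # per-sex standardized adjusted signal, used to plant analyte effects
  z_adj <- adj_signal
  for (s in c("F", "M")) {
    idx <- sex == s
    z_adj[idx] <- (adj_signal[idx] - mean(adj_signal[idx])) / stats::sd(adj_signal[idx])
  }

  pheno <- tibble::tibble(sample_id = id, sex = sex, age = age,
                          menopausal_status = menop, vo2peak = vo2,
                          FM_pct = fm)
  for (i in seq_len(nrow(covariate_loadings()))) {
    row <- covariate_loadings()[i, ]
    w_noise <- sqrt(max(0, 1 - row$w_adj^2 - row$w_age^2 - row$w_fm^2))
    val <- ifelse(sex == "F", row$mean_f, row$mean_m) +
      row$scale * (row$w_adj * z_adj + row$w_age * z_age +
                     row$w_fm * z_fm + w_noise * stats::rnorm(n))
    pheno[[row$covariate]] <- pmax(val, row$lower)
  }
  pheno <- pheno[, c("sample_id", "sex", "age", "menopausal_status", "vo2peak",
                     covariate_names())]
  for (v in imputable_covariates()) {
    gone <- stats::runif(n) < config$missing_aee_pwv_rate
    pheno[[v]][gone] <- NA_real_
  }

  # ---- analytes -------------------------------------------------------------
  blocks <- rep(names(config$block_sizes), times = config$block_sizes)
  p <- config$p_analytes
  aid <- sprintf("A%04d", seq_len(p))
  truth <- tibble::tibble(analyte_id = aid, block = blocks,
                          effect_r = 0, sex_of_effect = "none")
  U <- matrix(stats::rnorm(n * p), n, p)
  rng <- config$effect_r
  for (j in seq_len(p)) {
    b <- blocks[j]
    if (b == "null") next
    if (b %in% c("female_specific", "male_specific", "shared")) {
      r <- sample(c(-1, 1), 1) * stats::runif(1, rng[1], rng[2])
      target <- switch(b, female_specific = "F", male_specific = "M",
                       shared = c("F", "M"))
      idx <- sex %in% target
      U[idx, j] <- r * z_adj[idx] + sqrt(1 - r^2) * U[idx, j]
      truth$effect_r[j] <- r
      truth$sex_of_effect[j] <- if (length(target) == 2) "both" else target
    } else if (b == "confounder_only") {
      U[, j] <- 0.5 * z_age + sqrt(0.75) * U[, j]
    } else if (b == "covariate_mediated") {
      # loading on the fat-mass component; induces |r| ~ 0.33 with the
      # adjusted response, inside the planted metabolite effect range
      lam <- sample(c(-1, 1), 1) * 0.55
      U[, j] <- lam * z_fm + sqrt(1 - lam^2) * U[, j]
      truth$sex_of_effect[j] <- "both"
    }
  }
  mu <- stats::runif(p, 1, 5)
  sig <- stats::runif(p, 0.3, 0.8)

  # duplicate injection: a copy on a second, less quantitative platform
  n_dup <- floor(config$duplicate_fraction * p)
  dup_src <- if (n_dup > 0) sort(sample(p, n_dup)) else integer()
  platforms <- platform_levels()
  base_platform <- platforms[(seq_len(p) - 1) %% length(platforms) + 1]

  make_cells <- function(analyte_id, u, mu_j, sig_j) {
    value <- exp(mu_j + sig_j * u)
    cq <- stats::runif(1, 0, config$lod_censor_max)
    status <- rep("detected", n)
    if (cq > 0) {
      thr <- stats::quantile(value, cq, type = 7, names = FALSE)
      status[value < thr] <- "below_lod"
    }
    tibble::tibble(sample_id = id, analyte_id = analyte_id,
                   value = ifelse(status == "detected", value, NA_real_),
                   status = status)
  }

  cells <- vector("list", p + n_dup)
  ann <- vector("list", p + n_dup)
  lipid_heavy <- c("lipid", "lipid", "lipid", "amino_acid", "amino_acid",
                   "xenobiotics", "energy", "carbohydrate",
                   "mammalian_microbial", "nucleotide", "cofactors_vitamins")
  for (j in seq_len(p)) {
    cells[[j]] <- make_cells(aid[j], U[, j], mu[j], sig[j])
    identified <- if (blocks[j] == "null") stats::runif(1) < 0.5 else TRUE
    ann[[j]] <- tibble::tibble(
      analyte_id = aid[j], platform = base_platform[j], quantitative_rank = 1L,
      identified = identified,
      major_pathway = if (identified) sample(lipid_heavy, 1) else "unknown",
      specific_pathway = "",
      duplicate_group = if (j %in% dup_src) aid[j] else "")
  }
  for (k in seq_along(dup_src)) {
    j <- dup_src[k]
    u_copy <- U[, j] + stats::rnorm(n, 0, 0.3)
    did <- paste0(aid[j], "_dup")
    cells[[p + k]] <- make_cells(did, u_copy, mu[j], sig[j])
    other <- setdiff(platforms, base_platform[j])[1]
    ann[[p + k]] <- dplyr::mutate(ann[[j]], analyte_id = did, platform = other,
                                  quantitative_rank = 2L, duplicate_group = aid[j])
    truth <- dplyr::bind_rows(truth, dplyr::mutate(truth[j, ], analyte_id = did,
                                                   block = "duplicate_copy"))
  }
  metab <- metabolite_matrix(dplyr::bind_rows(cells), dplyr::bind_rows(ann))
  list(pheno = pheno, metabolites = metab, truth = truth)
}

#' Generate a null cohort (no metabolite-fitness associations)
#'
#' Convenience wrapper around [generate_cohort()] with every analyte in the
#' null block, no duplicates and no censoring: used by type-I-error suites.
#'
#' @param n Total sample count (split ~40/60 female/male); `n >= 20`.
#' @param p Number of analytes.
#' @param seed Integer seed.
#' @inherit generate_cohort return
#' @export
generate_null_dataset <- function(n, p, seed = 1) {
  if (n < 20) rlang::abort("need n >= 20")
  nf <- round(0.4 * n)
  generate_cohort(synthetic_config(
    n_female = nf, n_male = n - nf, p_analytes = p,
    block_sizes = c(female_specific = 0, male_specific = 0, shared = 0,
                    confounder_only = 0, covariate_mediated = 0, null = p),
    lod_censor_max = 0, duplicate_fraction = 0,
    missing_aee_pwv_rate = 0, seed = seed))
}

#' Write a synthetic cohort to delimited-text files
#'
#' Emits the same formats the readers consume: wide metabolite matrix,
#' annotation, phenotype table, and the truth table.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter.
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir, delim = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("metabolites.tsv", "annotation.tsv",
                            "phenotype.tsv", "truth.tsv"))
  write_metabolite_table(cohort$metabolites, paths[1], paths[2], delim = delim)
  readr::write_delim(cohort$pheno, paths[3], delim = delim, na = "")
  readr::write_delim(cohort$truth, paths[4], delim = delim)
  invisible(paths)
}
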