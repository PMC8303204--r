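test_that("duplicate resolution keeps the most quantitative copy", {
  # glutamate measured twice: the less quantitative platform copy is dropped
  ann <- dplyr::bind_rows(
    make_annotation("glu_p180", platform = "lcms_p180", quantitative_rank = 1L,
                    duplicate_group = "glutamate"),
    make_annotation("glu_gcxgc", platform = "gcxgc_ms", quantitative_rank = 3L,
                    duplicate_group = "glutamate"),
    make_annotation("other"))
  vals <- matrix(runif(12, 1, 2), 4, 3,
                 dimnames = list(NULL, c("glu_p180", "glu_gcxgc", "other")))
  mm <- make_mm(vals, annotation = ann)
  res <- resolve_platform_duplicates(mm)
  expect_setequal(mm_analytes(res$matrix), c("glu_p180", "other"))
  expect_equal(res$report$removed_duplicates, "glu_gcxgc")

  # no duplicate groups: identity
  mm2 <- make_mm(vals[, 3, drop = FALSE])
  res2 <- resolve_platform_duplicates(mm2)
  expect_equal(mm_value_matrix(res2$matrix), mm_value_matrix(mm2))
  expect_length(res2$report$removed_duplicates, 0)
})

test_that("three-way duplicates leave exactly the minimum-rank survivor", {
  ann <- dplyr::bind_rows(
    make_annotation("a_nmr", platform = "nmr", quantitative_rank = 2L, duplicate_group = "g"),
    make_annotation("a_p180", platform = "lcms_p180", quantitative_rank = 1L, duplicate_group = "g"),
    make_annotation("a_gc", platform = "gcxgc_ms", quantitative_rank = 3L, duplicate_group = "g"))
  mm <- make_mm(matrix(runif(9, 1, 2), 3, 3,
                       dimnames = list(NULL, c("a_nmr", "a_p180", "a_gc"))),
                annotation = ann)
  res <- resolve_platform_duplicates(mm)
  expect_equal(mm_analytes(res$matrix), "a_p180")
  expect_setequal(res$report$removed_duplicates, c("a_nmr", "a_gc"))
})

test_that("detection filter applies the either-subgroup rule with a >= boundary", {
  n_f <- 10; n_m <- 10
  sex <- c(rep("F", n_f), rep("M", n_m))
  names(sex) <- sprintf("S%02d", 1:20)
  vals <- matrix(runif(20 * 3, 1, 2), 20, 3,
                 dimnames = list(NULL, c("lowF", "at20", "full")))
  # lowF: detected in 10% of F, 90% of M -> removed
  vals[1:9, "lowF"] <- NA
  vals[20, "lowF"] <- NA
  # at20: exactly 20% in both subgroups -> kept
  vals[1:8, "at20"] <- NA
  vals[11:18, "at20"] <- NA
  mm <- make_mm(vals, sample_ids = names(sex))
  res <- filter_detection_frequency(mm, sex, min_freq = 0.20)
  expect_setequal(mm_analytes(res$matrix), c("at20", "full"))
  expect_equal(res$report$removed_low_frequency, "lowF")
  # conservation: removed + kept = input
  expect_equal(length(res$report$removed_low_frequency) +
                 length(mm_analytes(res$matrix)), 3L)
  expect_error(filter_detection_frequency(mm, sex[sex == "F"]), "cover")
})

test_that("Van der Waerden transform matches the inverse-normal oracle", {
  # explicit qnorm(rank/(n+1)) oracle
  expect_equal(vdw_transform(c(1, 2, 3)), qnorm(c(1, 2, 3) / 4), tolerance = 1e-12)
  expect_equal(vdw_transform(c(1, 2, 3))[2], 0)
  expect_equal(round(vdw_transform(c(1, 2, 3)), 4), c(-0.6745, 0, 0.6745))
  # full tie: all-zero scores unless strict
  expect_equal(vdw_transform(c(5, 5, 5, 5)), rep(0, 4))
  expect_error(vdw_transform(c(5, 5, 5, 5), strict = TRUE), "degenerate")
  # LOD block shares the tied minimum rank: ranks (1.5, 1.5, 3, 4) / 5
  got <- vdw_transform(c(NA, NA, 1.0, 2.0), lod = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(got, qnorm(c(1.5, 1.5, 3, 4) / 5), tolerance = 1e-12)
  # missing entries propagate and do not consume ranks
  got <- vdw_transform(c(1, NA, 2, 3))
  expect_true(is.na(got[2]))
  expect_equal(got[-2], qnorm(c(1, 2, 3) / 4))
  expect_error(vdw_transform(c(1, NA, NA)), "at least 3")
})

test_that("VdW transform is monotone and idempotent", {
  set.seed(42)
  for (i in 1:20) {
    x <- sample(rexp(30))
    s <- vdw_transform(x)
    expect_equal(order(s), order(x))              # monotone on untied data
    expect_equal(vdw_transform(s), s, tolerance = 1e-12)  # rank-preserving
  }
})

test_that("residualization matches the normal-equations oracle and its invariants", {
  # 4-point worked case solved by explicit matrix inversion
  y <- c(2, 4, 5, 9)
  C <- cbind(c(1, 2, 3, 5), c(0, 1, 0, 1))
  X <- cbind(1, C)
  beta <- solve(t(X) %*% X) %*% t(X) %*% y
  oracle <- as.numeric(y - X %*% beta)
  expect_equal(residualize(y, C), oracle, tolerance = 1e-10)
  expect_lt(abs(mean(residualize(y, C))), 1e-10)
  expect_lt(abs(sum(residualize(y, C) * C[, 1])), 1e-8)

  # covariate orthogonal to y: residual is just the centered y
  y2 <- c(1, -1, 1, -1)
  c2 <- c(1, 1, -1, -1)
  expect_equal(residualize(y2, cbind(c2)), y2 - mean(y2))
  # y affine in the covariate: all-zero residuals
  expect_equal(residualize(2 + 3 * C[, 1], C[, 1, drop = FALSE]),
               rep(0, 4), tolerance = 1e-10)
  # rank-deficient covariate set is refused with the offender named
  CC <- cbind(a = C[, 1], b = 2 * C[, 1])
  expect_error(residualize(y, CC), "b")
})

test_that("residualize_columns centers every column and drops the adjustment set", {
  d <- tibble::tibble(sample_id = sprintf("S%d", 1:10),
                      age = rnorm(10), v1 = rnorm(10), v2 = rnorm(10))
  out <- residualize_columns(d, "age")
  expect_setequal(names(out), c("sample_id", "v1", "v2"))
  expect_lt(abs(mean(out$v1)), 1e-8)
  expect_lt(abs(sum(out$v2 * d$age)), 1e-8)
  expect_equal(attr(out, "adjustment_set"), "age")
})

test_that("random-forest imputation is deterministic, in-range, and an identity when complete", {
  co <- generate_cohort(synthetic_config(n_female = 30, n_male = 30, p_analytes = 4,
    block_sizes = c(female_specific = 0, male_specific = 0, shared = 0,
                    confounder_only = 0, covariate_mediated = 0, null = 4),
    missing_aee_pwv_rate = 0.1, duplicate_fraction = 0, seed = 11))
  ph <- co$pheno
  expect_true(anyNA(ph$AEE) || anyNA(ph$PWV))
  r1 <- impute_random_forest(ph, seed = 7)
  r2 <- impute_random_forest(ph, seed = 7)
  expect_identical(r1$pheno, r2$pheno)
  expect_false(anyNA(r1$pheno$AEE))
  expect_false(anyNA(r1$pheno$PWV))
  for (v in c("AEE", "PWV")) {
    miss <- is.na(ph[[v]])
    if (any(miss)) {
      expect_true(all(r1$pheno[[v]][miss] >= min(ph[[v]], na.rm = TRUE)))
      expect_true(all(r1$pheno[[v]][miss] <= max(ph[[v]], na.rm = TRUE)))
    }
  }
  complete <- r1$pheno
  r3 <- impute_random_forest(complete, seed = 1)
  expect_identical(r3$pheno, complete)
  expect_equal(nrow(r3$report$imputed_cells), 0L)
})

test_that("forest imputation tracks a monotone covariate-age relationship", {
  # AEE noiseless linear in age: imputed values must fall within the range
  # spanned by training neighbours (forest predictions average leaves)
  co <- generate_cohort(synthetic_config(n_female = 40, n_male = 40, p_analytes = 4,
    block_sizes = c(female_specific = 0, male_specific = 0, shared = 0,
                    confounder_only = 0, covariate_mediated = 0, null = 4),
    missing_aee_pwv_rate = 0, duplicate_fraction = 0, seed = 12))
  ph <- co$pheno
  ph$AEE <- 10 * ph$age
  target <- which.min(abs(ph$age - stats::median(ph$age)))
  truth_val <- ph$AEE[target]
  ph$AEE[target] <- NA
  imp <- impute_random_forest(ph, targets = "AEE", seed = 5)
  got <- imp$pheno$AEE[target]
  nbr <- sort(abs(ph$age[-target] - ph$age[target]), partial = 10)[10]
  nbr_vals <- ph$AEE[-target][abs(ph$age[-target] - ph$age[target]) <= nbr]
  expect_gt(got, min(nbr_vals) - 50)
  expect_lt(got, max(nbr_vals) + 50)
  expect_lt(abs(got - truth_val) / truth_val, 0.25)
})

test_that("sex score table wires confounders and stays aligned", {
  co <- generate_cohort(synthetic_config(n_female = 20, n_male = 20, p_analytes = 6,
    block_sizes = c(female_specific = 2, male_specific = 0, shared = 0,
                    confounder_only = 0, covariate_mediated = 0, null = 4),
    missing_aee_pwv_rate = 0, duplicate_fraction = 0, seed = 13))
  sf <- sex_score_table(co$metabolites, co$pheno, "F")
  expect_equal(attr(sf, "confounders"), c("age", "menopause"))
  expect_equal(nrow(sf), 20)
  sm <- sex_score_table(co$metabolites, co$pheno, "M")
  expect_equal(attr(sm, "confounders"), "age")
  expect_true(all(mm_analytes(co$metabolites) %in% names(sf)))
})
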