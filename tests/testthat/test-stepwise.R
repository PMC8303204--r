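test_that("forward selection finds a perfect single candidate and keeps R2 nondecreasing", {
  set.seed(1)
  d <- tibble::tibble(y = rnorm(30))
  d$x <- d$y
  path <- stepwise_forward(d, "y", "x")
  expect_equal(path$variable[1], "x")
  expect_equal(path$cumulative_r2[1], 1, tolerance = 1e-10)

  d2 <- make_regression_data(n = 100, n_noise = 8, seed = 2)
  path2 <- stepwise_forward(d2, "y", setdiff(names(d2), "y"))
  expect_true(all(diff(path2$cumulative_r2) >= -1e-10))
})

test_that("true predictors occupy the first steps of the path", {
  for (seed in 1:5) {
    d <- make_regression_data(n = 150, n_noise = 10, noise_sd = 0.3, seed = seed)
    path <- stepwise_forward(d, "y", setdiff(names(d), "y"), max_steps = 4)
    expect_setequal(path$variable[1:2], c("x1", "x2"))
  }
})

test_that("collinear candidates are skipped with a log entry, not an error", {
  d <- make_regression_data(n = 60, n_noise = 3, seed = 3)
  d$dup <- d$x1  # exactly collinear once x1 enters
  path <- stepwise_forward(d, "y", c("x1", "x2", "dup", "z01", "z02", "z03"))
  expect_false("dup" %in% path$variable && "x1" %in% path$variable &&
                 which(path$variable == "dup") > which(path$variable == "x1"))
  expect_true("dup" %in% attr(path, "skipped") || !"x1" %in% path$variable)
})

test_that("fixed variables enter before selection and stay disjoint from candidates", {
  d <- make_regression_data(n = 80, n_noise = 4, seed = 4)
  path <- stepwise_forward(d, "y", c("x2", "z01"), fixed = "x1")
  expect_false("x1" %in% path$variable)
  expect_gt(attr(path, "r2_fixed"), 0.2)
  expect_error(stepwise_forward(d, "y", c("x1", "x2"), fixed = "x1"), "disjoint")
})

test_that("cross-validated frequencies recover the truth and conserve counts", {
  d <- make_regression_data(n = 150, n_noise = 10, noise_sd = 0.4, seed = 5)
  fr <- cv_stepwise_frequencies(d, "y", setdiff(names(d), "y"),
                                n_repeats = 100, seed = 6)
  expect_gte(fr$frequency[fr$variable == "x1"], 0.95)
  expect_gte(fr$frequency[fr$variable == "x2"], 0.95)
  # conservation: sum of frequencies x repeats = sum of per-repeat set sizes
  expect_equal(sum(fr$frequency) * attr(fr, "n_repeats"),
               sum(attr(fr, "selected_sizes")))
  # pure-noise candidates mostly fall below the default threshold
  noise_freq <- fr$frequency[grepl("^z", fr$variable)]
  expect_gte(mean(noise_freq < 0.5), 0.9)
})

test_that("a single repeat with a fixed seed is reproducible", {
  d <- make_regression_data(n = 60, n_noise = 5, seed = 7)
  a <- cv_stepwise_frequencies(d, "y", setdiff(names(d), "y"), n_repeats = 1, seed = 9)
  b <- cv_stepwise_frequencies(d, "y", setdiff(names(d), "y"), n_repeats = 1, seed = 9)
  expect_identical(a$frequency, b$frequency)
})

test_that("final model applies the >= threshold, orders by frequency, and computes adjusted R2", {
  d <- make_regression_data(n = 102, n_noise = 5, seed = 8)
  fr <- tibble::tibble(variable = c("x1", "x2", "z01", "z02"),
                       frequency = c(1, 0.8, 0.05, 0.049))
  fm <- build_final_model(d, "y", fr, threshold = 0.05)
  expect_equal(fm$variables, c("x1", "x2", "z01"))  # 0.05 included, 0.049 not
  expect_lte(fm$adjusted_r2, fm$r2)
  expect_equal(fm$adjusted_r2,
               1 - (1 - fm$r2) * (fm$n - 1) / (fm$n - length(fm$variables) - 1),
               tolerance = 1e-12)
  # worked arithmetic: r2 = 0.5, n = 102, p = 7
  expect_equal(1 - 0.5 * 101 / 94, 0.462766, tolerance = 1e-6)

  # perfect fit
  dp <- tibble::tibble(y = rnorm(40)); dp$x <- dp$y
  fmp <- build_final_model(dp, "y", tibble::tibble(variable = "x", frequency = 1))
  expect_equal(fmp$adjusted_r2, 1, tolerance = 1e-10)

  # empty selection: intercept-only model
  fm0 <- build_final_model(d, "y", tibble::tibble(variable = "z01", frequency = 0.01))
  expect_length(fm0$variables, 0)
  expect_equal(fm0$r2, 0)
  expect_equal(fm0$intercept, mean(d$y))
})

test_that("approaches wire fixed and candidate sets per their contracts", {
  co <- generate_cohort(synthetic_config(n_female = 60, n_male = 60, p_analytes = 10,
    block_sizes = c(female_specific = 0, male_specific = 0, shared = 4,
                    confounder_only = 0, covariate_mediated = 0, null = 6),
    missing_aee_pwv_rate = 0, duplicate_fraction = 0, lod_censor_max = 0, seed = 40))
  sc <- sex_score_table(co$metabolites, co$pheno, "M")
  adj <- residualize_columns(sc[, c("vo2peak", "age", covariate_names(),
                                    mm_analytes(co$metabolites))], "age")
  mets <- mm_analytes(co$metabolites)
  expect_length(covariate_names(), 21)
  res2 <- run_approach(2, adj, "vo2peak", covariate_names(), mets,
                       n_repeats = 10, seed = 41, max_steps = 5)
  expect_true(all(covariate_names() %in% res2$final_model$variables))
  expect_false(any(covariate_names() %in% res2$frequencies$variable))
  res1 <- run_approach(1, adj, "vo2peak", covariate_names(), mets,
                       n_repeats = 10, seed = 42, max_steps = 5)
  expect_setequal(res1$frequencies$variable, covariate_names())
  expect_error(run_approach(4, adj, "vo2peak", covariate_names(), mets), "approach")
})

test_that("a fat-mass-dominated cohort selects FM_pct first under approach 3", {
  co <- generate_cohort(synthetic_config(n_female = 102, n_male = 150, p_analytes = 20,
    block_sizes = c(female_specific = 3, male_specific = 3, shared = 4,
                    confounder_only = 0, covariate_mediated = 5, null = 5),
    missing_aee_pwv_rate = 0, duplicate_fraction = 0, lod_censor_max = 0, seed = 43))
  for (sx in c("F", "M")) {
    sc <- sex_score_table(co$metabolites, co$pheno, sx)
    confs <- attr(sc, "confounders")
    adj <- residualize_columns(sc[, c("vo2peak", confs, covariate_names(),
                                      mm_analytes(co$metabolites))], confs)
    path <- stepwise_forward(adj, "vo2peak",
                             c(covariate_names(), mm_analytes(co$metabolites)),
                             max_steps = 3)
    expect_equal(path$variable[1], "FM_pct")
  }
})
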