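test_that("quartile groups follow the type-7 convention with lower-quarter ties", {
  expect_equal(quartile_groups(1:8), rep(1:4, each = 2))
  # n = 10: type-7 boundaries give sizes (3, 2, 2, 3)
  expect_equal(as.integer(table(quartile_groups(1:10))), c(3L, 2L, 2L, 3L))
  # a value exactly at the first boundary falls into the lower quarter
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  q1 <- stats::quantile(x, 0.25, type = 7, names = FALSE)
  g <- quartile_groups(c(x, q1))
  expect_equal(g[9], 1L)
  expect_error(quartile_groups(rep(2, 10)), "constant")
  expect_error(quartile_groups(1:7), "at least 8")
})

test_that("quarter sizes differ by at most one on distinct values", {
  set.seed(3)
  for (n in c(8, 13, 40, 101)) {
    g <- quartile_groups(sample(rnorm(n)))
    expect_lte(diff(range(table(g))), 1)
  }
})

test_that("Welch ANOVA matches its oracles", {
  # identical groups: F = 0, p = 1
  v <- rep(c(1, 2, 3), 4)
  g <- rep(1:4, each = 3)
  res <- welch_anova(v, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # two groups: F equals Welch's t squared
  set.seed(4)
  a <- rnorm(12); b <- rnorm(15, 1, 2)
  res2 <- welch_anova(c(a, b), rep(1:2, c(12, 15)))
  tt <- t.test(a, b, var.equal = FALSE)
  expect_equal(res2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p_value, tt$p.value, tolerance = 1e-10)

  # three-group worked case against the hand-computed weighted-means formula
  groups <- list(c(7.1, 6.3, 6.8, 7.4), c(5.9, 6.1, 6.4), c(8.0, 7.7, 8.4, 8.1, 7.9))
  w <- sapply(groups, function(x) length(x) / var(x))
  xbar <- sapply(groups, mean)
  k <- length(groups)
  grand <- sum(w * xbar) / sum(w)
  num <- sum(w * (xbar - grand)^2) / (k - 1)
  h <- sum((1 - w / sum(w))^2 / (sapply(groups, length) - 1))
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * h
  f_oracle <- num / den
  df2_oracle <- (k^2 - 1) / (3 * h)
  res3 <- welch_anova(unlist(groups), rep(1:3, sapply(groups, length)))
  expect_equal(res3$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res3$df2, df2_oracle, tolerance = 1e-10)
  expect_error(welch_anova(c(1, 2, 3), c(1, 1, 2)), "at least 2")
})

test_that("Welch ANOVA converges to classical ANOVA for balanced equal-variance groups", {
  # Welch's denominator correction vanishes as group sizes grow, so the two
  # statistics agree in the balanced equal-variance limit
  ratio_at <- function(n_per) {
    set.seed(5)
    v <- rnorm(4 * n_per, rep(c(0, 0.2, 0.4, 0.6), each = n_per), 1)
    g <- rep(1:4, each = n_per)
    for (i in 1:4) {   # equalize group variances exactly
      idx <- g == i
      v[idx] <- (v[idx] - mean(v[idx])) / sd(v[idx]) + mean(v[idx])
    }
    w <- welch_anova(v, g)$statistic
    cl <- unname(stats::oneway.test(v ~ factor(g), var.equal = TRUE)$statistic)
    abs(w / cl - 1)
  }
  expect_lt(ratio_at(100), 0.01)
  expect_lt(ratio_at(2000), 0.001)
  expect_lt(ratio_at(2000), ratio_at(100))
})

test_that("chi-squared across quarters matches the O-E oracle and warns on small cells", {
  # identical column distributions: statistic 0, p 1
  cats <- rep(rep(c("a", "b"), each = 5), 4)
  qs <- rep(1:4, each = 10)
  res <- chi_squared_quarters(cats, qs)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  # hand-computed 2x2 table
  tab <- matrix(c(20, 10, 12, 28), 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  oracle <- sum((tab - expected)^2 / expected)
  cats2 <- rep(c("x", "x", "y", "y"), c(20, 10, 12, 28))
  qs2 <- rep(c(1, 2, 1, 2), c(20, 10, 12, 28))
  res2 <- chi_squared_quarters(cats2, qs2)
  expect_equal(res2$statistic, oracle, tolerance = 1e-10)
  expect_equal(res2$df, 1)

  expect_warning(chi_squared_quarters(rep(c("a", "b"), c(3, 5)),
                                      rep(1:2, 4)), "below 5")
  expect_error(chi_squared_quarters(rep("a", 10), rep(1:2, 5)), "degenerate")
})

test_that("quarter summaries compute relative means and detect planted trends", {
  co <- generate_cohort(synthetic_config(n_female = 80, n_male = 80, p_analytes = 4,
    block_sizes = c(female_specific = 0, male_specific = 0, shared = 0,
                    confounder_only = 0, covariate_mediated = 0, null = 4),
    missing_aee_pwv_rate = 0, duplicate_fraction = 0, seed = 50))
  qs <- quarter_summary_table(co$pheno, "M")
  # first-quarter reference is exactly 1
  expect_true(all(qs$relative_mean[qs$quarter == 1 & !is.na(qs$relative_mean)] == 1))
  # quarter sizes sum to the subgroup size for every variable
  expect_true(all(tapply(qs$n[qs$test == "welch_anova"],
                         qs$variable[qs$test == "welch_anova"], sum) == 80))
  # the generator makes VO2peak fall with age, so age differs across quarters
  age_p <- unique(qs$p_value[qs$variable == "age"])
  expect_lt(age_p, 0.05)
  # females get the menopause chi-squared row
  qf <- quarter_summary_table(co$pheno, "F")
  expect_true("chi_squared" %in% qf$test)
})

test_that("a variable doubled in one quarter has relative mean 2 and constants give p = 1", {
  ph <- generate_cohort(synthetic_config(n_female = 40, n_male = 40, p_analytes = 4,
    block_sizes = c(female_specific = 0, male_specific = 0, shared = 0,
                    confounder_only = 0, covariate_mediated = 0, null = 4),
    missing_aee_pwv_rate = 0, duplicate_fraction = 0, seed = 51))$pheno
  m <- ph[ph$sex == "M", ]
  q <- quartile_groups(m$vo2peak)
  m$HEI_NVS <- 1
  m$HEI_NVS[q == 2] <- 2
  m$Hb <- 7  # constant across quarters
  m$Hb <- m$Hb + rep(c(0), nrow(m))
  ph2 <- dplyr::bind_rows(m, ph[ph$sex == "F", ])
  qs <- suppressWarnings(quarter_summary_table(ph2, "M"))
  expect_equal(qs$relative_mean[qs$variable == "HEI_NVS" & qs$quarter == 2], 2)
  expect_equal(unique(qs$p_value[qs$variable == "Hb"]), 1)
})
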