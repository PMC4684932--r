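test_that("ttest_individual matches the reference t computation", {
  d <- generate_design_b(design_spec("B", 10, 6),
                         resolve_params(d = 0.4, icc = 0, var_u1 = 0),
                         seed = 21)
  fr <- ttest_individual(d)
  ref <- t.test(y ~ condition, data = d, var.equal = TRUE)
  expect_equal(fr$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(fr$estimate, diff(ref$estimate)[[1]], tolerance = 1e-12)
  expect_equal(fr$df, 2 * 10 * 6 - 2)

  frw <- ttest_individual(d, welch = TRUE)
  refw <- t.test(y ~ condition, data = d)
  expect_equal(frw$p_value, refw$p.value, tolerance = 1e-12)

  # degenerate noiseless data
  p0 <- population_params(gamma00 = 1, gamma10 = 2, var_e = 0)
  fr0 <- ttest_individual(generate_design_b(design_spec("B", 4, 3), p0, 1))
  expect_equal(fr0$estimate, 2)
  expect_identical(fr0$se, 0)
  expect_identical(fr0$p_value, 0)
})

test_that("paired_ttest_means reproduces the hand-computed oracle", {
  # cluster condition means (0,1), (1,3), (2,2) -> differences (1, 2, 0)
  d <- data_from_cells(cells0 = list(c(-1, 1), c(0, 2), c(1.5, 2.5)),
                       cells1 = list(c(0.5, 1.5), c(2, 4), c(1, 3)))
  fr <- paired_ttest_means(d)
  expect_equal(fr$estimate, 1)
  expect_equal(fr$se, 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(fr$statistic, sqrt(3), tolerance = 1e-10)
  expect_equal(fr$df, 2)
  ref <- t.test(c(1, 2, 0))
  expect_equal(fr$p_value, ref$p.value, tolerance = 1e-12)

  # constant differences -> degenerate se
  dc <- data_from_cells(list(0, 1, 2), list(3, 4, 5))
  frc <- paired_ttest_means(dc)
  expect_equal(frc$estimate, 3)
  expect_identical(frc$se, 0)

  # a cluster missing a condition is named in the error
  bad <- as.data.frame(d)[-(1:2), ]
  expect_error(as_nested_data(bad, design = "B"), "1",
               class = "np_validation_error")
})

test_that("ttest_cluster_means matches the pooled-t oracle on cluster means", {
  df <- data.frame(cluster = rep(1:4, each = 2),
                   condition = rep(c(0L, 0L, 1L, 1L), each = 2),
                   y = c(-1, 1, 1, 3, 0, 2, 2, 4))  # means 0, 2 | 1, 3
  d <- as_nested_data(df, design = "A")
  fr <- ttest_cluster_means(d)
  expect_equal(fr$estimate, 1)
  expect_equal(fr$statistic, 1 / sqrt(2), tolerance = 1e-10)
  expect_equal(fr$df, 2)
  ref <- t.test(c(1, 3), c(0, 2), var.equal = TRUE)
  expect_equal(fr$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(ttest_cluster_means(toy_b()), class = "np_usage_error")
})

test_that("lmm_intercept: balanced GLS equals the grand mean difference", {
  d <- toy_b(N = 12, nc = 5, d = 0.4, icc = 0.5, var_u1 = 0, seed = 31)
  fr <- lmm_intercept(d)
  raw_diff <- mean(d$y[d$condition == 1]) - mean(d$y[d$condition == 0])
  expect_equal(fr$estimate, raw_diff, tolerance = 1e-8)
  expect_identical(fr$df, Inf)
  expect_equal(fr$p_value, 2 * pnorm(-abs(fr$statistic)), tolerance = 1e-12)
  expect_true(all(c("var_e", "var_u0") %in% names(fr$varcomp)))

  # boundary recovery: data generated with var_u0 = 0
  d0 <- toy_b(N = 30, nc = 10, d = 0, icc = 0, var_u1 = 0, seed = 32)
  fr0 <- lmm_intercept(d0)
  expect_lt(fr0$varcomp$var_u0, 0.05)
  expect_true(fr0$converged)
})

test_that("lmm_intercept_slope agrees with the paired-means estimate when balanced", {
  d <- toy_b(N = 15, nc = 6, d = 0.5, icc = 0.25, var_u1 = 0.1, seed = 33)
  fr <- lmm_intercept_slope(d)
  frp <- paired_ttest_means(d)
  expect_equal(fr$estimate, frp$estimate, tolerance = 1e-6)
  expect_true(all(c("var_e", "var_u0", "var_u1", "cov_u0u1") %in%
                    names(fr$varcomp)))
  fr_nc <- lmm_intercept_slope(d, estimate_covariance = FALSE)
  expect_equal(fr_nc$estimate, frp$estimate, tolerance = 1e-6)
  expect_false("cov_u0u1" %in% names(fr_nc$varcomp))
})

test_that("fixed_effects_dummies equals the OLS dummy regression", {
  d <- toy_b(N = 8, nc = 4, d = 0.3, icc = 0.5, var_u1 = 0.05, seed = 34)
  fr <- fixed_effects_dummies(d)
  ref <- summary(lm(y ~ condition + factor(cluster), data = d))$coefficients
  expect_equal(fr$estimate, ref["condition", "Estimate"], tolerance = 1e-10)
  expect_equal(fr$se, ref["condition", "Std. Error"], tolerance = 1e-10)
  expect_equal(fr$p_value, ref["condition", "Pr(>|t|)"], tolerance = 1e-10)
  expect_equal(fr$df, nrow(d) - 8 - 1)
  expect_equal(fr$estimate, paired_ttest_means(d)$estimate, tolerance = 1e-8)
})

test_that("lmm_covariate recovers the residual slope variance", {
  spec <- design_spec("B", 300, 10)
  p <- resolve_params(d = 0.5, icc = 0.25, var_u1 = 0.2)
  d <- generate_with_cluster_covariate(spec, p, explained_fraction = 0.5,
                                       seed = 35)
  fr <- lmm_covariate(d)
  expect_true(fr$converged)
  expect_lt(abs(fr$varcomp$var_u1 - 0.1), 0.04)
  # the full model ignoring w sees the marginal slope variance instead
  fr_marg <- lmm_intercept_slope(d)
  expect_lt(abs(fr_marg$varcomp$var_u1 - 0.2), 0.06)
  expect_error(lmm_covariate(toy_b()), class = "np_usage_error")
})

test_that("all design-B estimators agree on the balanced point estimate", {
  d <- toy_b(N = 10, nc = 5, d = 0.6, icc = 0.5, var_u1 = 0.1, seed = 36)
  ests <- c(ttest_individual(d)$estimate,
            paired_ttest_means(d)$estimate,
            lmm_intercept(d)$estimate,
            lmm_intercept_slope(d)$estimate,
            fixed_effects_dummies(d)$estimate)
  expect_lt(max(ests) - min(ests), 1e-6)
})

test_that("estimators are equivariant and invariant to cluster relabeling", {
  d <- toy_b(N = 8, nc = 4, seed = 37)
  methods <- c("ttest_individual", "paired_ttest_means", "lmm_intercept",
               "lmm_intercept_slope", "fixed_effects_dummies")
  set.seed(373)
  perm <- sample(8)
  d_relab <- d
  d_relab$cluster <- perm[d$cluster]
  for (m in methods) {
    fr <- fit_method(m, d)
    expect_gte(fr$p_value, 0)
    expect_lte(fr$p_value, 1)
    # shift invariance
    d_shift <- d; d_shift$y <- d$y + 5
    expect_equal(fit_method(m, d_shift)$estimate, fr$estimate,
                 tolerance = 1e-6)
    # scale equivariance of estimate and se
    d_scale <- d; d_scale$y <- d$y * 3
    frs <- fit_method(m, d_scale)
    expect_equal(frs$estimate, 3 * fr$estimate, tolerance = 1e-6)
    expect_equal(frs$se, 3 * fr$se, tolerance = 1e-5)
    # relabeling clusters
    expect_equal(fit_method(m, d_relab)$p_value, fr$p_value, tolerance = 1e-6)
  }
  expect_error(fit_method("no_such_method", d), class = "np_usage_error")
})
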