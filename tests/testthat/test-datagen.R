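test_that("noiseless design-B data are exactly the fixed effects", {
  p <- population_params(gamma00 = 1, gamma10 = 2, var_e = 0)
  d <- generate_design_b(design_spec("B", 5, 3), p, seed = 1)
  expect_equal(unique(d$y[d$condition == 0]), 1)
  expect_equal(unique(d$y[d$condition == 1]), 3)
  expect_identical(nrow(d), 2L * 3L * 5L)
})

test_that("generation is seed-deterministic and balanced", {
  spec <- design_spec("B", 8, 6)
  p <- resolve_params(d = 0.5, icc = 0.25, var_u1 = 0.05, cov_u0u1 = 0.02)
  d1 <- generate_design_b(spec, p, seed = 99)
  d2 <- generate_design_b(spec, p, seed = 99)
  expect_identical(d1, d2)
  d3 <- generate_design_b(spec, p, seed = 100)
  expect_false(identical(d1$y, d3$y))
  counts <- table(d1$cluster, d1$condition)
  expect_true(all(counts == 6L))
  expect_true(attr(d1, "balanced"))
  # design mismatch is a usage error
  expect_error(generate_design_b(design_spec("A", 8, 6), p, seed = 1),
               class = "np_usage_error")
})

test_that("design-B moments recover the generating parameters", {
  # variance of cluster control-condition means = var_u0 + var_e/nc
  nc <- 5
  p <- resolve_params(d = 0.2, icc = 0.5, var_u1 = 0)  # var_u0 = 1
  d <- generate_design_b(design_spec("B", 2000, nc), p, seed = 7)
  m0 <- tapply(d$y[d$condition == 0], d$cluster[d$condition == 0], mean)
  v_expect <- 1 + 1 / nc
  se_var <- sqrt(2 / (2000 - 1)) * v_expect
  expect_lt(abs(var(m0) - v_expect), 3 * se_var)

  # variance of per-cluster effect estimates = var_u1 + 2 var_e / nc
  p2 <- resolve_params(d = 0, icc = 0, var_u1 = 0.15)
  d2 <- generate_design_b(design_spec("B", 2000, nc), p2, seed = 8)
  dif <- cluster_diffs(d2)
  v2 <- 0.15 + 2 / nc
  expect_lt(abs(var(dif) - v2), 3 * sqrt(2 / 1999) * v2)
  expect_lt(abs(mean(dif)), 3 * sqrt(v2 / 2000))
})

test_that("design-A generator allocates half/half and recovers the ICC", {
  p <- resolve_params(d = 0, icc = 0.5)
  spec <- design_spec("A", 2000, 5)
  d <- generate_design_a(spec, p, seed = 3)
  z_by_cl <- tapply(d$condition, d$cluster, unique)
  expect_true(all(lengths(z_by_cl) == 1L))
  expect_identical(sum(unlist(z_by_cl) == 1L), 1000L)
  # one-way moment estimator of the ICC
  cm <- tapply(d$y, d$cluster, mean)
  within_var <- mean(tapply(d$y, d$cluster, var))
  between <- var(cm) - within_var / 5
  icc_hat <- between / (between + within_var)
  expect_lt(abs(icc_hat - 0.5), 0.05)

  expect_error(generate_design_a(spec, resolve_params(d = 0, icc = 0, var_u1 = 0.1),
                                 seed = 1),
               class = "np_usage_error")
  p0 <- population_params(gamma00 = 1, gamma10 = 2, var_e = 0)
  d0 <- generate_design_a(design_spec("A", 4, 3), p0, seed = 1)
  expect_equal(as.numeric(tapply(d0$y, d0$condition, mean)), c(1, 3))
})

test_that("cluster-covariate generator partitions the slope variance", {
  spec <- design_spec("B", 4000, 10)
  p <- resolve_params(d = 0, icc = 0.2, var_u1 = 0.10)
  d <- generate_with_cluster_covariate(spec, p, explained_fraction = 0.64,
                                       seed = 5)
  expect_true("w" %in% names(d))
  expect_true(all(tapply(d$w, d$cluster, function(v) length(unique(v))) == 1L))
  dif <- cluster_diffs(d)
  w <- tapply(d$w, d$cluster, function(v) v[1])
  coef_hat <- unname(coef(lm(dif ~ w))[2])
  expect_lt(abs(coef_hat - sqrt(0.064)), 3 * sqrt((0.036 + 2 / 10) / 4000))
  # marginal slope-estimate variance is var_u1 + 2 var_e/nc regardless of f
  v_marg <- 0.10 + 2 / 10
  expect_lt(abs(var(dif) - v_marg), 3 * sqrt(2 / 3999) * v_marg)

  expect_error(generate_with_cluster_covariate(spec, p, 1, seed = 1),
               class = "np_invalid_parameter")
  expect_error(
    generate_with_cluster_covariate(spec, resolve_params(d = 0, icc = 0), 0.5,
                                    seed = 1),
    class = "np_usage_error")
})

test_that("explained_fraction = 0 reproduces the plain design-B distribution", {
  spec <- design_spec("B", 30, 5)
  p <- resolve_params(d = 0.3, icc = 0.25, var_u1 = 0.08)
  d0 <- generate_with_cluster_covariate(spec, p, 0, seed = 77)
  # same marginal law; with f = 0 the covariate is pure noise, so a large-N
  # regression slope of cluster effects on w is ~0
  d_big <- generate_with_cluster_covariate(design_spec("B", 3000, 5), p, 0,
                                           seed = 78)
  dif <- cluster_diffs(d_big)
  w <- tapply(d_big$w, d_big$cluster, function(v) v[1])
  expect_lt(abs(unname(coef(lm(dif ~ w))[2])), 3 * sqrt((0.08 + 0.4) / 3000))
  expect_identical(attr(d0, "design"), "B")
})

test_that("as_nested_data validates structural invariants", {
  df <- data.frame(cluster = c(1, 1, 2, 2), condition = c(0, 1, 0, 1),
                   y = rnorm(4))
  nd <- as_nested_data(df)
  expect_identical(attr(nd, "design"), "B")
  expect_error(as_nested_data(transform(df, condition = c(0, 2, 0, 1))),
               class = "np_validation_error")
  # design B with a cluster lacking a condition
  expect_error(as_nested_data(df[-2, ], design = "B"),
               class = "np_validation_error")
  # w varying within cluster
  expect_error(as_nested_data(cbind(df, w = c(1, 2, 3, 3))),
               class = "np_validation_error")
})
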