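#' @rdname fit_result
#' @export
ESTIMATOR_METHODS <- c("ttest_individual", "paired_ttest_means",
                       "ttest_cluster_means", "lmm_intercept",
                       "lmm_intercept_slope", "fixed_effects_dummies",
                       "lmm_covariate")

#' Uniform result container for all estimators
#'
#' Every estimator in the package returns a `fit_result` describing its
#' inference on the overall experimental effect: the point estimate (condition
#' mean difference / \eqn{\hat\gamma_{10}}), its standard error, the Wald-form
#' statistic `estimate/se`, the degrees-of-freedom convention (`Inf` means a
#' standard-normal reference, the Wald z used for mixed models), the two-sided
#' p-value, estimated variance components where the method provides them, and
#' a convergence flag.
#'
#' @param method One of `ESTIMATOR_METHODS`.
#' @param estimate,se,df Effect estimate, its standard error, reference df.
#' @param varcomp Named list of estimated variance components.
#' @param converged Logical; `FALSE` only when the optimiser failed.
#' @param alpha Optional significance level; if given, `alpha_decision` is
#'   `p_value < alpha`.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(method, estimate, se, df, varcomp = list(),
                       converged = TRUE, alpha = NULL) {
  method <- match.arg(method, ESTIMATOR_METHODS)
  if (se < 0 || is.na(se)) np_validation_error("standard error must be >= 0")
  if (se == 0) {
    # degenerate (noiseless) data: decide by the sign of the estimate
    statistic <- if (estimate == 0) 0 else sign(estimate) * Inf
    p_value <- if (estimate == 0) 1 else 0
  } else {
    statistic <- estimate / se
    p_value <- if (is.finite(df)) 2 * stats::pt(-abs(statistic), df)
               else 2 * stats::pnorm(-abs(statistic))
  }
  structure(
    list(method = method, estimate = estimate, se = se, statistic = statistic,
         df = df, p_value = p_value,
         alpha_decision = if (!is.null(alpha)) p_value < alpha else NA,
         varcomp = varcomp, converged = converged),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s\n", x$method))
  cat(sprintf("  estimate = %.6g  se = %.6g  %s = %.4g  df = %s  p = %.4g%s\n",
              x$estimate, x$se, if (is.finite(x$df)) "t" else "z", x$statistic,
              if (is.finite(x$df)) format(x$df) else "Inf (Wald z)", x$p_value,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  if (length(x$varcomp))
    cat("  varcomp:", paste(sprintf("%s = %.4g", names(x$varcomp),
                                    unlist(x$varcomp)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.fit_result <- function(x, ...) {
  jsonlite::toJSON(
    c(x[c("method", "estimate", "se", "statistic", "df", "p_value",
          "alpha_decision", "converged")], list(varcomp = x$varcomp)),
    auto_unbox = TRUE, digits = NA, na = "null")
}

check_dataset <- function(data) {
  if (!inherits(data, "nested_data")) data <- as_nested_data(data)
  data
}

#' t test on the individual observations, ignoring clusters
#'
#' The "conventional analysis": a pooled-variance two-sample Student t test
#' comparing all experimental against all control observations as if they were
#' independent. Under cluster-related variation in the experimental effect its
#' standard error is underestimated and the false positive rate inflates well
#' above the nominal level; under intercept variation only, it loses power.
#'
#' @param data A `nested_data` object (or coercible data frame).
#' @param alpha Significance level recorded in the result.
#' @param welch Use the Welch (unequal-variance) t instead of the pooled t.
#'   The pooled Student t is the default: group sizes are equal by design.
#' @return A [fit_result()].
#' @export
ttest_individual <- function(data, alpha = 0.05, welch = FALSE) {
  data <- check_dataset(data)
  y1 <- data$y[data$condition == 1L]
  y0 <- data$y[data$condition == 0L]
  n1 <- length(y1); n0 <- length(y0)
  if (n1 < 2L || n0 < 2L)
    np_usage_error("each condition needs at least 2 observations")
  est <- mean(y1) - mean(y0)
  v1 <- stats::var(y1); v0 <- stats::var(y0)
  if (welch) {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- n1 + n0 - 2
  }
  fit_result("ttest_individual", est, se, df, alpha = alpha)
}

cluster_condition_means <- function(data, caller) {
  cl <- data$cluster; x <- data$condition
  m0 <- tapply(data$y[x == 0L], cl[x == 0L], mean)
  m1 <- tapply(data$y[x == 1L], cl[x == 1L], mean)
  ids <- sort(unique(cl))
  missing <- ids[!(ids %in% as.integer(names(m0))) | !(ids %in% as.integer(names(m1)))]
  if (length(missing))
    np_usage_error(sprintf("%s: cluster(s) %s lack observations in one condition",
                           caller, paste(missing, collapse = ", ")))
  cbind(m0 = m0[as.character(ids)], m1 = m1[as.character(ids)])
}

#' Paired t test on condition-specific cluster means
#'
#' The summary-statistics analysis for design B: average the observations per
#' condition within each cluster, then run a one-sample t test on the `N`
#' within-cluster differences (df = N - 1). This accommodates both intercept
#' and slope variation, so it keeps the nominal type-I error rate, at the cost
#' of some power when the number of clusters is small. Correct parameter
#' estimates require (sub)sample sizes equal over clusters and conditions.
#'
#' @inheritParams ttest_individual
#' @return A [fit_result()].
#' @export
paired_ttest_means <- function(data, alpha = 0.05) {
  data <- check_dataset(data)
  if (attr(data, "design") != "B")
    np_usage_error("paired_ttest_means() requires design-B data")
  m <- cluster_condition_means(data, "paired_ttest_means")
  dif <- m[, "m1"] - m[, "m0"]
  N <- length(dif)
  if (N < 2L) np_usage_error("need at least 2 clusters")
  est <- mean(dif)
  se <- stats::sd(dif) / sqrt(N)
  fit_result("paired_ttest_means", est, se, N - 1, alpha = alpha)
}

#' Two-sample t test on cluster means (design A)
#'
#' The summary-statistics analysis for design A: average all observations in
#' each cluster and compare the two groups of cluster means with a pooled
#' Student t test.
#'
#' @inheritParams ttest_individual
#' @return A [fit_result()].
#' @export
ttest_cluster_means <- function(data, alpha = 0.05) {
  data <- check_dataset(data)
  if (attr(data, "design") != "A")
    np_usage_error("ttest_cluster_means() requires design-A data")
  m <- tapply(data$y, data$cluster, mean)
  z <- tapply(data$condition, data$cluster, function(v) v[1])
  m1 <- m[z == 1]; m0 <- m[z == 0]
  if (length(m1) < 2L || length(m0) < 2L)
    np_usage_error("need at least 2 clusters per condition")
  n1 <- length(m1); n0 <- length(m0)
  sp2 <- ((n1 - 1) * stats::var(m1) + (n0 - 1) * stats::var(m0)) / (n1 + n0 - 2)
  fit_result("ttest_cluster_means", mean(m1) - mean(m0),
             sqrt(sp2 * (1 / n1 + 1 / n0)), n1 + n0 - 2, alpha = alpha)
}

# Shared lme4 fitting with convergence bookkeeping. Singular fits (variance on
# the boundary) are kept as converged; only optimizer failures flag FALSE.
fit_lmer <- function(formula, data, reml) {
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(formula, data = data, REML = reml, control = ctrl),
             error = function(e) e),
    warning = function(w) {
      if (grepl("conv", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  if (inherits(fit, "error")) return(list(fit = NULL, converged = FALSE))
  list(fit = fit, converged = converged)
}

lmer_result <- function(method, fitted, data, alpha, term = "condition") {
  if (is.null(fitted$fit)) {
    # optimizer failure: return a degenerate, clearly flagged result
    return(fit_result(method, NA_real_, Inf, Inf, varcomp = list(),
                      converged = FALSE, alpha = alpha))
  }
  fit <- fitted$fit
  beta <- lme4::fixef(fit)[[term]]
  se <- sqrt(as.matrix(stats::vcov(fit))[term, term])
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- list(var_e = vc$vcov[vc$grp == "Residual"])
  vint <- vc$vcov[vc$grp != "Residual" & vc$var1 == "(Intercept)" &
                    is.na(vc$var2)]
  vslp <- vc$vcov[vc$grp != "Residual" & vc$var1 == "condition" & is.na(vc$var2)]
  vcov01 <- vc$vcov[!is.na(vc$var2)]
  if (length(vint)) varcomp$var_u0 <- sum(vint)
  if (length(vslp)) varcomp$var_u1 <- sum(vslp)
  if (length(vcov01)) varcomp$cov_u0u1 <- sum(vcov01)
  fit_result(method, beta, se, Inf, varcomp = varcomp,
             converged = fitted$converged, alpha = alpha)
}

#' Random-intercept multilevel model ("multilevel analysis I")
#'
#' Fits \eqn{Y = \gamma_{00} + \gamma_{10} X + u_{0j} + e} with a random
#' intercept only, by REML (default) via \pkg{lme4}. The fixed effect is
#' tested with a Wald z (estimate/SE against the standard normal). For design
#' B data this model is *misspecified* whenever slope variance exists: it then
#' inherits the same inflated false positive rate as the naive t test.
#'
#' @inheritParams ttest_individual
#' @param reml Use REML (default) rather than ML.
#' @return A [fit_result()] with `varcomp` entries `var_e`, `var_u0`.
#' @export
lmm_intercept <- function(data, alpha = 0.05, reml = TRUE) {
  data <- check_dataset(data)
  if (length(unique(data$cluster)) < 2L)
    np_usage_error("need at least 2 clusters")
  fitted <- fit_lmer(y ~ condition + (1 | cluster), data, reml)
  lmer_result("lmm_intercept", fitted, data, alpha)
}

#' Random-intercept + random-slope multilevel model ("multilevel analysis II")
#'
#' The correctly specified model for design-B data with cluster-related
#' variation in both the intercept and the experimental effect:
#' \eqn{Y = \gamma_{00} + u_{0j} + (\gamma_{10} + u_{1j}) X + e}, with
#' \eqn{(u_{0j}, u_{1j})} bivariate normal. REML by default; Wald z test of
#' \eqn{\gamma_{10}}.
#'
#' @inheritParams lmm_intercept
#' @param estimate_covariance Estimate the intercept-slope covariance
#'   (default); if `FALSE` the two random effects are modelled independent.
#' @return A [fit_result()] with `varcomp` entries `var_e`, `var_u0`,
#'   `var_u1` (and `cov_u0u1` when estimated).
#' @export
lmm_intercept_slope <- function(data, alpha = 0.05, reml = TRUE,
                                estimate_covariance = TRUE) {
  data <- check_dataset(data)
  if (attr(data, "design") != "B")
    np_usage_error("lmm_intercept_slope() requires design-B data")
  form <- if (estimate_covariance) y ~ condition + (1 + condition | cluster)
          else y ~ condition + (1 | cluster) + (0 + condition | cluster)
  fitted <- fit_lmer(form, data, reml)
  lmer_result("lmm_intercept_slope", fitted, data, alpha)
}

#' Fixed-effects dummy regression
#'
#' OLS of Y on the condition dummy plus `N - 1` cluster-membership indicators,
#' testing the condition coefficient with df `n - N - 1`. Computed via
#' within-cluster centering (Frisch-Waugh), which is exact and avoids the
#' `N`-column model matrix. Treats clusters as fixed: inference does not
#' generalize beyond the clusters in the study, and slope variation is not
#' modelled.
#'
#' @inheritParams ttest_individual
#' @return A [fit_result()].
#' @export
fixed_effects_dummies <- function(data, alpha = 0.05) {
  data <- check_dataset(data)
  if (attr(data, "design") != "B")
    np_usage_error("fixed_effects_dummies() requires design-B data (in design A the cluster dummies absorb the condition)")
  cl <- data$cluster
  xt <- data$condition - stats::ave(data$condition, cl)
  yt <- data$y - stats::ave(data$y, cl)
  sxx <- sum(xt^2)
  if (sxx <= 0)
    np_usage_error("condition is collinear with the cluster indicators (rank deficient)")
  est <- sum(xt * yt) / sxx
  n <- nrow(data); N <- length(unique(cl))
  df <- n - N - 1
  rss <- sum((yt - est * xt)^2)
  se <- sqrt(rss / df / sxx)
  fit_result("fixed_effects_dummies", est, se, df, alpha = alpha)
}

#' Multilevel model with a cluster-level covariate for the slope
#'
#' Extends the random-intercept/random-slope model with fixed terms for a
#' cluster-level covariate `w` and its cross-level interaction `w:X`, which
#' (partly) explains the cluster-related variation in the experimental effect.
#' The reported effect is the conditional overall effect \eqn{\gamma_{10}}
#' (at `w = 0`); `varcomp$var_u1` is the *residual* slope variance, whose
#' reduction is what buys extra power.
#'
#' @inheritParams lmm_intercept
#' @return A [fit_result()].
#' @export
lmm_covariate <- function(data, alpha = 0.05, reml = TRUE) {
  data <- check_dataset(data)
  if (!("w" %in% names(data)))
    np_usage_error("lmm_covariate() requires a cluster covariate column `w`")
  if (attr(data, "design") != "B")
    np_usage_error("lmm_covariate() requires design-B data")
  fitted <- fit_lmer(y ~ condition * w + (1 + condition | cluster), data, reml)
  lmer_result("lmm_covariate", fitted, data, alpha)
}

#' Fit one of the package's estimators by name
#'
#' @param method One of `ESTIMATOR_METHODS`.
#' @param data A `nested_data` object.
#' @param alpha Significance level.
#' @param ... Passed to the method (e.g. `reml`, `welch`).
#' @return A [fit_result()].
#' @export
fit_method <- function(method, data, alpha = 0.05, ...) {
  if (!method %in% ESTIMATOR_METHODS)
    np_usage_error(sprintf("unknown method '%s'; valid: %s", method,
                           paste(ESTIMATOR_METHODS, collapse = ", ")))
  switch(method,
         ttest_individual = ttest_individual(data, alpha, ...),
         paired_ttest_means = paired_ttest_means(data, alpha),
         ttest_cluster_means = ttest_cluster_means(data, alpha),
         lmm_intercept = lmm_intercept(data, alpha, ...),
         lmm_intercept_slope = lmm_intercept_slope(data, alpha, ...),
         fixed_effects_dummies = fixed_effects_dummies(data, alpha),
         lmm_covariate = lmm_covariate(data, alpha, ...))
}
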