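#' Standard error of the overall experimental effect in multilevel analysis
#'
#' Closed form for a balanced two-level design with standardized data
#' (both the condition variable and the outcome scaled to unit variance):
#' \deqn{SE_{\gamma_{10}} = \sqrt{(nc\,\sigma^2_{u1} + \sigma^2_e) / (nc\,N)}.}
#' Two structural facts follow directly: slope variance puts a floor under
#' the SE that extra observations per cluster cannot remove (as
#' \eqn{nc \to \infty} the SE tends to \eqn{\sqrt{\sigma^2_{u1}/N}}), while
#' extra clusters always shrink it by \eqn{1/\sqrt{N}}.
#'
#' Note this standardized-data convention differs by constant factors from
#' the sampling variance of the dummy-coded (0/1) mean-difference estimator;
#' the dummy-coded expressions used for type-I predictions are kept in
#' [analytic_type1_naive_ttest()].
#'
#' @param nc Observations per condition per cluster.
#' @param N Number of clusters.
#' @param var_u1 Slope variance, `>= 0`.
#' @param var_e Residual variance, `> 0`.
#' @return The standard error (positive scalar).
#' @examples
#' se_gamma10(nc = 5, N = 10, var_u1 = 0.05, var_e = 1)
#' @export
se_gamma10 <- function(nc, N, var_u1, var_e) {
  nc <- check_count(nc, "nc"); N <- check_count(N, "N")
  var_u1 <- check_scalar(var_u1, "var_u1"); var_e <- check_scalar(var_e, "var_e")
  if (var_u1 < 0) np_invalid_parameter("`var_u1` must be >= 0")
  if (var_e <= 0) np_invalid_parameter("`var_e` must be > 0")
  sqrt((nc * var_u1 + var_e) / (nc * N))
}

#' Standard error of the condition effect assumed by the naive t test
#'
#' The conventional analysis of individual observations prices the effect's
#' uncertainty as \deqn{SE_{\beta_1} = \sqrt{\sigma^2_e / (nc\,N)},} i.e. it
#' omits the slope-variance term of [se_gamma10()]. `var_e` here is a
#' composite of everything the naive model leaves unexplained (residual,
#' intercept and slope variance). The ratio of the two SEs quantifies how
#' much the naive analysis underestimates its uncertainty; it grows with
#' both `nc` and the slope variance.
#'
#' @inheritParams se_gamma10
#' @return The naive standard error.
#' @export
se_beta1_naive <- function(nc, N, var_e) {
  nc <- check_count(nc, "nc"); N <- check_count(N, "N")
  var_e <- check_scalar(var_e, "var_e")
  if (var_e <= 0) np_invalid_parameter("`var_e` must be > 0")
  sqrt(var_e / (nc * N))
}

#' Analytic power of multilevel analysis in design B
#'
#' Two-sided normal-approximation power for detecting the overall effect at
#' noncentrality \eqn{\lambda = d\,\sigma_e / SE_{\gamma_{10}}}:
#' \deqn{power = \Phi(\lambda - z_{1-\alpha/2}) + \Phi(-\lambda - z_{1-\alpha/2}).}
#' Power is monotone in `N` and `d` and, when `var_u1 > 0`, plateaus below 1
#' as `nc` grows: observations per cluster sharpen each cluster's effect
#' estimate, but only more clusters sharpen the overall effect. The
#' intercept variance (ICC) does not enter. Large-sample approximation; at
#' small `N` the Monte-Carlo layer is the authority.
#'
#' @inheritParams se_gamma10
#' @param d Standardized effect size.
#' @param alpha Two-sided significance level in `(0, 1)`.
#' @return A one-row data frame of class `power_point` with columns
#'   `n_clusters`, `n_per_condition`, `d`, `var_u1`, `var_e`, `alpha`,
#'   `power`.
#' @examples
#' analytic_power_design_b(d = 0.5, nc = 5, N = 20, var_u1 = 0.05,
#'                         var_e = 1, alpha = 0.05)
#' @export
analytic_power_design_b <- function(d, nc, N, var_u1, var_e, alpha) {
  d <- check_scalar(d, "d")
  alpha <- check_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) np_invalid_parameter("`alpha` must lie in (0, 1)")
  se <- se_gamma10(nc, N, var_u1, var_e)
  lambda <- d * sqrt(var_e) / se
  zc <- stats::qnorm(1 - alpha / 2)
  pow <- stats::pnorm(lambda - zc) + stats::pnorm(-lambda - zc)
  structure(
    data.frame(n_clusters = N, n_per_condition = nc, d = d, var_u1 = var_u1,
               var_e = var_e, alpha = alpha, power = pow),
    class = c("power_point", "data.frame")
  )
}

#' Asymptotic type-I error of the naive t test under slope variation
#'
#' Predicts the false positive rate of the pooled t test on individual
#' observations when the overall effect is null but the experimental effect
#' varies over clusters, for the dummy-coded balanced design. The true
#' sampling SD of the mean-difference estimator is
#' \deqn{sd_{true} = \sqrt{\sigma^2_{u1}/N + 2\sigma^2_e/(nc\,N)}}
#' (intercepts cancel between the two conditions within clusters), while the
#' naive pooled SE converges to
#' \deqn{se_{naive} = \sqrt{2(\sigma^2_e + \sigma^2_{u0} + \sigma^2_{u1}/2)/(nc\,N)},}
#' because intercept and slope variance inflate the pooled within-group
#' variance. The rejection rate is
#' \deqn{2\,(1 - \Phi(z_{1-\alpha/2}\; se_{naive}/sd_{true})).}
#' Sampling noise in the naive variance estimate is ignored (its expectation
#' is used), an approximation that is excellent at the `nc N` sizes of
#' interest and validated against simulation.
#'
#' Intercept variance appears only in `se_naive`, so more intercept variance
#' *lowers* this inflation for the t test — and plays no role at all for the
#' misspecified random-intercept multilevel model, whose inflation therefore
#' matches this formula at `var_u0 = 0` for any actual ICC.
#'
#' @inheritParams se_gamma10
#' @param var_u0 Intercept variance, `>= 0`.
#' @param alpha Nominal two-sided level in `(0, 1)`.
#' @return The predicted type-I error rate, in `(0, 1)`.
#' @examples
#' analytic_type1_naive_ttest(nc = 105, N = 50, var_u0 = 0, var_u1 = 0.025,
#'                            var_e = 1, alpha = 0.05)  # ~0.195
#' @export
analytic_type1_naive_ttest <- function(nc, N, var_u0, var_u1, var_e, alpha) {
  nc <- check_count(nc, "nc"); N <- check_count(N, "N")
  var_u0 <- check_scalar(var_u0, "var_u0")
  var_u1 <- check_scalar(var_u1, "var_u1")
  var_e <- check_scalar(var_e, "var_e")
  alpha <- check_scalar(alpha, "alpha")
  if (var_u0 < 0 || var_u1 < 0) np_invalid_parameter("variances must be >= 0")
  if (var_e <= 0) np_invalid_parameter("`var_e` must be > 0")
  if (alpha <= 0 || alpha >= 1) np_invalid_parameter("`alpha` must lie in (0, 1)")
  sd_true <- sqrt(var_u1 / N + 2 * var_e / (nc * N))
  se_naive <- sqrt(2 * (var_e + var_u0 + var_u1 / 2) / (nc * N))
  2 * (1 - stats::pnorm(stats::qnorm(1 - alpha / 2) * se_naive / sd_true))
}

#' Analytic power grid over cluster and observation allocations
#'
#' Evaluates [analytic_power_design_b()] on a cross of settings, the standard
#' planning sweep: vary the number of clusters at fixed `nc`, and vary `nc`
#' at a fixed number of clusters, for several effect sizes and slope
#' variances.
#'
#' @param d Vector of effect sizes.
#' @param nc Vector of observations per condition per cluster.
#' @param N Vector of numbers of clusters.
#' @param var_u1 Vector of slope variances.
#' @param var_e Residual variance.
#' @param alpha Significance level.
#' @return A data frame with one `power_point` row per combination.
#' @export
power_grid <- function(d = c(0.2, 0.5, 0.8), nc = 5, N = 10,
                       var_u1 = c(0, 0.05, 0.15), var_e = 1, alpha = 0.05) {
  grid <- expand.grid(d = d, nc = nc, N = N, var_u1 = var_u1,
                      KEEP.OUT.ATTRS = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    analytic_power_design_b(grid$d[i], grid$nc[i], grid$N[i], grid$var_u1[i],
                            var_e, alpha)))
  rownames(out) <- NULL
  out
}
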