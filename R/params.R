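#' Structural layout of a two-condition nested study
#'
#' A design spec fixes the shape of a study without saying anything about the
#' data-generating parameters. Two layouts are supported. In design A the
#' experimental condition is a cluster-level variable: every observation in a
#' cluster shares one condition (e.g. wild-type vs knock-out animals, with
#' several measurements per animal). In design B both conditions occur inside
#' every cluster: condition is an observation-level variable (e.g. treated and
#' untreated cells from the same animal).
#'
#' @param design `"A"` or `"B"`.
#' @param n_clusters Number of clusters `N` (at least 2; even for design A so
#'   the two condition groups have equal size).
#' @param n_per_condition For design B, observations per condition per cluster
#'   (`nc`); for design A, observations per cluster. At least 2.
#' @return An object of class `design_spec`.
#' @examples
#' design_spec("B", n_clusters = 10, n_per_condition = 5)
#' @export
design_spec <- function(design = c("B", "A"), n_clusters, n_per_condition) {
  design <- match.arg(toupper(design), c("B", "A"))
  n_clusters <- check_count(n_clusters, "n_clusters", min = 2L)
  n_per_condition <- check_count(n_per_condition, "n_per_condition", min = 2L)
  if (design == "A" && n_clusters %% 2L != 0L)
    np_usage_error("design A requires an even `n_clusters` (clusters are split half/half over conditions)")
  structure(
    list(design = design, n_clusters = n_clusters,
         n_per_condition = n_per_condition, n_conditions = 2L),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> design %s: N = %d clusters, nc = %d obs per condition per cluster\n",
              x$design, x$n_clusters, x$n_per_condition))
  invisible(x)
}

#' Generative parameters of the two-level model
#'
#' Collects the fixed effects and variance components of the model
#' \deqn{Y_{ij} = \gamma_{00} + u_{0j} + (\gamma_{10} + u_{1j}) X_{ij} + e_{ij}}
#' with \eqn{e_{ij} \sim N(0, \sigma^2_e)} and \eqn{(u_{0j}, u_{1j})} bivariate
#' normal with variances \eqn{\sigma^2_{u0}}, \eqn{\sigma^2_{u1}} and
#' covariance \eqn{\sigma^2_{u0,u1}}. Derived quantities are attached:
#' the intracluster correlation `icc` and the standardized effect size
#' `effect_size_d` \eqn{= \gamma_{10}/\sigma_e}.
#'
#' For design A data the same container is used with `var_u1 = 0`; `gamma10`
#' then plays the role of the cluster-level condition effect.
#'
#' @param gamma00 Overall intercept (mean of the control condition).
#' @param gamma10 Overall experimental effect.
#' @param var_e Residual (within-cluster) variance, `> 0`.
#' @param var_u0 Intercept variance across clusters, `>= 0`.
#' @param var_u1 Slope (experimental-effect) variance across clusters, `>= 0`.
#' @param cov_u0u1 Covariance between random intercept and random slope. The
#'   implied 2x2 covariance matrix must be positive semi-definite.
#' @return An object of class `population_params` with fields `gamma00`,
#'   `gamma10`, `var_e`, `var_u0`, `var_u1`, `cov_u0u1`, `icc`,
#'   `effect_size_d`.
#' @seealso [resolve_params()] to build this object from `(d, ICC)` settings.
#' @examples
#' population_params(gamma10 = 0.5, var_u0 = 1, var_u1 = 0.05)
#' @export
population_params <- function(gamma00 = 0, gamma10 = 0, var_e = 1,
                              var_u0 = 0, var_u1 = 0, cov_u0u1 = 0) {
  gamma00 <- check_scalar(gamma00, "gamma00")
  gamma10 <- check_scalar(gamma10, "gamma10")
  var_e <- check_scalar(var_e, "var_e")
  var_u0 <- check_scalar(var_u0, "var_u0")
  var_u1 <- check_scalar(var_u1, "var_u1")
  cov_u0u1 <- check_scalar(cov_u0u1, "cov_u0u1")
  # var_e = 0 is tolerated for degenerate noiseless data; derived icc and d
  # are then taken as limits (d undefined -> NA).
  if (var_e < 0) np_invalid_parameter("`var_e` must be >= 0")
  if (var_u0 < 0) np_invalid_parameter("`var_u0` must be >= 0")
  if (var_u1 < 0) np_invalid_parameter("`var_u1` must be >= 0")
  # PSD of [[var_u0, cov],[cov, var_u1]]; tiny tolerance for round-trip noise
  if (cov_u0u1^2 > var_u0 * var_u1 * (1 + 1e-12) + 1e-15)
    np_invalid_parameter(sprintf(
      "random-effects covariance matrix is not positive semi-definite: |cov_u0u1| = %g > sqrt(var_u0 * var_u1) = %g",
      abs(cov_u0u1), sqrt(var_u0 * var_u1)))
  structure(
    list(gamma00 = gamma00, gamma10 = gamma10, var_e = var_e,
         var_u0 = var_u0, var_u1 = var_u1, cov_u0u1 = cov_u0u1,
         icc = if (var_e > 0) icc(var_u0, var_e)
               else if (var_u0 > 0) 1 else 0,
         effect_size_d = if (var_e > 0) gamma10 / sqrt(var_e) else NA_real_),
    class = "population_params"
  )
}

#' @export
print.population_params <- function(x, ...) {
  cat("<population_params>\n")
  cat(sprintf("  fixed:    gamma00 = %g, gamma10 = %g  (d = %g)\n",
              x$gamma00, x$gamma10, x$effect_size_d))
  cat(sprintf("  variance: var_e = %g, var_u0 = %g (ICC = %g), var_u1 = %g, cov_u0u1 = %g\n",
              x$var_e, x$var_u0, x$icc, x$var_u1, x$cov_u0u1))
  invisible(x)
}

#' Intracluster correlation
#'
#' The ICC is the between-cluster (intercept) variance divided by the total
#' variance, \eqn{\sigma^2_{u0} / (\sigma^2_{u0} + \sigma^2_e)}. It ranges
#' from 0 (no dependency: observations in a cluster are no more alike than
#' observations across clusters) towards 1 (complete dependency).
#'
#' @param var_u0 Between-cluster variance, `>= 0`.
#' @param var_e Residual within-cluster variance, `> 0`.
#' @return The ICC, a number in `[0, 1)`.
#' @examples
#' icc(1, 1)  # 0.5
#' @export
icc <- function(var_u0, var_e) {
  var_u0 <- check_scalar(var_u0, "var_u0")
  var_e <- check_scalar(var_e, "var_e")
  if (var_u0 < 0) np_invalid_parameter("`var_u0` must be >= 0")
  if (var_e <= 0) np_invalid_parameter("`var_e` must be > 0")
  var_u0 / (var_u0 + var_e)
}

#' Map user-facing settings (d, ICC) onto generative parameters
#'
#' Simulation studies in this area are parameterised by the standardized
#' effect size `d` and the intracluster correlation rather than by raw
#' variance components. With the residual variance fixed (default
#' \eqn{\sigma^2_e = 1}) these settings invert uniquely:
#' \eqn{\sigma^2_{u0} = ICC/(1-ICC)\,\sigma^2_e} and
#' \eqn{\gamma_{10} = d\,\sigma_e}.
#'
#' @param d Standardized effect size (condition mean difference over
#'   \eqn{\sigma_e}).
#' @param icc Intracluster correlation in `[0, 1)`. `ICC = 1` (complete
#'   dependency) is excluded: it has no finite intercept variance under a
#'   fixed residual variance.
#' @param var_u1 Slope variance, `>= 0`.
#' @param cov_u0u1 Intercept-slope covariance (default 0, as in the standard
#'   simulation settings).
#' @param var_e Residual variance, `> 0` (default 1).
#' @param gamma00 Overall intercept (default 0).
#' @return A [population_params()] object.
#' @examples
#' resolve_params(d = 0.2, icc = 0.5)          # var_u0 = 1, gamma10 = 0.2
#' resolve_params(d = 0, icc = 0, var_u1 = 0.025)  # a null-effect cell
#' @export
resolve_params <- function(d, icc, var_u1 = 0, cov_u0u1 = 0, var_e = 1,
                           gamma00 = 0) {
  d <- check_scalar(d, "d")
  icc_v <- check_scalar(icc, "icc")
  var_e <- check_scalar(var_e, "var_e")
  if (var_e <= 0) np_invalid_parameter("`var_e` must be > 0")
  if (icc_v < 0 || icc_v >= 1)
    np_invalid_parameter("`icc` must lie in [0, 1); ICC = 1 (complete dependency) is not representable")
  population_params(
    gamma00 = gamma00,
    gamma10 = d * sqrt(var_e),
    var_e = var_e,
    var_u0 = icc_v / (1 - icc_v) * var_e,
    var_u1 = var_u1,
    cov_u0u1 = cov_u0u1
  )
}

#' Dispersion of cluster-specific experimental effects
#'
#' With slope variance \eqn{\sigma^2_{u1}}, the cluster-specific effects are
#' \eqn{N(d, \sigma^2_{u1})}; this returns their standard deviation and the
#' central `coverage` interval \eqn{d \mp z_{(1+coverage)/2}\,\sigma_{u1}}.
#' Useful to translate an abstract slope variance into the range of effects
#' one would actually see across clusters: e.g. `d = 0.5` with a "small"
#' slope variance of 0.05 already spans effects from near 0 to near 1.
#'
#' @param d Overall effect size.
#' @param var_u1 Slope variance, `>= 0`.
#' @param coverage Central coverage probability in `(0, 1)`, default 0.95.
#' @return A list with `low`, `high` and `sd`.
#' @examples
#' effect_dispersion_interval(0.5, 0.05)
#' @export
effect_dispersion_interval <- function(d, var_u1, coverage = 0.95) {
  d <- check_scalar(d, "d")
  var_u1 <- check_scalar(var_u1, "var_u1")
  coverage <- check_scalar(coverage, "coverage")
  if (var_u1 < 0) np_invalid_parameter("`var_u1` must be >= 0")
  if (coverage <= 0 || coverage >= 1)
    np_invalid_parameter("`coverage` must lie strictly between 0 and 1")
  sd_u1 <- sqrt(var_u1)
  z <- stats::qnorm((1 + coverage) / 2)
  list(low = d - z * sd_u1, high = d + z * sd_u1, sd = sd_u1)
}
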