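new_nested_data <- function(df, design, balanced) {
  structure(df, design = design, balanced = balanced,
            class = c("nested_data", "data.frame"))
}

#' @export
print.nested_data <- function(x, ...) {
  cat(sprintf("<nested_data> design %s, %d rows, %d clusters%s%s\n",
              attr(x, "design"), nrow(x), length(unique(x$cluster)),
              if (isTRUE(attr(x, "balanced"))) ", balanced" else "",
              if ("w" %in% names(x)) ", with cluster covariate w" else ""))
  NextMethod()
  invisible(x)
}

# Lower-triangular factor of [[v0, c],[c, v1]], valid for singular matrices.
chol2_lower <- function(v0, v1, cv) {
  a <- sqrt(v0)
  b <- if (a > 0) cv / a else 0
  c <- sqrt(max(v1 - b^2, 0))
  c(a = a, b = b, c = c)
}

draw_random_effects <- function(n, params) {
  f <- chol2_lower(params$var_u0, params$var_u1, params$cov_u0u1)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  list(u0 = f["a"] * z1, u1 = f["b"] * z1 + f["c"] * z2)
}

#' Simulate design-B data (both conditions within every cluster)
#'
#' Generates a balanced long-format dataset under the random-intercept /
#' random-slope model: for cluster `j`, \eqn{(u_{0j}, u_{1j})} is drawn from
#' a bivariate normal with the covariance in `params`, and each observation is
#' \deqn{Y_{ij} = \gamma_{00} + u_{0j} + (\gamma_{10} + u_{1j}) X_{ij} + e_{ij},}
#' with condition dummy-coded `X = 0` (control) / `1` (experimental) and
#' exactly `nc` observations per condition per cluster. The same seed always
#' reproduces the same dataset.
#'
#' @param spec A [design_spec()] with `design == "B"`.
#' @param params A [population_params()] object.
#' @param seed Integer seed.
#' @return A `nested_data` data frame with columns `cluster`, `condition`,
#'   `y`, ordered by cluster then condition.
#' @examples
#' d <- generate_design_b(design_spec("B", 10, 5),
#'                        resolve_params(d = 0.5, icc = 0.25, var_u1 = 0.05),
#'                        seed = 42)
#' head(d)
#' @export
generate_design_b <- function(spec, params, seed) {
  stopifnot(inherits(spec, "design_spec"), inherits(params, "population_params"))
  if (spec$design != "B")
    np_usage_error("generate_design_b() requires a design-B spec; see generate_design_a()")
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  N <- spec$n_clusters; nc <- spec$n_per_condition
  u <- draw_random_effects(N, params)
  cl <- rep.int(seq_len(N), rep.int(2L * nc, N))
  x <- rep.int(rep.int(c(0L, 1L), c(nc, nc)), N)
  y <- params$gamma00 + u$u0[cl] + (params$gamma10 + u$u1[cl]) * x +
    stats::rnorm(2L * nc * N, 0, sqrt(params$var_e))
  new_nested_data(data.frame(cluster = cl, condition = x, y = y),
                  design = "B", balanced = TRUE)
}

#' Simulate design-A data (one condition per cluster)
#'
#' Generates data where condition is a cluster-level variable `Z_j`: the first
#' half of the clusters is assigned the control condition (`Z = 0`), the
#' second half the experimental condition (`Z = 1`), and
#' \deqn{Y_{ij} = \gamma_{00} + \gamma_{10} Z_j + u_{0j} + e_{ij}.}
#' The slope variance must be zero: with only one condition per cluster a
#' cluster-specific experimental effect is not identifiable.
#'
#' @inheritParams generate_design_b
#' @param spec A [design_spec()] with `design == "A"` and even `n_clusters`.
#' @return A `nested_data` data frame with columns `cluster`, `condition`, `y`.
#' @export
generate_design_a <- function(spec, params, seed) {
  stopifnot(inherits(spec, "design_spec"), inherits(params, "population_params"))
  if (spec$design != "A")
    np_usage_error("generate_design_a() requires a design-A spec")
  if (params$var_u1 != 0 || params$cov_u0u1 != 0)
    np_usage_error("design A has one condition per cluster: var_u1 and cov_u0u1 must be 0")
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  N <- spec$n_clusters; nc <- spec$n_per_condition
  u0 <- stats::rnorm(N, 0, sqrt(params$var_u0))
  z_cl <- rep.int(c(0L, 1L), c(N %/% 2L, N - N %/% 2L))
  cl <- rep.int(seq_len(N), rep.int(nc, N))
  z <- z_cl[cl]
  y <- params$gamma00 + params$gamma10 * z + u0[cl] +
    stats::rnorm(nc * N, 0, sqrt(params$var_e))
  new_nested_data(data.frame(cluster = cl, condition = z, y = y),
                  design = "A", balanced = TRUE)
}

#' Simulate design-B data with a cluster-level covariate
#'
#' Emulates a measurable cluster-level source of the slope variation: a
#' standard-normal covariate `w_j` enters the cluster-specific effect as
#' \deqn{\beta_{1j} = \gamma_{10} + b\,w_j + u_{1j}}
#' with \eqn{b = \sqrt{f\,\sigma^2_{u1}}} and residual slope variance
#' \eqn{\mathrm{var}(u_{1j}) = (1-f)\,\sigma^2_{u1}}, where
#' `f = explained_fraction`. The marginal slope variance across clusters is
#' therefore `var_u1` regardless of `f`; the covariate just relabels part of
#' it as explainable. Fitting [lmm_covariate()] to such data recovers the
#' reduced residual slope variance and hence gains power.
#'
#' @inheritParams generate_design_b
#' @param explained_fraction Fraction of the slope variance carried by the
#'   covariate, in `[0, 1)`.
#' @return A `nested_data` data frame with columns `cluster`, `condition`,
#'   `y`, `w` (`w` constant within cluster).
#' @export
generate_with_cluster_covariate <- function(spec, params, explained_fraction,
                                            seed) {
  stopifnot(inherits(spec, "design_spec"), inherits(params, "population_params"))
  if (spec$design != "B")
    np_usage_error("generate_with_cluster_covariate() requires a design-B spec")
  if (params$var_u1 <= 0)
    np_usage_error("a cluster covariate for the slope requires var_u1 > 0")
  ef <- check_scalar(explained_fraction, "explained_fraction")
  if (ef < 0 || ef >= 1)
    np_invalid_parameter("`explained_fraction` must lie in [0, 1)")
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  N <- spec$n_clusters; nc <- spec$n_per_condition
  b <- sqrt(ef * params$var_u1)
  resid_params <- population_params(
    gamma00 = params$gamma00, gamma10 = params$gamma10, var_e = params$var_e,
    var_u0 = params$var_u0, var_u1 = (1 - ef) * params$var_u1,
    cov_u0u1 = if (ef > 0) 0 else params$cov_u0u1)
  u <- draw_random_effects(N, resid_params)
  w <- stats::rnorm(N)
  cl <- rep.int(seq_len(N), rep.int(2L * nc, N))
  x <- rep.int(rep.int(c(0L, 1L), c(nc, nc)), N)
  slope <- params$gamma10 + b * w + u$u1
  y <- params$gamma00 + u$u0[cl] + slope[cl] * x +
    stats::rnorm(2L * nc * N, 0, sqrt(params$var_e))
  new_nested_data(data.frame(cluster = cl, condition = x, y = y, w = w[cl]),
                  design = "B", balanced = TRUE)
}

#' Assemble a nested dataset from a long-format data frame
#'
#' Validates a user-supplied table against the structural invariants: integer
#' cluster ids, condition codes in `{0, 1}`, design B means every cluster has
#' both conditions, design A means condition is constant within cluster, and
#' a covariate `w` (if present) is constant within cluster. The design is
#' inferred from the data when not given.
#'
#' @param df Data frame with columns `cluster`, `condition`, `y` and
#'   optionally `w`.
#' @param design `"A"`, `"B"`, or `NULL` to infer.
#' @return A `nested_data` object; attribute `balanced` records whether all
#'   (cluster, condition) cell sizes are equal.
#' @export
as_nested_data <- function(df, design = NULL) {
  df <- as.data.frame(df)
  need <- c("cluster", "condition", "y")
  if (!all(need %in% names(df)))
    np_validation_error(sprintf("dataset must have columns %s (optionally w)",
                                paste(need, collapse = ", ")))
  if (!all(df$condition %in% c(0, 1)))
    np_validation_error("column `condition` must contain only 0 (control) and 1 (experimental)")
  if (nrow(df) == 0L) np_validation_error("dataset has no rows")
  df$cluster <- as.integer(factor(df$cluster))
  df$condition <- as.integer(df$condition)
  both <- tapply(df$condition, df$cluster, function(v) length(unique(v)))
  inferred <- if (all(both == 2L)) "B" else if (all(both == 1L)) "A" else NA
  if (is.null(design)) {
    if (is.na(inferred))
      np_validation_error("cannot infer design: some clusters have both conditions, others only one")
    design <- inferred
  } else {
    design <- match.arg(toupper(design), c("A", "B"))
    if (design == "B" && !all(both == 2L)) {
      miss <- names(both)[both != 2L]
      np_validation_error(sprintf("design B requires both conditions in every cluster; cluster(s) %s lack one",
                                  paste(miss, collapse = ", ")))
    }
    if (design == "A" && !all(both == 1L))
      np_validation_error("design A requires a single condition per cluster")
  }
  if ("w" %in% names(df)) {
    wvar <- tapply(df$w, df$cluster, function(v) length(unique(v)))
    if (any(wvar != 1L))
      np_validation_error(sprintf("covariate `w` varies within cluster(s) %s",
                                  paste(names(wvar)[wvar != 1L], collapse = ", ")))
  }
  counts <- table(df$cluster, df$condition)
  balanced <- length(unique(counts[counts > 0])) == 1L
  new_nested_data(df[c(intersect(c("cluster", "condition", "y", "w"), names(df)))],
                  design = design, balanced = balanced)
}
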