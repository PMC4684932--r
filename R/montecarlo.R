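# Per-replicate child seeds: replicate r of an experiment depends only on
# (master_seed, r), so runs are reproducible and subsets re-usable.
replicate_seeds <- function(master_seed, n) {
  master_seed <- check_count(master_seed, "master_seed", min = 0L)
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

wilson_ci <- function(k, n, level = 0.95) {
  if (n == 0) return(c(low = NA_real_, high = NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}

#' Monte-Carlo rejection rates for one parameter cell
#'
#' Generates `n_reps` datasets from one `(params, spec)` cell and fits every
#' requested estimator on each dataset (common random numbers: all methods see
#' the same replicates, which sharpens between-method comparisons without
#' biasing marginal rates). A rejection is `p_value < alpha`. With a null
#' overall effect (`d = 0`) the rate is the empirical type-I error; with
#' `d > 0` it is the empirical power. Replicates on which a mixed-model
#' optimiser fails are excluded from that method's denominator and counted in
#' `n_nonconverged`, with a warning if more than 2\% drop.
#'
#' @param spec A [design_spec()].
#' @param params A [population_params()].
#' @param methods Character vector of estimator names (see
#'   `ESTIMATOR_METHODS`).
#' @param n_reps Number of Monte-Carlo replicates.
#' @param alpha Significance level.
#' @param master_seed Integer master seed; replicate `r` depends only on
#'   `(master_seed, r)`.
#' @return A `rejection_rate_table` data frame: one row per method with
#'   `rejections`, `reps_used`, `rate`, `ci_low`, `ci_high` (95\% Wilson) and
#'   `n_nonconverged`.
#' @examples
#' rejection_rate(design_spec("B", 10, 5), resolve_params(d = 0, icc = 0),
#'                methods = "ttest_individual", n_reps = 200, master_seed = 1)
#' @export
rejection_rate <- function(spec, params, methods, n_reps, alpha = 0.05,
                           master_seed = 1) {
  stopifnot(inherits(spec, "design_spec"), inherits(params, "population_params"))
  n_reps <- check_count(n_reps, "n_reps")
  bad <- setdiff(methods, ESTIMATOR_METHODS)
  if (length(bad))
    np_usage_error(sprintf("unknown method(s): %s; valid: %s",
                           paste(bad, collapse = ", "),
                           paste(ESTIMATOR_METHODS, collapse = ", ")))
  if (spec$design == "A" &&
      any(methods %in% c("paired_ttest_means", "lmm_intercept_slope",
                         "fixed_effects_dummies", "lmm_covariate")))
    np_usage_error("design A supports only ttest_individual, ttest_cluster_means and lmm_intercept")
  seeds <- replicate_seeds(master_seed, n_reps)
  rej <- structure(integer(length(methods)), names = methods)
  used <- structure(integer(length(methods)), names = methods)
  nonconv <- structure(integer(length(methods)), names = methods)
  gen <- if (spec$design == "B") generate_design_b else generate_design_a
  for (r in seq_len(n_reps)) {
    dat <- gen(spec, params, seeds[r])
    for (m in methods) {
      fr <- fit_method(m, dat, alpha)
      if (!fr$converged) {
        nonconv[m] <- nonconv[m] + 1L
      } else {
        used[m] <- used[m] + 1L
        rej[m] <- rej[m] + as.integer(fr$p_value < alpha)
      }
    }
  }
  dropped <- nonconv / n_reps > 0.02
  if (any(dropped))
    warning(sprintf("more than 2%% of replicates dropped for non-convergence: %s",
                    paste(sprintf("%s (%d/%d)", methods[dropped],
                                  nonconv[dropped], n_reps), collapse = ", ")))
  ci <- t(vapply(methods, function(m) wilson_ci(rej[m], used[m]), numeric(2)))
  structure(
    data.frame(method = methods, rejections = unname(rej),
               reps_used = unname(used),
               rate = unname(ifelse(used > 0, rej / used, NA_real_)),
               ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
               n_nonconverged = unname(nonconv), row.names = NULL),
    class = c("rejection_rate_table", "data.frame")
  )
}

# Default parameter grids of the four simulation studies. Studies 1a/1b probe
# power (d > 0, no slope variance); studies 2a/2b probe the false positive
# rate (d = 0, slope variance present); the a/b split is absent vs present
# intercept variance.
study_grid_defaults <- function(study_id) {
  switch(study_id,
    "1a" = expand.grid(d = c(0.20, 0.50), icc = 0, var_u1 = 0,
                       N = c(10L, 30L), nc = seq(5L, 50L, 10L)),
    "1b" = expand.grid(d = c(0.20, 0.50), icc = c(0.25, 0.50), var_u1 = 0,
                       N = c(10L, 30L), nc = seq(5L, 50L, 10L)),
    "2a" = expand.grid(d = 0, icc = 0, var_u1 = c(0.025, 0.05, 0.10, 0.15),
                       N = 50L, nc = seq(5L, 105L, 10L)),
    "2b" = expand.grid(d = 0, icc = 0.50, var_u1 = c(0.025, 0.05, 0.10, 0.15),
                       N = 50L, nc = seq(5L, 105L, 10L)),
    np_usage_error(sprintf("unknown study id '%s' (use 1a, 1b, 2a, 2b or custom)",
                           study_id))
  )
}

#' Replicate a whole simulation study
#'
#' Expands a study's parameter grid, runs [rejection_rate()] on every cell,
#' and stacks the results. The four canonical studies are:
#' \describe{
#'   \item{1a}{power; no intercept or slope variance (`d` in 0.2/0.5,
#'     `N` in 10/30, `nc` 5..50).}
#'   \item{1b}{power; intercept variance present (ICC 0.25/0.50), no slope
#'     variance.}
#'   \item{2a}{false positive rate; slope variance 0.025..0.15, no intercept
#'     variance (`d = 0`, `N = 50`, `nc` 5..105).}
#'   \item{2b}{as 2a with ICC = 0.50.}
#' }
#' Default `nc` grids step by 10 to keep curves tractable; pass `nc_grid`
#' for finer sweeps. Use `study_id = "custom"` with a `cells` override to run
#' an arbitrary grid.
#'
#' @param study_id `"1a"`, `"1b"`, `"2a"`, `"2b"` or `"custom"`.
#' @param n_reps Replicates per cell (the canonical studies use 10,000;
#'   scale down for mixed-model-heavy grids).
#' @param master_seed Master seed; each cell gets an independent child seed.
#' @param nc_grid Optional replacement for the default `nc` values.
#' @param methods Estimators to fit; default the four canonical analyses.
#' @param alpha Significance level.
#' @param cells Optional data frame with columns `d, icc, var_u1, N, nc`
#'   (required when `study_id = "custom"`).
#' @return A `rejection_rate_table` data frame with the cell columns
#'   `study, N, nc, d, icc, var_u1` prepended.
#' @examples
#' \donttest{
#' replicate_study("2a", n_reps = 200, master_seed = 1,
#'                 nc_grid = c(5, 105), methods = "ttest_individual")
#' }
#' @export
replicate_study <- function(study_id, n_reps = 10000, master_seed = 1,
                            nc_grid = NULL,
                            methods = c("ttest_individual",
                                        "paired_ttest_means",
                                        "lmm_intercept",
                                        "lmm_intercept_slope"),
                            alpha = 0.05, cells = NULL) {
  if (identical(study_id, "custom")) {
    if (is.null(cells)) np_usage_error("study 'custom' requires a `cells` data frame")
  } else {
    cells <- study_grid_defaults(study_id)
  }
  cells <- as.data.frame(cells)
  need <- c("d", "icc", "var_u1", "N", "nc")
  if (!all(need %in% names(cells)))
    np_usage_error(sprintf("`cells` must have columns %s", paste(need, collapse = ", ")))
  if (!is.null(nc_grid)) {
    base <- unique(cells[setdiff(names(cells), "nc")])
    cells <- merge(base, data.frame(nc = as.integer(nc_grid)))
  }
  if (nrow(cells) == 0L) np_usage_error("empty study grid")
  cell_seeds <- replicate_seeds(master_seed, nrow(cells))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    params <- resolve_params(d = ci$d, icc = ci$icc, var_u1 = ci$var_u1)
    spec <- design_spec("B", n_clusters = ci$N, n_per_condition = ci$nc)
    tab <- rejection_rate(spec, params, methods, n_reps, alpha,
                          master_seed = cell_seeds[i])
    out[[i]] <- cbind(data.frame(study = study_id, N = ci$N, nc = ci$nc,
                                 d = ci$d, icc = ci$icc, var_u1 = ci$var_u1),
                      tab)
  }
  res <- do.call(rbind, out)
  class(res) <- c("rejection_rate_table", "data.frame")
  res
}

#' Per-cell rejection-rate difference between two methods
#'
#' Computes `rate(method_a) - rate(method_b)` for every parameter cell of a
#' [replicate_study()] table, with a propagated 95\% normal-approximation CI.
#' The CI treats the two rates as independent, which is conservative here:
#' the study design uses common random numbers across methods.
#'
#' @param table A `rejection_rate_table` with cell columns.
#' @param method_a,method_b Method names present in `table`.
#' @return A data frame with the cell columns, `diff`, `ci_low`, `ci_high`.
#' @export
power_difference <- function(table, method_a, method_b) {
  for (m in c(method_a, method_b))
    if (!m %in% table$method)
      np_usage_error(sprintf("method '%s' not present in table", m))
  keys <- intersect(c("study", "N", "nc", "d", "icc", "var_u1"), names(table))
  if (!length(keys)) {  # single-cell table straight from rejection_rate()
    table$cell <- 1L
    keys <- "cell"
  }
  a <- table[table$method == method_a, c(keys, "rate", "reps_used")]
  b <- table[table$method == method_b, c(keys, "rate", "reps_used")]
  m <- merge(a, b, by = keys, suffixes = c("_a", "_b"))
  se <- sqrt(m$rate_a * (1 - m$rate_a) / m$reps_used_a +
             m$rate_b * (1 - m$rate_b) / m$reps_used_b)
  z <- stats::qnorm(0.975)
  cbind(m[keys],
        data.frame(diff = m$rate_a - m$rate_b,
                   ci_low = m$rate_a - m$rate_b - z * se,
                   ci_high = m$rate_a - m$rate_b + z * se))
}
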