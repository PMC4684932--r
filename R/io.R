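#' Write / read a nested dataset as CSV
#'
#' The single on-disk dataset format: RFC-4180 CSV, '.' decimal, header
#' exactly `cluster,condition,y` (plus `w` for a cluster covariate), one
#' observation per row in long format.
#'
#' @param data A `nested_data` object.
#' @param path File path.
#' @return `write_dataset_csv()` returns `path` invisibly;
#'   `read_dataset_csv()` returns a validated `nested_data` object.
#' @export
write_dataset_csv <- function(data, path) {
  data <- check_dataset(data)
  utils::write.table(as.data.frame(data), path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @param design Optional design override for `read_dataset_csv()`; by
#'   default inferred from the data.
#' @export
read_dataset_csv <- function(path, design = NULL) {
  if (!file.exists(path)) np_io_error(sprintf("no such file: %s", path))
  head_line <- readLines(path, n = 1L)
  if (!head_line %in% c("cluster,condition,y", "cluster,condition,y,w"))
    np_io_error(sprintf("%s: header must be exactly 'cluster,condition,y[,w]', got '%s'",
                        path, head_line))
  df <- tryCatch(
    utils::read.csv(path, colClasses = c(cluster = "integer",
                                         condition = "integer")),
    error = function(e) np_io_error(sprintf("%s: %s", path, conditionMessage(e))),
    warning = function(w) np_io_error(sprintf("%s: %s", path, conditionMessage(w))))
  bad <- which(!df$condition %in% c(0L, 1L))
  if (length(bad))
    np_io_error(sprintf("%s: row %d: condition must be 0 or 1", path, bad[1]))
  as_nested_data(df, design = design)
}

config_keys <- function() {
  list(
    parameter = c("design", "n_clusters", "n_per_condition", "d", "icc",
                  "var_u1", "cov_u0u1", "var_e", "gamma00", "alpha"),
    execution = c("reps", "seed", "workers", "out", "log_level", "method",
                  "study", "nc_grid", "explained_fraction")
  )
}

config_defaults <- function() {
  list(design = "B", var_u1 = 0, cov_u0u1 = 0, var_e = 1, gamma00 = 0,
       alpha = 0.05, reps = 10000, seed = 1, workers = 1, log_level = "info")
}

#' Load, validate and save run configurations
#'
#' Configurations are flat JSON key-value documents holding the parameter
#' section (`design, n_clusters, n_per_condition, d, icc, var_u1, cov_u0u1,
#' var_e, gamma00, alpha`) and the execution section (`reps, seed, workers,
#' out, log_level, method, study, nc_grid, explained_fraction`). Unknown keys
#' are rejected with the list of valid keys; omitted keys receive defaults
#' (`var_e = 1`, `alpha = 0.05`, `cov_u0u1 = 0`, ...). A loaded config
#' round-trips losslessly through [save_config()].
#'
#' @param path File path of a JSON config.
#' @return `load_config()` returns a validated named list of class
#'   `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) np_io_error(sprintf("no such config file: %s", path))
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    np_io_error(sprintf("cannot parse %s: %s", path,
                                        conditionMessage(e))))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  keys <- config_keys()
  valid <- c(keys$parameter, keys$execution)
  unknown <- setdiff(names(cfg), valid)
  if (length(unknown))
    np_validation_error(sprintf("unknown config key(s): %s\nvalid keys: %s",
                                paste(unknown, collapse = ", "),
                                paste(valid, collapse = ", ")))
  out <- utils::modifyList(config_defaults(), cfg)
  if (!is.null(out$icc) && (out$icc < 0 || out$icc >= 1))
    np_validation_error("config: `icc` must lie in [0, 1)")
  if (!is.null(out$alpha) && (out$alpha <= 0 || out$alpha >= 1))
    np_validation_error("config: `alpha` must lie in (0, 1)")
  if (!is.null(out$design)) {
    if (!toupper(out$design) %in% c("A", "B"))
      np_validation_error("config: `design` must be 'A' or 'B'")
    out$design <- toupper(out$design)
  }
  structure(out, class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config` list.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write canonical small fixture datasets
#'
#' Emits the small datasets the test suite (or a user exploring the package)
#' can rely on: noiseless design-A and design-B datasets, and one dataset per
#' simulation-study cell at `N = 10`, `nc = 5`, together with a JSON manifest
#' recording the generating parameters and seeds so each fixture can be
#' reproduced bit-for-bit.
#'
#' @param seed Master seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a named list.
#' @export
make_fixtures <- function(seed = 20150101, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- replicate_seeds(seed, 6L)
  cells <- list(
    noiseless_a = list(design = "A", d = 2, icc = 0, var_u1 = 0),
    noiseless_b = list(design = "B", d = 2, icc = 0, var_u1 = 0),
    study1a = list(design = "B", d = 0.20, icc = 0, var_u1 = 0),
    study1b = list(design = "B", d = 0.20, icc = 0.50, var_u1 = 0),
    study2a = list(design = "B", d = 0, icc = 0, var_u1 = 0.05),
    study2b = list(design = "B", d = 0, icc = 0.50, var_u1 = 0.05)
  )
  manifest <- list()
  for (i in seq_along(cells)) {
    nm <- names(cells)[i]; cell <- cells[[i]]
    if (grepl("noiseless", nm)) {  # degenerate: zero out all randomness
      params <- population_params(gamma00 = 1, gamma10 = cell$d,
                                  var_e = 0, var_u0 = 0, var_u1 = 0)
    } else {
      params <- resolve_params(d = cell$d, icc = cell$icc, var_u1 = cell$var_u1)
    }
    spec <- design_spec(cell$design, n_clusters = 10, n_per_condition = 5)
    dat <- if (cell$design == "B") generate_design_b(spec, params, seeds[i])
           else generate_design_a(spec, params, seeds[i])
    path <- file.path(dir, paste0(nm, ".csv"))
    write_dataset_csv(dat, path)
    manifest[[nm]] <- list(file = basename(path), design = cell$design,
                           n_clusters = 10, n_per_condition = 5,
                           seed = seeds[i],
                           params = params[c("gamma00", "gamma10", "var_e",
                                             "var_u0", "var_u1", "cov_u0u1")])
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
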