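# Shared fixtures built in code.

# A small balanced design-B dataset with known noise.
toy_b <- function(N = 6, nc = 4, d = 0.5, icc = 0.25, var_u1 = 0.05,
                  seed = 42) {
  generate_design_b(design_spec("B", N, nc),
                    resolve_params(d = d, icc = icc, var_u1 = var_u1),
                    seed = seed)
}

# Build a nested_data object directly from per-(cluster, condition) cell
# values: `cells` is a list of c(control_values, experimental_values).
data_from_cells <- function(cells0, cells1) {
  df <- do.call(rbind, lapply(seq_along(cells0), function(j) {
    rbind(data.frame(cluster = j, condition = 0L, y = cells0[[j]]),
          data.frame(cluster = j, condition = 1L, y = cells1[[j]]))
  }))
  as_nested_data(df, design = "B")
}

# Per-cluster condition-mean differences (independent of package estimators).
cluster_diffs <- function(data) {
  m0 <- tapply(data$y[data$condition == 0], data$cluster[data$condition == 0], mean)
  m1 <- tapply(data$y[data$condition == 1], data$cluster[data$condition == 1], mean)
  unname(m1 - m0)
}

# 3 binomial standard errors around a target rate.
binom_3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
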