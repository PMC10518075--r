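# Builders for small in-code fixtures shared across the test files.

# Writes a user-catalog CSV with a single `nr` x `nc` grid and returns its
# path; variable ids are V_<row>_<col>.
write_toy_catalog <- function(nr = 4, nc = 3, grid_name = "Toy grid",
                              path = tempfile(fileext = ".csv")) {
  rows <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  df <- data.frame(
    variable_id = sprintf("V_%d_%d", rows$r, rows$c),
    display_name = sprintf("Variable %d,%d", rows$r, rows$c),
    group = "Toy",
    grid = grid_name,
    row_label = sprintf("Row %d", rows$r),
    col_label = sprintf("Col %d", rows$c),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE)
  path
}

# Results covering the given variable ids, with deterministic estimates
# spanning both signs and a spread of P-values.
toy_results <- function(ids, seed = 42) {
  set.seed(seed)
  n <- length(ids)
  est <- round(rnorm(n, 0, 0.5), 6)
  p <- pmin(1, pmax(1e-50, 10^(-abs(rnorm(n, 5, 8)))))
  out <- data.frame(variable_id = ids, estimate = est, se = 0.1, p = p,
                    neglog10p = -log10(p), stringsAsFactors = FALSE)
  class(out) <- c("bubble_results", class(out))
  out
}

# A mapping-file keyspace {A -> x, B -> y, C -> z} written to disk.
write_toy_mapping <- function(map, path = tempfile(fileext = ".csv")) {
  write.csv(data.frame(external_id = names(map), variable_id = unname(map),
                       stringsAsFactors = FALSE),
            path, row.names = FALSE)
  path
}
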