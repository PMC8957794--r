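# fixture builders shared across test files

# two well-separated Gaussian clusters differing in the first n_signal
# features; remaining features are pure noise
make_separable <- function(n_per_class = 10, d = 5, n_signal = 1,
                           shift = 10, seed = 42) {
  with_seed(seed, {
    n <- 2 * n_per_class
    values <- matrix(stats::rnorm(n * d), n, d)
    values[(n_per_class + 1):n, seq_len(n_signal)] <-
      values[(n_per_class + 1):n, seq_len(n_signal)] + shift
    feature_matrix(values, rep(c("ctrl", "case"), each = n_per_class))
  })
}

# labels randomly permuted relative to the values
make_null_data <- function(n_per_class = 20, d = 10, seed = 1) {
  with_seed(seed, {
    n <- 2 * n_per_class
    values <- matrix(stats::rnorm(n * d), n, d)
    feature_matrix(values, sample(rep(c("a", "b"), each = n_per_class)))
  })
}

write_tsv_fixture <- function(lines, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}

# with_seed is internal; re-export for helpers
with_seed <- swarmFS:::with_seed
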