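# The simulation validation study (100 replicates, lags 0..15, both
# directions) backs several acceptance checks; it is computed once per test
# run and cached here.

.validation_cache <- new.env(parent = emptyenv())

validation_fixture <- function() {
  if (is.null(.validation_cache$run)) {
    .validation_cache$run <- validation_experiment(
      n_reps = 100, lags = 0:15, spec = ar_sim_spec(),
      policy = selection_policy(), k = 10,
      directions = c("xy", "yx"), surrogates = FALSE, seed = 20260929)
  }
  .validation_cache$run
}

# per-lag means and standard errors for one direction
lag_summary <- function(run, direction) {
  sub <- run$table[run$table$direction == direction, ]
  agg <- aggregate(value ~ lag, data = sub, FUN = function(v)
    c(mean = mean(v), sem = sd(v) / sqrt(length(v))))
  data.frame(lag = agg$lag, mean = agg$value[, "mean"],
             sem = agg$value[, "sem"])
}

# Bonferroni-adjusted p-value for a lag pair from pairwise.t.test output
pairwise_p <- function(mat, i, j) {
  a <- as.character(max(i, j)); b <- as.character(min(i, j))
  mat[a, b]
}
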