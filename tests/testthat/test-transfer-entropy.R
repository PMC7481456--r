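test_that("shift_align produces the documented design", {
  sim <- simulate_coupled_ar(ar_sim_spec(N = 300), seed = 1)
  pair <- bivariate_series(sim$x, sim$y)
  d0 <- shift_align(pair, lag = 0, L_max = 10)
  expect_equal(d0$rows, 290)
  d15 <- shift_align(pair, lag = 15, L_max = 10)
  expect_equal(d15$rows, 275)
  # the row whose target is y[n - 1] carries x[n - 1] as its delay-1 source
  d1 <- shift_align(pair, lag = 1, L_max = 10)
  n_idx <- (1 + 10 + 1):300
  expect_equal(d1$target, pair$y[n_idx - 1])
  expect_equal(d1$source_past[, 1], pair$x[n_idx - 1])
  expect_equal(d1$target_past[, 1], pair$y[n_idx - 2])
  expect_error(shift_align(pair, lag = 260, L_max = 10), "too short")
})

test_that("an empty source side yields exactly zero transfer", {
  sim <- simulate_coupled_ar(seed = 2)
  pair <- bivariate_series(sim$x, sim$y)
  emb <- manual_embedding(target_delays = c(1, 2))
  te <- transfer_entropy(pair, "xy", lag = 0, embedding = emb, seed = 5)
  expect_identical(te$value, 0)
  expect_identical(te$raw, 0)
})

test_that("TE equals the entropy combination of its four conditioning terms", {
  sim <- simulate_coupled_ar(seed = 6)
  pair <- bivariate_series(sim$x, sim$y)
  te <- transfer_entropy(pair, "xy", lag = 0, seed = 6,
                         clip_negative = FALSE)
  expect_gt(nrow(te$embedding$selected), 0)
  combo <- te$terms[["h_yz"]] + te$terms[["h_xz"]] -
    te$terms[["h_z"]] - te$terms[["h_joint"]]
  expect_equal(te$raw, combo, tolerance = 1e-9)
})

test_that("lagged TE on a linear system matches the closed form", {
  set.seed(12)
  n <- 10000
  x <- rnorm(n)
  y <- 0.5 * c(0, x[-n]) + rnorm(n)
  pair <- bivariate_series(x, y)
  emb <- manual_embedding(source_delays = 1, target_delays = 1)
  te <- transfer_entropy(pair, "xy", lag = 0, embedding = emb, seed = 13)
  expect_lt(abs(te$value - 0.5 * log(1.25)), 0.02)
})

test_that("surrogate test is deterministic and detects strong coupling", {
  set.seed(14)
  n <- 300
  x <- rnorm(n)
  y <- c(0, x[-n]) + 0.05 * rnorm(n)
  pair <- bivariate_series(x, y)
  s1 <- surrogate_test(pair, "xy", lag = 0, seed = 21)
  s2 <- surrogate_test(pair, "xy", lag = 0, seed = 21)
  expect_identical(s1$surrogate_values, s2$surrogate_values)
  expect_true(s1$significant)
  expect_equal(s1$threshold, sort(s1$surrogate_values)[95])
  expect_length(s1$surrogate_values, 100)
  expect_true(all(s1$shifts >= 1 & s1$shifts <= 20))
})

test_that("coupled replicates are detected as significant by surrogates", {
  sig <- 0
  n_reps <- 25
  for (r in seq_len(n_reps)) {
    sim <- simulate_coupled_ar(seed = 400 + r)
    pair <- bivariate_series(sim$x, sim$y)
    st <- surrogate_test(pair, "xy", lag = 0, seed = 600 + r)
    if (st$significant) sig <- sig + 1
  }
  expect_gte(sig, ceiling(0.95 * n_reps) - 1)
})

test_that("lag_profile matches direct per-cell computation bit for bit", {
  sim <- simulate_coupled_ar(seed = 31)
  pair <- bivariate_series(sim$x, sim$y)
  lp <- lag_profile(pair, tau_max = 2, directions = "xy",
                    surrogates = FALSE, seed = 99)
  expect_equal(nrow(lp$results), 3)
  direct <- transfer_entropy(pair, "xy", lag = 0,
                             seed = derive_seed(99, "cell:xy:0"))
  expect_identical(lp$results$value[lp$results$lag == 0], direct$value)
  expect_identical(lp$embeddings[["xy:0"]]$selected,
                   direct$embedding$selected)
})

test_that("a white-noise pair yields an almost entirely non-significant grid", {
  pair <- simulate_null_pair(300, seed = 71)
  pair <- bivariate_series(pair$x, pair$y)
  lp <- lag_profile(pair, tau_max = 7, directions = c("xy", "yx"),
                    surrogates = TRUE, seed = 72)
  expect_equal(nrow(lp$results), 16)
  expect_gte(sum(!lp$results$significant), 13)
})
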