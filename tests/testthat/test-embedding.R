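test_that("candidate set enumerates both processes at all delays", {
  cs <- build_candidate_set(selection_policy(L_max = 10))
  expect_equal(nrow(cs), 20)
  expect_equal(sort(unique(cs$delay)), 1:10)
  expect_equal(sum(cs$process == "source"), 10)
  cs1 <- build_candidate_set(1)
  expect_equal(cs1$process, c("source", "target"))
  expect_equal(cs1$delay, c(1L, 1L))
  cs3 <- build_candidate_set(3)
  expect_equal(nrow(cs3), 6)
  expect_equal(cs3$delay, rep(1:3, each = 2))
})

test_that("selection recovers a dominant source coupling at the right delay", {
  hits <- 0
  for (s in 1:30) {
    set.seed(s)
    n <- 300
    x <- rnorm(n)
    y <- c(rep(0, 3), x[1:(n - 3)]) + 0.05 * rnorm(n)
    pair <- bivariate_series(x, y)
    emb <- select_candidates(pair, "xy", lag = 0, seed = s)
    sel <- emb$selected
    if (nrow(sel) >= 1 && sel$process[1] == "source" && sel$delay[1] == 3)
      hits <- hits + 1
  }
  expect_gte(hits, 29)  # >= 95% of runs
})

test_that("selection is conservative under the null", {
  # independent white noise: the gate should keep the embedding empty in
  # the vast majority of runs, and false source selections at or below the
  # nominal family-wise level
  nonempty <- 0; with_source <- 0
  n_runs <- 200
  for (s in seq_len(n_runs)) {
    pair <- simulate_null_pair(300, seed = 5000 + s)
    pair <- bivariate_series(pair$x, pair$y)
    emb <- select_candidates(pair, "xy", lag = 0, seed = 900 + s)
    if (nrow(emb$selected) > 0) nonempty <- nonempty + 1
    if (any(emb$selected$process == "source")) with_source <- with_source + 1
  }
  expect_gte(n_runs - nonempty, 0.90 * n_runs)  # empty in >= 90% of runs
  # source acceptances controlled at the gate level (upper binomial bound)
  expect_lte(with_source, qbinom(0.975, n_runs, 0.05))
})

test_that("accepted gains are positive and greedy-ordered", {
  sim <- simulate_coupled_ar(seed = 3)
  pair <- bivariate_series(sim$x, sim$y)
  emb <- select_candidates(pair, "xy", lag = 0, seed = 3)
  expect_gt(nrow(emb$selected), 0)
  expect_true(all(emb$selected$gain > 0))
  # each accepted candidate maximized the gain in its round
  expect_equal(emb$selected$gain,
               emb$winner_gains[seq_len(nrow(emb$selected))])
})

test_that("selection is bit-reproducible given series, policy and seed", {
  sim <- simulate_coupled_ar(seed = 4)
  pair <- bivariate_series(sim$x, sim$y)
  e1 <- select_candidates(pair, "xy", lag = 2, seed = 77)
  e2 <- select_candidates(pair, "xy", lag = 2, seed = 77)
  expect_identical(e1$selected, e2$selected)
  expect_identical(e1$thresholds, e2$thresholds)
})

test_that("candidate_frequency tabulates selections over the full grid", {
  pol <- selection_policy(L_max = 3)
  mk <- function(proc, delay) {
    e <- manual_embedding(
      source_delays = if (proc == "source") delay else integer(),
      target_delays = if (proc == "target") delay else integer(),
      policy = pol)
    e
  }
  runs <- list(mk("target", 1), mk("target", 1))
  tab <- candidate_frequency(runs)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$fraction[tab$process == "target" & tab$delay == 1], 1.0)
  expect_equal(sum(tab$fraction), 1.0)
  runs2 <- list(mk("source", 2), mk("target", 3))
  tab2 <- candidate_frequency(runs2)
  expect_true(all(tab2$fraction %in% c(0, 0.5)))
  expect_error(candidate_frequency(list()), "at least one")
})
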