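test_that("validation_experiment assembles the full grid (small smoke run)", {
  v <- validation_experiment(n_reps = 10, lags = 0:2, directions = "xy",
                             seed = 5)
  expect_equal(nrow(v$table), 10 * 3)
  expect_true(all(v$table$value >= 0))
  expect_true(is.finite(v$anova$xy$p))
  expect_equal(dim(v$pairwise$xy), c(2, 2))
  expect_equal(nrow(v$candidate_freq$xy), 20)
})

test_that("a response with no lag structure yields a null lag effect", {
  # identical replicate values at every lag: between-lag variance is zero
  set.seed(21)
  tab <- data.frame(value = rep(1 + rnorm(10, 0, 0.1), times = 16),
                    lag = rep(0:15, each = 10))
  fit <- aov(value ~ factor(lag), data = tab)
  s <- summary(fit)[[1]]
  expect_lt(s$`F value`[1], 1e-10)
  expect_gt(s$`Pr(>F)`[1], 0.999)
})

test_that("cohort model recovers an injected graded group effect", {
  tab <- simulate_cohort_table(n_per_group = 60, group_shift = c(0, 0.5, 1),
                               lags = 0:3, seed = 11)
  m <- cohort_model(tab)
  pg <- m$anova_table$p[m$anova_table$term == "group"]
  expect_lt(pg, 0.01)
  expect_true(all(m$contrasts$p.value < 0.05))
  # marginal-mean ordering matches construction (LPT < ET < FT)
  emm <- m$emmeans
  ord <- emm$emmean[match(c("LPT", "ET", "FT"), emm$group)]
  expect_true(all(diff(ord) > 0))
})

test_that("group p-values are uniform under permuted labels", {
  tab <- simulate_cohort_table(n_per_group = 30, group_shift = c(0, 0, 0),
                               lags = 0:1, seed = 12)
  ps <- numeric(200)
  set.seed(13)
  for (i in seq_len(200)) {
    tab$group <- sample(tab$group)
    fit <- lm(value ~ factor(lag) + group + sex + mod + hol, data = tab)
    a <- car::Anova(fit, type = 2)
    ps[i] <- a["group", "Pr(>F)"]
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a zero interaction is rarely declared significant", {
  hits <- 0
  for (s in 1:20) {
    tab <- simulate_cohort_table(n_per_group = 40,
                                 group_shift = c(0, 0.3, 0.6),
                                 lags = 0:2, lag_effect = c(0, 0.2, 0.4),
                                 interaction = 0, seed = 100 + s)
    m <- cohort_model(tab)
    pi2 <- m$anova_table$p[m$anova_table$term == "lag:group"]
    if (pi2 < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 2)  # >= 90% of runs keep the null interaction
})

test_that("sobel mediation recovers designed path structure", {
  set.seed(14)
  n <- 10000
  iv <- rnorm(n)
  med <- 0.5 * iv + 0.1 * rnorm(n)
  dv <- 0.5 * med + 0.75 * iv + 0.1 * rnorm(n)
  m <- sobel_mediation(iv, med, dv)
  expect_lt(abs(m$prop_mediated_pct - 25), 2)
  expect_lt(m$p, 1e-10)
  # unrelated mediator: no indirect path
  med0 <- rnorm(n)
  m0 <- sobel_mediation(iv, med0, dv = 0.75 * iv + 0.1 * rnorm(n))
  expect_lt(abs(m0$prop_mediated_pct), 2)
  expect_lt(abs(m0$sobel_z), 3)
})

test_that("sobel z is antisymmetric in the sign of the indirect path", {
  set.seed(15)
  n <- 2000
  iv <- rnorm(n)
  med <- 0.5 * iv + rnorm(n)
  dv <- 0.4 * med + rnorm(n)
  z1 <- sobel_mediation(iv, med, dv)$sobel_z
  z2 <- sobel_mediation(iv, med, -dv)$sobel_z  # flips b, hence a * b
  expect_equal(z1, -z2, tolerance = 1e-10)
  expect_error(sobel_mediation(rep(1, 100), med[1:100], dv[1:100]),
               "zero-variance")
})
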