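test_that("knn_entropy recovers closed-form entropies", {
  set.seed(1)
  g <- matrix(rnorm(10000), ncol = 1)
  expect_lt(abs(knn_entropy(g) - gauss_entropy()), 0.05)
  u <- matrix(runif(10000), ncol = 1)
  expect_lt(abs(knn_entropy(u)), 0.03)
})

test_that("knn_entropy matches the brute-force oracle on a hand-listed cloud", {
  pts <- matrix(c(0.12, 0.31, 0.55, 0.72, 1.04, 1.31, 1.58, 2.02), ncol = 1)
  expect_equal(knn_entropy(pts, k = 2), brute_knn_entropy(pts, k = 2),
               tolerance = 1e-12)
  set.seed(7)
  cloud <- matrix(rnorm(60), ncol = 2)
  expect_equal(knn_entropy(cloud, k = 4), brute_knn_entropy(cloud, k = 4),
               tolerance = 1e-12)
})

test_that("knn_entropy is translation-invariant and validates input", {
  set.seed(2)
  pts <- matrix(rnorm(500), ncol = 1)
  expect_lt(abs(knn_entropy(pts + 7.3) - knn_entropy(pts)), 1e-9)
  expect_error(knn_entropy(pts[1:5, , drop = FALSE], k = 10), "too few")
  expect_error(knn_entropy(cbind(pts, 1)), "constant")
  expect_error(knn_entropy(rbind(pts, pts[1:20, , drop = FALSE])),
               "duplicate")
})

test_that("cmi_knn recovers Gaussian mutual information", {
  p <- rgauss_pair(2000, 0, seed = 3)
  expect_lt(abs(cmi_knn(p$a, p$b, clip_negative = FALSE)), 0.02)
  p <- rgauss_pair(10000, 0.6, seed = 4)
  expect_lt(abs(cmi_knn(p$a, p$b) - gauss_mi(0.6)), 0.03)
})

test_that("cmi_knn accuracy tightens at large n (jointly Gaussian)", {
  p <- rgauss_pair(20000, 0.5, seed = 5)
  expect_lt(abs(cmi_knn(p$a, p$b) - gauss_mi(0.5)), 0.03)
})

test_that("conditioning on a copy of the source removes its information", {
  p <- rgauss_pair(2000, 0.6, seed = 6)
  val <- cmi_knn(p$a, p$b, cond_block = p$b, clip_negative = FALSE)
  expect_lt(abs(val), 0.02)
})

test_that("cmi_knn raw values sit above the estimator noise floor", {
  for (s in 1:5) {
    set.seed(100 + s)
    y <- rnorm(1000); x <- rnorm(1000); z <- rnorm(1000)
    raw <- cmi_knn(y, x, z, clip_negative = FALSE)
    expect_gt(raw, -0.05)
    expect_lt(abs(raw), 0.02)  # conditional independence holds by design
  }
})

test_that("entropy-combination terms reproduce the CMI exactly", {
  set.seed(8)
  y <- rnorm(400); x <- rnorm(400) + 0.5 * y; z <- rnorm(400)
  est <- cmi_knn(y, x, z, detail = TRUE)
  combo <- est$terms[["h_yz"]] + est$terms[["h_xz"]] -
    est$terms[["h_z"]] - est$terms[["h_joint"]]
  expect_equal(est$raw, combo, tolerance = 1e-9)
})

test_that("gaussian_te_oracle matches residual-variance closed forms", {
  set.seed(9)
  n <- 50000
  x <- rnorm(n)
  y <- 0.5 * c(0, x[-n]) + rnorm(n)
  te <- gaussian_te_oracle(x, y, source_lags = 1, target_lags = 1)
  expect_lt(abs(te - 0.5 * log(1.25)), 0.01)
  # uncoupled white noise
  te0 <- gaussian_te_oracle(rnorm(5000), rnorm(5000), 1, 1)
  expect_lt(abs(te0), 0.01)
})

test_that("kNN TE agrees with the linear-Gaussian oracle", {
  set.seed(10)
  n <- 10000
  x <- rnorm(n)
  y <- 0.5 * c(0, x[-n]) + rnorm(n)
  pair <- bivariate_series(x, y)
  emb <- manual_embedding(source_delays = 1, target_delays = 1)
  te_knn <- transfer_entropy(pair, "xy", lag = 0, embedding = emb, seed = 11)
  te_lin <- gaussian_te_oracle(x, y, 1, 1)
  expect_lt(abs(te_knn$value - te_lin), 0.05)
})
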