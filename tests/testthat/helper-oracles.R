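# Independent oracles used to freeze expected values.

# brute-force Kozachenko-Leonenko entropy in plain R (Chebyshev metric)
brute_knn_entropy <- function(pts, k = 10) {
  pts <- as.matrix(pts)
  n <- nrow(pts); d <- ncol(pts)
  slog <- 0
  for (i in seq_len(n)) {
    dist <- apply(abs(sweep(pts, 2, pts[i, ])), 1, max)
    eps <- sort(dist[-i])[k]
    slog <- slog + log(2 * eps)
  }
  digamma(n) - digamma(k) + d * slog / n
}

# closed forms
gauss_entropy <- function(sd = 1) 0.5 * log(2 * pi * exp(1) * sd^2)
gauss_mi <- function(rho) -0.5 * log(1 - rho^2)

# stationary variance of an AR(2) process (Yule-Walker)
ar2_variance <- function(a1, a2, s2 = 1) {
  s2 * (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
}

# correlated Gaussian pair
rgauss_pair <- function(n, rho, seed = 1) {
  set.seed(seed)
  a <- rnorm(n)
  b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  list(a = a, b = b)
}
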