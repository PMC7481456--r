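#' Bivariate series container
#'
#' Pairs the two aligned sample vectors under analysis. For analysis use the
#' channels are z-normalized to zero mean and unit (population) variance,
#' the form expected by the nearest-neighbor estimator.
#'
#' @param x source-role series (e.g. RR intervals, or simulated X).
#' @param y target-role series (e.g. beat-aligned respiration, simulated Y).
#' @param normalize z-normalize both channels (default `TRUE`).
#' @param labels length-2 character vector naming the channels.
#' @return A `bivariate_series` object with fields `x`, `y`, `N`, `labels`.
#' @export
bivariate_series <- function(x, y, normalize = TRUE, labels = c("X", "Y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("series must be finite")
  if (normalize) { x <- znorm(x); y <- znorm(y) }
  structure(list(x = x, y = y, N = length(x), labels = labels,
                 normalized = normalize),
            class = "bivariate_series")
}

#' @export
print.bivariate_series <- function(x, ...) {
  cat("Bivariate series ", x$labels[1], "/", x$labels[2], ", N = ", x$N,
      if (x$normalized) ", z-normalized" else "", "\n", sep = "")
  invisible(x)
}

#' Lag-shifted embedded design
#'
#' Aligns the target sample `y[n - lag]` with the source past
#' `x[n - 1 .. n - L_max]` and the target past
#' `y[n - lag - 1 .. n - lag - L_max]`, truncated to the common support of
#' `N - lag - L_max` rows. `lag = 0` reproduces the standard TE design.
#'
#' @param pair a [bivariate_series()].
#' @param lag target shift in samples (>= 0).
#' @param L_max past depth in samples.
#' @param direction `"xy"` or `"yx"`.
#' @return List with `target` (vector), `source_past` and `target_past`
#'   (matrices, column d = delay d) and `rows`.
#' @export
shift_align <- function(pair, lag = 0, L_max = 10,
                        direction = c("xy", "yx")) {
  direction <- match.arg(direction)
  stopifnot(inherits(pair, "bivariate_series"), lag >= 0, L_max >= 1)
  ds <- direction_series(pair, direction)
  te_design(ds$src, ds$tgt, lag, L_max)
}

# TE (raw nats) for a fixed embedding on already-jittered series.
te_value_fixed <- function(src, tgt, lag, embedding, k) {
  sel <- embedding$selected
  L_max <- embedding$policy$L_max
  dsn <- te_design(src, tgt, lag, L_max)
  is_src <- sel$process == "source"
  if (!any(is_src)) return(list(raw = 0, terms = NULL))
  xb <- dsn$source_past[, sel$delay[is_src], drop = FALSE]
  zb <- if (any(!is_src))
    dsn$target_past[, sel$delay[!is_src], drop = FALSE] else NULL
  est <- cmi_knn(dsn$target, xb, zb, k = k, clip_negative = FALSE,
                 detail = TRUE)
  list(raw = est$raw, terms = est$terms)
}

#' Lagged Transfer Entropy for one direction and lag
#'
#' Computes TE through the conditioning-vector entropy decomposition
#' \deqn{TE = H(y_n, V^Y) - H(V^Y) - H(y_n, V) + H(V),}
#' evaluated with the shared-radius nearest-neighbor estimator, where
#' \eqn{V = [V^X, V^Y]} is the non-uniformly selected embedding. When the
#' embedding holds no source candidate the transfer is zero by construction.
#'
#' @param pair a [bivariate_series()].
#' @param direction `"xy"` (X drives Y) or `"yx"`.
#' @param lag target shift in samples (0 = standard TE).
#' @param embedding optional `te_embedding` from [select_candidates()];
#'   selected automatically (same `seed`) when `NULL`.
#' @param policy [selection_policy()] used when selecting.
#' @param k neighbor count (default 10).
#' @param seed integer seed (jitter + selection permutations).
#' @param clip_negative clip the reported value at 0 (default `TRUE`).
#' @return A `te_estimate`: `value` (nats, clipped), `raw`, `terms` (the
#'   four entropy terms, `NULL` for an empty source side), `embedding`,
#'   `direction`, `lag`, `k`.
#' @export
transfer_entropy <- function(pair, direction = c("xy", "yx"), lag = 0,
                             embedding = NULL, policy = selection_policy(),
                             k = 10, seed = 1, clip_negative = TRUE) {
  direction <- match.arg(direction)
  stopifnot(inherits(pair, "bivariate_series"))
  if (is.null(embedding))
    embedding <- select_candidates(pair, direction, lag, policy, k, seed)
  stopifnot(inherits(embedding, "te_embedding"))
  jp <- jittered_pair(pair, seed)
  ds <- direction_series(jp, direction)
  v <- te_value_fixed(ds$src, ds$tgt, lag, embedding, k)
  structure(list(value = if (clip_negative) max(0, v$raw) else v$raw,
                 raw = v$raw, terms = v$terms, embedding = embedding,
                 direction = direction, lag = lag, k = k, seed = seed),
            class = "te_estimate")
}

#' @export
print.te_estimate <- function(x, ...) {
  cat("TE ", x$direction, " lag ", x$lag, ": ",
      format(x$value, digits = 4), " nats (raw ",
      format(x$raw, digits = 4), "), ",
      sum(x$embedding$selected$process == "source"), " source / ",
      sum(x$embedding$selected$process == "target"),
      " target candidate(s)\n", sep = "")
  invisible(x)
}

#' Time-shift surrogate significance test
#'
#' Recomputes TE after circularly shifting the source series by an integer
#' drawn uniformly from `[1, max_shift]` (forward, with replacement across
#' surrogates), destroying directed coupling while preserving both
#' marginals. The embedding is selected once on the original data and
#' reused for every surrogate. The observed TE is significant when its raw
#' value strictly exceeds the empirical 95th percentile of the surrogate
#' distribution.
#'
#' @inheritParams transfer_entropy
#' @param n_surrogates number of surrogate series (default 100).
#' @param max_shift maximum circular shift in samples (default 20).
#' @return A `te_surrogate`: the observed `estimate`, `surrogate_values`
#'   (raw nats), `threshold` (95th percentile), `significant`.
#' @export
surrogate_test <- function(pair, direction = c("xy", "yx"), lag = 0,
                           embedding = NULL, n_surrogates = 100,
                           max_shift = 20, policy = selection_policy(),
                           k = 10, seed = 1) {
  direction <- match.arg(direction)
  stopifnot(inherits(pair, "bivariate_series"),
            max_shift >= 1, n_surrogates >= 1)
  if (pair$N <= 2 * max_shift)
    stop("series too short for max_shift = ", max_shift)
  if (is.null(embedding))
    embedding <- select_candidates(pair, direction, lag, policy, k, seed)
  est <- transfer_entropy(pair, direction, lag, embedding, policy, k, seed,
                          clip_negative = TRUE)
  jp <- jittered_pair(pair, seed)
  ds <- direction_series(jp, direction)
  if (sd(ds$src) == 0) stop("degenerate (constant) source series")
  N <- pair$N
  shifts <- with_local_seed(derive_seed(seed, "surrogates"),
                            sample.int(max_shift, n_surrogates,
                                       replace = TRUE))
  vals <- vapply(shifts, function(s) {
    xs <- c(ds$src[(N - s + 1):N], ds$src[1:(N - s)])
    te_value_fixed(xs, ds$tgt, lag, embedding, k)$raw
  }, numeric(1))
  thr <- sort(vals)[ceiling(0.95 * n_surrogates)]
  structure(list(estimate = est, surrogate_values = vals, threshold = thr,
                 significant = est$raw > thr, shifts = shifts,
                 n_surrogates = n_surrogates, max_shift = max_shift),
            class = "te_surrogate")
}

#' @export
print.te_surrogate <- function(x, ...) {
  cat("Surrogate test (", x$n_surrogates, " time-shift surrogates): TE = ",
      format(x$estimate$value, digits = 4), ", threshold = ",
      format(x$threshold, digits = 4), " -> ",
      if (x$significant) "significant" else "not significant", "\n",
      sep = "")
  invisible(x)
}

#' Lag profile of directed Transfer Entropy
#'
#' Computes TE (embedding re-selected per direction and lag) and optionally
#' the surrogate significance test on the complete grid of lags
#' `0..tau_max` for both directions.
#'
#' The seed for the cell `(direction d, lag t)` is
#' `derive_seed(seed, paste0("cell:", d, ":", t))`, so any single cell can
#' be reproduced with a direct [transfer_entropy()] or [surrogate_test()]
#' call.
#'
#' @inheritParams surrogate_test
#' @param tau_max maximum lag in samples (default 15; must satisfy
#'   `tau_max < N / 4`).
#' @param directions subset of `c("xy", "yx")`.
#' @param surrogates run the surrogate test per cell (default `TRUE`).
#' @return A `te_lag_profile` with a long-format `results` data frame (one
#'   row per direction and lag: `value`, `raw_value`, `threshold`,
#'   `significant`, `n_candidates_source`, `n_candidates_target`) and the
#'   per-cell embeddings.
#' @export
lag_profile <- function(pair, tau_max = 15, directions = c("xy", "yx"),
                        policy = selection_policy(), k = 10,
                        surrogates = TRUE, n_surrogates = 100,
                        max_shift = 20, seed = 1) {
  stopifnot(inherits(pair, "bivariate_series"), tau_max >= 0)
  if (tau_max >= pair$N / 4) stop("tau_max must be below N / 4")
  directions <- match.arg(directions, c("xy", "yx"), several.ok = TRUE)
  rows <- list()
  embeddings <- list()
  for (d in directions) {
    for (t in 0:tau_max) {
      cs <- derive_seed(seed, paste0("cell:", d, ":", t))
      if (surrogates) {
        st <- surrogate_test(pair, d, t, NULL, n_surrogates, max_shift,
                             policy, k, cs)
        est <- st$estimate
        thr <- st$threshold; sig <- st$significant
      } else {
        est <- transfer_entropy(pair, d, t, NULL, policy, k, cs)
        thr <- NA_real_; sig <- NA
      }
      key <- paste0(d, ":", t)
      embeddings[[key]] <- est$embedding
      rows[[key]] <- data.frame(
        direction = d, lag = t, value = est$value, raw_value = est$raw,
        threshold = thr, significant = sig,
        n_candidates_source = sum(est$embedding$selected$process == "source"),
        n_candidates_target = sum(est$embedding$selected$process == "target"),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(results = do.call(rbind, c(rows, make.row.names = FALSE)),
                 embeddings = embeddings, tau_max = tau_max,
                 policy = policy, k = k, seed = seed,
                 surrogates = surrogates),
            class = "te_lag_profile")
}

#' @export
print.te_lag_profile <- function(x, ...) {
  cat("Lagged TE profile, lags 0..", x$tau_max, "\n", sep = "")
  print(x$results, row.names = FALSE)
  invisible(x)
}
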