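#' Selection policy for non-uniform embedding
#'
#' Bundles the tunable parameters of the greedy candidate-selection
#' procedure: the maximum past depth `L_max` (the candidate set holds the
#' past `L_max` states of both processes), the number of permutations used
#' by the significance gate, and the gate level `alpha`.
#'
#' Two gate rules are available. `"sidak"` (default) accepts the winning
#' candidate only if its conditional-mutual-information gain exceeds the
#' empirical `(1 - alpha)^(1/m)` quantile of its permutation null, where `m`
#' is the number of candidates still in play; this Sidak correction targets
#' a family-wise false-selection rate of `alpha` per round despite the gain
#' being a maximum over `m` candidates. `"percentile"` is the uncorrected
#' per-candidate `1 - alpha` percentile gate.
#'
#' @param L_max maximum candidate delay in samples (default 10).
#' @param n_shuffles permutations per gate (default 100).
#' @param alpha gate significance level (default 0.05).
#' @param gate `"sidak"` or `"percentile"`.
#' @return A `selection_policy` list.
#' @export
selection_policy <- function(L_max = 10, n_shuffles = 100, alpha = 0.05,
                             gate = c("sidak", "percentile")) {
  gate <- match.arg(gate)
  stopifnot(L_max >= 1, n_shuffles >= 1, alpha > 0, alpha < 1)
  structure(list(L_max = as.integer(L_max),
                 n_shuffles = as.integer(n_shuffles),
                 alpha = alpha, gate = gate),
            class = "selection_policy")
}

#' Enumerate the initial candidate set
#'
#' The candidate pool holds one entry per (process, delay) pair for delays
#' `1..L_max` of both the source and the target process, ordered by delay
#' with the source process first within a delay (this ordering is also the
#' deterministic tie-break used during selection).
#'
#' @param policy a [selection_policy()] (or an integer taken as `L_max`).
#' @return Data frame with columns `process` (`"source"`/`"target"`) and
#'   `delay`; exactly `2 * L_max` rows.
#' @export
build_candidate_set <- function(policy = selection_policy()) {
  L <- if (inherits(policy, "selection_policy")) policy$L_max
       else as.integer(policy)
  stopifnot(L >= 1)
  data.frame(
    process = rep(c("source", "target"), L),
    delay = rep(seq_len(L), each = 2),
    stringsAsFactors = FALSE
  )
}

# Lag-shifted embedded design shared by selection, TE and surrogates.
# Row n (original time index) carries target y[n - lag], source past
# x[n - 1 .. n - L_max] and target past y[n - lag - 1 .. n - lag - L_max].
te_design <- function(x, y, lag, L_max, min_rows = 50) {
  N <- length(x)
  rows <- N - lag - L_max
  if (rows < min_rows)
    stop("series too short: ", rows, " usable rows after lag ", lag,
         " and depth ", L_max, " (need >= ", min_rows, ")")
  n_idx <- (lag + L_max + 1):N
  lagmat <- function(v, offs) {
    vapply(offs, function(d) v[n_idx - d], numeric(length(n_idx)))
  }
  list(target = y[n_idx - lag],
       source_past = lagmat(x, seq_len(L_max)),
       target_past = lagmat(y, seq_len(L_max) + lag),
       rows = rows)
}

# source/target series of a bivariate pair for one direction
direction_series <- function(pair, direction) {
  if (direction == "xy") list(src = pair$x, tgt = pair$y)
  else list(src = pair$y, tgt = pair$x)
}

# jittered copy of the pair (deterministic tie-breaking before kNN queries)
jittered_pair <- function(pair, seed) {
  pair$x <- add_jitter(pair$x, derive_seed(seed, "jitter-x"))
  pair$y <- add_jitter(pair$y, derive_seed(seed, "jitter-y"))
  pair
}

#' Greedy non-uniform embedding selection
#'
#' Builds the conditioning vector for one direction and lag by progressive
#' selection: at each round the candidate with the largest
#' conditional-mutual-information gain (given the candidates already
#' accepted) is gated against its permutation null; the first gate failure
#' terminates selection. Candidates cover delays `1..L_max` of both the
#' source and the target process, with target delays counted from the
#' lag-shifted target sample.
#'
#' Because the lag shifts the target while the source window stays anchored
#' at the original time index, source samples with absolute delay below the
#' lag would lie *after* the target sample; such anti-causal candidates are
#' excluded from the pool. The contemporaneous sample (delay equal to the
#' lag) is retained — it carries the instantaneous pathway, and at lag 1 it
#' is precisely the source sample aligned with the shifted target. When the
#' lag exceeds `L_max` no causal source candidate exists: selection is
#' skipped and the embedding is empty (the transfer is identically zero).
#'
#' @param pair a [bivariate_series()].
#' @param direction `"xy"` (source = `x`) or `"yx"` (source = `y`).
#' @param lag target shift in samples (>= 0).
#' @param policy a [selection_policy()].
#' @param k neighbor count for the estimator (default 10).
#' @param seed integer seed controlling jitter and gate permutations;
#'   selection is bit-reproducible given `(pair, policy, seed)`.
#' @return A `te_embedding` object: data frame `selected` (acceptance order,
#'   with per-candidate gains), gate `thresholds`, `rounds`, and the context
#'   (`direction`, `lag`, `policy`, `n`).
#' @export
select_candidates <- function(pair, direction = c("xy", "yx"), lag = 0,
                              policy = selection_policy(), k = 10, seed = 1) {
  direction <- match.arg(direction)
  stopifnot(inherits(pair, "bivariate_series"), lag >= 0)
  jp <- jittered_pair(pair, seed)
  ds <- direction_series(jp, direction)
  dsn <- te_design(ds$src, ds$tgt, lag, policy$L_max)
  n <- dsn$rows
  if (n > 3000)
    stop("non-uniform selection is designed for short segments (n <= 3000)")
  cand <- build_candidate_set(policy)
  # drop anti-causal source candidates (samples after the shifted target)
  cand <- cand[cand$process == "target" | cand$delay >= lag, , drop = FALSE]
  rownames(cand) <- NULL
  if (!any(cand$process == "source")) {
    return(structure(list(
      selected = data.frame(process = character(), delay = integer(),
                            gain = numeric()),
      thresholds = numeric(), winner_gains = numeric(), rounds = 0L,
      direction = direction, lag = lag, policy = policy, k = k,
      seed = seed, n = n), class = "te_embedding"))
  }
  # columns in candidate-set order: delay-major, source before target
  cmat <- matrix(0, n, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cmat[, i] <- if (cand$process[i] == "source")
      dsn$source_past[, cand$delay[i]] else dsn$target_past[, cand$delay[i]]
  }
  nshuf <- policy$n_shuffles
  perms <- with_local_seed(derive_seed(seed, "shuffles"), {
    matrix(replicate(nshuf * nrow(cand), sample.int(n) - 1L), nrow = n)
  })
  res <- nue_select_cpp(cmat, dsn$target, as.integer(k), perms,
                        as.integer(nshuf), policy$alpha,
                        if (policy$gate == "sidak") 2L else 1L)
  sel <- cand[res$selected, , drop = FALSE]
  sel$gain <- res$gains
  rownames(sel) <- NULL
  structure(list(selected = sel,
                 thresholds = res$thresholds,
                 winner_gains = res$winner_gains,
                 rounds = res$rounds,
                 direction = direction, lag = lag,
                 policy = policy, k = k, seed = seed, n = n),
            class = "te_embedding")
}

#' @export
print.te_embedding <- function(x, ...) {
  cat("Non-uniform embedding (", x$direction, ", lag ", x$lag, "): ",
      nrow(x$selected), " candidate(s) over ", x$rounds, " round(s)\n",
      sep = "")
  if (nrow(x$selected)) print(x$selected)
  invisible(x)
}

#' Manually specified embedding
#'
#' Builds a `te_embedding` from explicit delay lists, bypassing selection.
#' Useful for estimator cross-checks against closed-form oracles and for
#' exactly calibrated surrogate tests, where the data-driven selection step
#' would confound the property under study.
#'
#' @param source_delays integer delays for the source process.
#' @param target_delays integer delays for the target process (counted from
#'   the lag-shifted target sample).
#' @param policy a [selection_policy()]; its `L_max` must cover the delays.
#' @param direction,lag context fields (defaults `"xy"`, 0).
#' @return A `te_embedding`.
#' @export
manual_embedding <- function(source_delays = integer(),
                             target_delays = integer(),
                             policy = selection_policy(),
                             direction = "xy", lag = 0) {
  stopifnot(all(source_delays >= 1), all(target_delays >= 1),
            all(c(source_delays, target_delays) <= policy$L_max))
  sel <- rbind(
    if (length(source_delays))
      data.frame(process = "source", delay = as.integer(source_delays),
                 gain = NA_real_),
    if (length(target_delays))
      data.frame(process = "target", delay = as.integer(target_delays),
                 gain = NA_real_))
  if (is.null(sel))
    sel <- data.frame(process = character(), delay = integer(),
                      gain = numeric())
  structure(list(selected = sel, thresholds = numeric(),
                 winner_gains = numeric(), rounds = 0L,
                 direction = direction, lag = lag, policy = policy,
                 k = NA_integer_, seed = NA_integer_, n = NA_integer_),
            class = "te_embedding")
}

#' Candidate selection frequencies across runs
#'
#' Tabulates, for every (process, delay) candidate, the fraction of runs in
#' which it entered the conditioning vector.
#'
#' @param runs list of `te_embedding` objects (e.g. one per replicate).
#' @param L_max candidate depth of the table; defaults to the policy of the
#'   first run.
#' @return Long-format data frame `(process, delay, fraction)` covering all
#'   `2 * L_max` candidates.
#' @export
candidate_frequency <- function(runs, L_max = NULL) {
  if (length(runs) == 0) stop("need at least one selection run")
  if (is.null(L_max)) L_max <- runs[[1]]$policy$L_max
  tab <- build_candidate_set(L_max)
  counts <- numeric(nrow(tab))
  key <- paste(tab$process, tab$delay)
  for (r in runs) {
    if (nrow(r$selected) == 0) next
    hit <- unique(paste(r$selected$process, r$selected$delay))
    counts[key %in% hit] <- counts[key %in% hit] + 1
  }
  tab$fraction <- counts / length(runs)
  tab
}
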