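#' Simulation validation experiment: lag effect on directed TE
#'
#' Generates `n_reps` seeded realizations of the coupled autoregressive
#' system, computes lagged TE on the full lag grid for the requested
#' directions (embedding re-selected per direction and lag), and tests the
#' fixed factor lag with a one-way ANOVA per direction, followed by
#' Bonferroni-adjusted pairwise lag comparisons.
#'
#' @param n_reps replicates (default 100).
#' @param lags lag grid (default `0:15`).
#' @param spec an [ar_sim_spec()].
#' @param policy a [selection_policy()].
#' @param k neighbor count.
#' @param directions subset of `c("xy", "yx")`.
#' @param surrogates run the surrogate test per cell (default `FALSE`; the
#'   lag ANOVA does not need it).
#' @param seed master seed; replicate r uses `derive_seed(seed, "rep", r)`.
#' @param progress print a dot per replicate (default `FALSE`).
#' @return A `te_validation` object: `table` (one row per replicate,
#'   direction and lag), per-direction `anova` (`F`, `p`, `fit`),
#'   `pairwise` (Bonferroni-adjusted p-value matrices) and
#'   `candidate_freq` (selection frequencies at lag 0).
#' @export
validation_experiment <- function(n_reps = 100, lags = 0:15,
                                  spec = ar_sim_spec(),
                                  policy = selection_policy(), k = 10,
                                  directions = c("xy", "yx"),
                                  surrogates = FALSE, seed = 1,
                                  progress = FALSE) {
  stopifnot(n_reps >= 10, all(lags >= 0))
  directions <- match.arg(directions, c("xy", "yx"), several.ok = TRUE)
  tau_max <- max(lags)
  rows <- vector("list", n_reps)
  lag0_emb <- list(xy = list(), yx = list())
  for (r in seq_len(n_reps)) {
    sim <- simulate_coupled_ar(spec, seed = derive_seed(seed, "rep", r))
    pair <- bivariate_series(sim$x, sim$y)
    lp <- lag_profile(pair, tau_max = tau_max, directions = directions,
                      policy = policy, k = k, surrogates = surrogates,
                      seed = derive_seed(seed, "profile", r))
    res <- lp$results[lp$results$lag %in% lags, , drop = FALSE]
    res$replicate <- r
    rows[[r]] <- res
    for (d in directions)
      lag0_emb[[d]][[r]] <- lp$embeddings[[paste0(d, ":0")]]
    if (progress) cat(".", if (r %% 50 == 0) "\n" else "", sep = "")
  }
  if (progress) cat("\n")
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))

  anova_res <- list(); pairwise <- list(); cand_freq <- list()
  for (d in directions) {
    sub <- tab[tab$direction == d, ]
    fit <- aov(value ~ factor(lag), data = sub)
    s <- summary(fit)[[1]]
    anova_res[[d]] <- list(F = s$`F value`[1], p = s$`Pr(>F)`[1], fit = s)
    pairwise[[d]] <- stats::pairwise.t.test(
      sub$value, factor(sub$lag), p.adjust.method = "bonferroni")$p.value
    cand_freq[[d]] <- candidate_frequency(lag0_emb[[d]], policy$L_max)
  }
  structure(list(table = tab, anova = anova_res, pairwise = pairwise,
                 candidate_freq = cand_freq, n_reps = n_reps, lags = lags,
                 spec = spec, policy = policy, seed = seed),
            class = "te_validation")
}

#' @export
print.te_validation <- function(x, ...) {
  cat("Lagged-TE validation experiment: ", x$n_reps, " replicates, lags ",
      min(x$lags), "..", max(x$lags), "\n", sep = "")
  for (d in names(x$anova))
    cat("  ", d, ": lag-effect F = ",
        format(x$anova[[d]]$F, digits = 4), ", p = ",
        format.pval(x$anova[[d]]$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Covariate-adjusted cohort model for TE
#'
#' Linear model with categorical lag, group (e.g. gestational-age strata)
#' and their interaction, adjusting for the covariates sex, mode of
#' delivery and hours of life; Type-II sums of squares, plus
#' Bonferroni-adjusted pairwise group contrasts on the estimated marginal
#' means.
#'
#' @param table data frame with columns `value`, `lag`, `group` and the
#'   covariates `sex`, `mod`, `hol` (and optionally `sleep_state`).
#' @param sleep_state optional filter on a `sleep_state` column.
#' @return A `te_cohort_model`: `anova_table` (term, df, F, p), `emmeans`
#'   (group estimated marginal means), `contrasts` (Bonferroni-adjusted
#'   pairwise group comparisons) and the fitted model.
#' @export
cohort_model <- function(table, sleep_state = NULL) {
  need <- c("value", "lag", "group", "sex", "mod", "hol")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!is.null(sleep_state)) {
    stopifnot("sleep_state" %in% names(table))
    table <- table[table$sleep_state %in% sleep_state, ]
  }
  if (length(unique(table$group)) < 2 || length(unique(table$lag)) < 2)
    stop("need at least two groups and two lags")
  table$lag <- factor(table$lag)
  table$group <- factor(table$group)
  fit <- lm(value ~ lag * group + sex + mod + hol, data = table)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased term(s): ",
         paste(bad, collapse = ", "))
  }
  a2 <- car::Anova(fit, type = 2)
  at <- data.frame(term = rownames(a2), df = a2$Df, F = a2$`F value`,
                   p = a2$`Pr(>F)`, row.names = NULL)
  emm <- suppressMessages(emmeans::emmeans(fit, "group"))
  ctr <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = "bonferroni"))
  structure(list(anova_table = at, emmeans = summary(emm),
                 contrasts = ctr, fit = fit),
            class = "te_cohort_model")
}

#' @export
print.te_cohort_model <- function(x, ...) {
  cat("Cohort model (Type-II ANCOVA)\n")
  print(x$anova_table, row.names = FALSE)
  invisible(x)
}

#' Sobel mediation analysis
#'
#' Three-regression mediation: path `a` from `mediator ~ iv`, paths `b` and
#' `c'` from `dv ~ iv + mediator`, total effect `c` from `dv ~ iv`. The
#' Sobel statistic is
#' \deqn{z = ab / \sqrt{b^2 se_a^2 + a^2 se_b^2},}
#' and the proportion mediated is `(c - c') / c`.
#'
#' @param iv independent variable (binary or numeric).
#' @param mediator mediator variable.
#' @param dv dependent variable.
#' @return A `mediation_result`: paths `a`, `b`, `c`, `c_prime` with
#'   standard errors, `sobel_z`, `p`, and `prop_mediated_pct`.
#' @export
sobel_mediation <- function(iv, mediator, dv) {
  iv <- as.numeric(iv); mediator <- as.numeric(mediator); dv <- as.numeric(dv)
  n <- length(iv)
  stopifnot(length(mediator) == n, length(dv) == n)
  if (n < 30) stop("need at least 30 units")
  if (sd(iv) == 0 || sd(mediator) == 0 || sd(dv) == 0)
    stop("zero-variance input")
  cf <- function(fit, term) {
    s <- summary(fit)$coefficients
    c(est = s[term, 1], se = s[term, 2])
  }
  m_a <- lm(mediator ~ iv)
  m_bc <- lm(dv ~ iv + mediator)
  m_c <- lm(dv ~ iv)
  a <- cf(m_a, "iv"); b <- cf(m_bc, "mediator")
  cp <- cf(m_bc, "iv"); cc <- cf(m_c, "iv")
  z <- a["est"] * b["est"] /
    sqrt(b["est"]^2 * a["se"]^2 + a["est"]^2 * b["se"]^2)
  prop <- if (cc["est"] != 0) (cc["est"] - cp["est"]) / cc["est"] * 100
          else NA_real_
  structure(list(a = a, b = b, c = cc, c_prime = cp,
                 sobel_z = unname(z), p = unname(2 * pnorm(-abs(z))),
                 prop_mediated_pct = unname(prop), n = n),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Sobel mediation: z = ", format(x$sobel_z, digits = 4), ", p = ",
      format.pval(x$p, digits = 3), ", proportion mediated = ",
      format(x$prop_mediated_pct, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' Synthetic cohort table for exercising the cohort model
#'
#' Draws a cohort-style TE result table with a graded group effect (in
#' pooled-SD units), a lag profile, an optional lag-by-group interaction,
#' and independently drawn covariates. Used to verify parameter recovery of
#' [cohort_model()]; it stands in for the unavailable real cohort.
#'
#' @param n_per_group segments per group (default 60).
#' @param groups group labels, ordered (default LPT, ET, FT).
#' @param group_shift per-group mean shift in noise-SD units (default
#'   `c(0, 0.5, 1)`).
#' @param lags lag grid (default `0:3`).
#' @param lag_effect additive lag means (recycled across `lags`).
#' @param interaction lag-by-group interaction magnitude (default 0).
#' @param noise_sd residual SD (default 1).
#' @param seed integer seed.
#' @return Data frame with `value`, `lag`, `group`, `sex`, `mod`, `hol`,
#'   `sleep_state`.
#' @export
simulate_cohort_table <- function(n_per_group = 60,
                                  groups = c("LPT", "ET", "FT"),
                                  group_shift = c(0, 0.5, 1),
                                  lags = 0:3, lag_effect = 0,
                                  interaction = 0, noise_sd = 1,
                                  seed = 1) {
  stopifnot(length(group_shift) == length(groups))
  lag_effect <- rep_len(lag_effect, length(lags))
  with_local_seed(seed, {
    rows <- expand.grid(unit = seq_len(n_per_group), group = groups,
                        lag = lags, stringsAsFactors = FALSE)
    gi <- match(rows$group, groups)
    li <- match(rows$lag, lags)
    rows$value <- group_shift[gi] * noise_sd + lag_effect[li] +
      interaction * (gi - 1) * (li - 1) + rnorm(nrow(rows), 0, noise_sd)
    rows$sex <- rbinom(nrow(rows), 1, 0.5)
    rows$mod <- rbinom(nrow(rows), 1, 0.5)
    rows$hol <- rnorm(nrow(rows), 48, 12)
    rows$sleep_state <- sample(c("AS", "QS"), nrow(rows), replace = TRUE)
    rows[c("value", "lag", "group", "sex", "mod", "hol", "sleep_state")]
  })
}
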