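#' AR(2) oscillator coefficients from pole frequency and modulus
#'
#' A complex-conjugate pole pair at modulus `rho` and normalized frequency
#' `f` (cycles/sample) gives the autoregression
#' `a1 = 2 * rho * cos(2 * pi * f)`, `a2 = -rho^2`, i.e. a self-sustained
#' stochastic rhythm centered at `f`.
#'
#' @param f normalized frequency in cycles/sample, `0 < f < 0.5`.
#' @param rho pole modulus, `0 < rho < 1`.
#' @return Named numeric vector `c(a1, a2)`.
#' @export
ar_oscillator_coeffs <- function(f, rho) {
  if (!(f > 0 && f < 0.5)) stop("f must be in (0, 0.5) cycles/sample")
  if (!(rho > 0 && rho < 1)) stop("rho must be in (0, 1)")
  c(a1 = 2 * rho * cos(2 * pi * f), a2 = -rho^2)
}

#' Specification of the coupled autoregressive validation system
#'
#' Defines the bivariate system
#' \deqn{X_n = a_1 X_{n-1} + a_2 X_{n-2} + b_{yx} Y_{n-1} + U_n}
#' \deqn{Y_n = C_1 X_{n-1} + C_2 X_{n-2} + C_3 X_{n-5} + V_n}
#' with independent zero-mean white noises. The defaults put a stochastic
#' oscillation at normalized frequency 0.1 in X (pole modulus 0.95), a
#' strong, lasting X-to-Y coupling at delays 1, 2 and 5, and a weak,
#' transient Y-to-X coupling (0.07 at delay 1).
#'
#' @param a1,a2 X autoregression coefficients (default: oscillator at
#'   `f = 0.1`, `rho = 0.95`).
#' @param b_yx Y-to-X coupling at delay 1 (default 0.07).
#' @param C X-to-Y couplings at delays 1, 2 and 5 (length-3, default all
#'   0.5).
#' @param noise_sd standard deviations of `U` and `V` (default `c(1, 1)`).
#' @param N series length after burn-in (default 300).
#' @param burn_in discarded transient samples (default 1000).
#' @return An `ar_sim_spec` list; stationarity (companion-matrix spectral
#'   radius < 1) is checked at construction.
#' @export
ar_sim_spec <- function(a1 = NULL, a2 = NULL, b_yx = 0.07,
                        C = c(0.5, 0.5, 0.5), noise_sd = c(1, 1),
                        N = 300, burn_in = 1000) {
  if (is.null(a1) || is.null(a2)) {
    ab <- ar_oscillator_coeffs(0.1, 0.95)
    if (is.null(a1)) a1 <- ab[["a1"]]
    if (is.null(a2)) a2 <- ab[["a2"]]
  }
  stopifnot(length(C) == 3, length(noise_sd) == 2, all(noise_sd > 0),
            N >= 100, burn_in >= 0)
  spec <- structure(list(a1 = a1, a2 = a2, b_yx = b_yx, C = C,
                         noise_sd = noise_sd, N = as.integer(N),
                         burn_in = as.integer(burn_in)),
                    class = "ar_sim_spec")
  sr <- companion_spectral_radius(spec)
  if (sr >= 1)
    stop("unstable coefficient set: companion spectral radius ",
         format(sr, digits = 4), " >= 1")
  spec$spectral_radius <- sr
  spec
}

# spectral radius of the joint companion matrix (state: X and Y pasts, depth 5)
companion_spectral_radius <- function(spec) {
  A <- matrix(0, 10, 10)
  # rows 1..5: X_{n}, X_{n-1}, ..; rows 6..10: Y_{n}, ..
  A[1, 1] <- spec$a1; A[1, 2] <- spec$a2; A[1, 6] <- spec$b_yx
  A[6, 1] <- spec$C[1]; A[6, 2] <- spec$C[2]; A[6, 5] <- spec$C[3]
  for (i in 2:5) { A[i, i - 1] <- 1; A[i + 5, i + 4] <- 1 }
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Simulate the coupled autoregressive validation system
#'
#' @param spec an [ar_sim_spec()].
#' @param seed integer seed; identical `(spec, seed)` give identical output.
#' @return A [bivariate_series()] (not normalized) of length `spec$N`.
#' @export
simulate_coupled_ar <- function(spec = ar_sim_spec(), seed = 1) {
  stopifnot(inherits(spec, "ar_sim_spec"))
  total <- spec$N + spec$burn_in
  noise <- with_local_seed(seed, list(u = rnorm(total, 0, spec$noise_sd[1]),
                                      v = rnorm(total, 0, spec$noise_sd[2])))
  x <- numeric(total); y <- numeric(total)
  for (n in 6:total) {
    x[n] <- spec$a1 * x[n - 1] + spec$a2 * x[n - 2] +
      spec$b_yx * y[n - 1] + noise$u[n]
    y[n] <- spec$C[1] * x[n - 1] + spec$C[2] * x[n - 2] +
      spec$C[3] * x[n - 5] + noise$v[n]
  }
  keep <- (spec$burn_in + 1):total
  bivariate_series(x[keep], y[keep], normalize = FALSE)
}

#' Simulate an uncoupled white-noise pair
#'
#' Two independent standard-normal series; the null input for type-I-error
#' calibration of selection and surrogate testing.
#'
#' @param N series length (>= 100).
#' @param seed integer seed.
#' @return A [bivariate_series()] (not normalized).
#' @export
simulate_null_pair <- function(N = 300, seed = 1) {
  stopifnot(N >= 100)
  z <- with_local_seed(seed, rnorm(2 * N))
  bivariate_series(z[1:N], z[(N + 1):(2 * N)], normalize = FALSE)
}

#' Specification of the synthetic cardiorespiratory record generator
#'
#' Parameters of a simplified neonatal cardiorespiratory model used for
#' end-to-end pipeline tests: R-peak event times whose inter-beat intervals
#' carry respiratory sinus arrhythmia (RSA), and a sampled respiration
#' waveform with a sleep-state-dependent breathing rate.
#'
#' @param duration record length in seconds (default 600).
#' @param mean_rr mean RR interval in seconds, within `[0.3, 0.667]`
#'   (default 0.45).
#' @param rr_noise_sd SD of the AR(1) beat-to-beat noise in seconds
#'   (default 0.008).
#' @param resp_rate baseline breathing rate in Hz; quiet-sleep bouts run at
#'   85% and active-sleep bouts at 115% of it (default 0.8; the respiratory
#'   period must stay within `[0.5, 2.5]` s).
#' @param rsa_gain RESP-to-RR coupling in seconds per unit respiration
#'   amplitude (default 0.01; 0 removes the coupling). The default is sized
#'   so that clean beat-to-beat changes stay below the 10% artifact rule:
#'   injected artifacts must round-trip exactly through the filter.
#' @param rr2resp_gain RR-to-RESP amplitude modulation per second of RR
#'   deviation (default 0).
#' @param resp_noise_sd additive respiration noise SD (default 0.05).
#' @param resp_fs respiration sampling rate in Hz (default 200).
#' @param artifact_rate expected fraction of beats replaced by an
#'   out-of-range RR artifact (default 0).
#' @param artifact_rr RR value written at artifact beats, outside the
#'   acceptance range (default 0.75 s).
#' @param bout_length sleep-state bout duration in seconds; bouts alternate
#'   QS/AS (default 150).
#' @return A `physio_sim_spec` list.
#' @export
physio_sim_spec <- function(duration = 600, mean_rr = 0.45,
                            rr_noise_sd = 0.008, resp_rate = 0.8,
                            rsa_gain = 0.01, rr2resp_gain = 0,
                            resp_noise_sd = 0.05, resp_fs = 200,
                            artifact_rate = 0, artifact_rr = 0.75,
                            bout_length = 150) {
  stopifnot(duration > 0, resp_fs > 0, bout_length > 0,
            artifact_rate >= 0, artifact_rate < 1)
  if (mean_rr < 0.3 || mean_rr > 0.667)
    stop("mean_rr must lie within [0.3, 0.667] s")
  for (r in resp_rate * c(0.85, 1.15)) {
    if (1 / r < 0.5 || 1 / r > 2.5)
      stop("respiratory period must stay within [0.5, 2.5] s")
  }
  # worst-case RR must stay inside the physiological acceptance range
  slack <- abs(rsa_gain) * 1.3 + 5 * rr_noise_sd
  if (mean_rr - slack < 0.3 || mean_rr + slack > 0.667)
    stop("infeasible combination: RSA gain and noise can drive RR outside ",
         "[0.3, 0.667] s")
  structure(as.list(environment())[c(
    "duration", "mean_rr", "rr_noise_sd", "resp_rate", "rsa_gain",
    "rr2resp_gain", "resp_noise_sd", "resp_fs", "artifact_rate",
    "artifact_rr", "bout_length")], class = "physio_sim_spec")
}

#' Simulate a cardiorespiratory record
#'
#' Generates a respiration waveform (sinusoidal oscillator with
#' sleep-state-dependent rate, slow rate wander and additive noise) and
#' R-peak event times whose RR intervals follow
#' `mean_rr + rsa_gain * resp(t) + AR(1) noise`, optionally with
#' out-of-range artifact beats injected at known indices.
#'
#' @param spec a [physio_sim_spec()].
#' @param seed integer seed.
#' @return A `physio_record`: `rpeak_times` (s, strictly increasing),
#'   `resp` (waveform), `resp_fs`, `sleep_states` (data frame
#'   `start`/`end`/`state`), and `ground_truth` (list with
#'   `rr_artifact_index`).
#' @export
simulate_physio <- function(spec = physio_sim_spec(), seed = 1) {
  stopifnot(inherits(spec, "physio_sim_spec"))
  with_local_seed(seed, {
    n_resp <- round(spec$duration * spec$resp_fs)
    tt <- (seq_len(n_resp) - 1) / spec$resp_fs
    # alternating QS/AS bouts
    n_bouts <- ceiling(spec$duration / spec$bout_length)
    states <- data.frame(
      start = (seq_len(n_bouts) - 1) * spec$bout_length,
      end = pmin(seq_len(n_bouts) * spec$bout_length, spec$duration),
      state = rep(c("QS", "AS"), length.out = n_bouts),
      stringsAsFactors = FALSE)
    state_at <- function(t) {
      states$state[pmin(findInterval(t, states$start), nrow(states))]
    }
    rate <- ifelse(state_at(tt) == "AS", 1.15, 0.85) * spec$resp_rate
    # slow multiplicative rate wander, bounded to keep cycles in range
    wander <- stats::filter(rnorm(n_resp, 0, 0.002), 0.999, "recursive")
    rate <- rate * exp(pmax(pmin(as.numeric(wander), 0.1), -0.1))
    phase <- 2 * pi * cumsum(rate) / spec$resp_fs
    resp_clean <- sin(phase)
    resp <- resp_clean + rnorm(n_resp, 0, spec$resp_noise_sd)

    # beats: RR driven by respiration at the current beat onset
    max_beats <- ceiling(spec$duration / 0.3) + 1
    beat_t <- numeric(max_beats)
    rr <- numeric(max_beats)
    ar_noise <- 0
    t_cur <- 0; i <- 0
    resp_at <- function(t) {
      resp_clean[pmin(pmax(round(t * spec$resp_fs) + 1, 1), n_resp)]
    }
    while (TRUE) {
      ar_noise <- 0.8 * ar_noise + rnorm(1, 0, spec$rr_noise_sd * 0.6)
      r <- spec$mean_rr + spec$rsa_gain * resp_at(t_cur) + ar_noise
      r <- min(max(r, 0.301), 0.666)
      if (t_cur + r > spec$duration) break
      i <- i + 1
      rr[i] <- r
      t_cur <- t_cur + r
      beat_t[i] <- t_cur
    }
    n_beats <- i
    rr <- rr[1:n_beats]

    artifact_idx <- integer(0)
    if (spec$artifact_rate > 0) {
      # keep artifact beats isolated so ground truth stays unambiguous
      cand <- which(runif(n_beats) < spec$artifact_rate)
      cand <- cand[cand > 1 & cand < n_beats]
      keep <- cand[c(TRUE, diff(cand) > 2)]
      rr[keep] <- spec$artifact_rr
      artifact_idx <- keep
    }
    rpeak_times <- cumsum(c(0, rr))
    # injected long beats stretch the record; trim trailing beats so every
    # peak stays inside the respiration waveform span
    keep_n <- max(which(rpeak_times <= spec$duration))
    rpeak_times <- rpeak_times[seq_len(keep_n)]
    rr <- rr[seq_len(keep_n - 1)]
    artifact_idx <- artifact_idx[artifact_idx <= keep_n - 1]

    # optional RR -> RESP amplitude modulation from the previous beat
    if (spec$rr2resp_gain != 0) {
      amp <- rep(1, n_resp)
      dev <- c(0, rr - spec$mean_rr)
      bi <- findInterval(tt, rpeak_times)
      amp <- 1 + spec$rr2resp_gain * dev[pmax(bi, 1)]
      resp <- resp_clean * amp + rnorm(n_resp, 0, spec$resp_noise_sd)
    }

    structure(list(rpeak_times = rpeak_times, resp = resp,
                   resp_fs = spec$resp_fs, sleep_states = states,
                   ground_truth = list(rr_artifact_index = artifact_idx),
                   spec = spec),
              class = "physio_record")
  })
}

#' @export
print.physio_record <- function(x, ...) {
  cat("Cardiorespiratory record: ", length(x$rpeak_times), " R peaks over ",
      format(max(x$rpeak_times), digits = 4), " s, respiration at ",
      x$resp_fs, " Hz\n", sep = "")
  invisible(x)
}
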