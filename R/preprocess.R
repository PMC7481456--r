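#' RR intervals from R-peak times
#'
#' `RR(n)` is the interval between the n-th R peak and the next one, so the
#' series is one shorter than the peak list and `RR(n)` is anchored at the
#' n-th peak onset.
#'
#' @param rpeak_times numeric vector of R-peak times in seconds, strictly
#'   increasing.
#' @return Numeric vector of RR intervals in seconds.
#' @export
rr_from_peaks <- function(rpeak_times) {
  if (length(rpeak_times) < 2) stop("need at least two R peaks")
  rr <- diff(rpeak_times)
  if (any(rr <= 0)) {
    bad <- which(rr <= 0)[1] + 1
    stop("R-peak times must be strictly increasing (entry ", bad, ")")
  }
  rr
}

#' Band-pass filter a respiration waveform
#'
#' Zero-phase (forward-backward) Butterworth band-pass over the respiratory
#' band 0.05-3.5 Hz: removes baseline drift and out-of-band noise without
#' introducing group delay.
#'
#' @param resp sampled respiration waveform.
#' @param rate sampling rate in Hz (must exceed 7 Hz so the upper band edge
#'   stays below Nyquist).
#' @param band lower/upper passband edges in Hz (default `c(0.05, 3.5)`).
#' @param order Butterworth section order (default 2; forward-backward
#'   filtering doubles the effective order).
#' @return Filtered waveform, same length.
#' @export
bandpass_resp <- function(resp, rate, band = c(0.05, 3.5), order = 2) {
  stopifnot(is.numeric(resp), length(band) == 2, band[1] < band[2])
  if (rate <= 2 * band[2]) stop("sampling rate too low for the 3.5 Hz band edge")
  bf <- signal::butter(order, band / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, resp))
}

#' Resample a respiration waveform at given event times
#'
#' Linear interpolation of the waveform at the supplied times (typically
#' R-peak onsets, yielding one respiration value per heartbeat, aligned with
#' the RR series).
#'
#' @param resp sampled waveform.
#' @param rate sampling rate in Hz.
#' @param times event times in seconds; must lie within the waveform span.
#' @return Numeric vector, one interpolated value per time.
#' @export
resample_resp_at_peaks <- function(resp, rate, times) {
  tt <- (seq_along(resp) - 1) / rate
  if (any(times < tt[1] - 1e-9) || any(times > tt[length(tt)] + 1e-9))
    stop("event time outside the waveform span")
  approx(tt, resp, xout = pmin(pmax(times, tt[1]), tt[length(tt)]))$y
}

#' Respiratory cycle durations from zero crossings
#'
#' Cycle boundaries are the upward zero crossings of the (band-passed)
#' waveform, located by linear interpolation; a cycle's duration is the time
#' between consecutive boundaries.
#'
#' @param resp band-passed waveform.
#' @param rate sampling rate in Hz.
#' @return Data frame with `start`, `end` (s) and `duration` (s), one row
#'   per complete cycle.
#' @export
resp_cycle_durations <- function(resp, rate) {
  s <- sign(resp)
  up <- which(s[-length(s)] <= 0 & s[-1] > 0)
  if (length(up) < 2)
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0)))
  frac <- -resp[up] / (resp[up + 1] - resp[up])
  tcross <- (up - 1 + frac) / rate
  data.frame(start = tcross[-length(tcross)], end = tcross[-1],
             duration = diff(tcross))
}

#' Physiological artifact filter for RR and respiration
#'
#' A sample is rejected when it falls outside the physiological acceptance
#' range or when its relative change versus the previous *accepted* sample
#' exceeds the stated limit (so a single outlier does not cascade).
#' Defaults implement the neonatal rules: RR accepted within 0.3-0.667 s
#' with at most 10% beat-to-beat change; respiratory cycle durations
#' accepted within 0.5-2.5 s with at most 40% cycle-to-cycle change. A
#' segment is discarded when more than 5% of its samples are rejected.
#'
#' @param rr RR interval series in seconds.
#' @param resp_cycles optional vector (or data frame from
#'   [resp_cycle_durations()]) of respiratory cycle durations in seconds.
#' @param rr_range,resp_range acceptance ranges in seconds.
#' @param rr_rel,resp_rel maximum relative change vs. the previous accepted
#'   sample.
#' @param max_reject_frac rejected fraction above which the segment verdict
#'   is `discard` (default 0.05).
#' @return List with logical `rr_rejected`, optional `cycle_rejected`,
#'   `reject_fraction` (RR-based) and logical `discard`.
#' @export
artifact_filter <- function(rr, resp_cycles = NULL,
                            rr_range = c(0.3, 0.667), rr_rel = 0.10,
                            resp_range = c(0.5, 2.5), resp_rel = 0.40,
                            max_reject_frac = 0.05) {
  reject_series <- function(v, rng, rel) {
    rej <- logical(length(v))
    prev <- NA_real_
    for (i in seq_along(v)) {
      bad <- v[i] < rng[1] || v[i] > rng[2] ||
        (!is.na(prev) && abs(v[i] - prev) / prev > rel)
      rej[i] <- bad
      if (!bad) prev <- v[i]
    }
    rej
  }
  rr_rej <- reject_series(rr, rr_range, rr_rel)
  cyc_rej <- NULL
  if (!is.null(resp_cycles)) {
    dur <- if (is.data.frame(resp_cycles)) resp_cycles$duration
           else as.numeric(resp_cycles)
    cyc_rej <- reject_series(dur, resp_range, resp_rel)
  }
  frac <- mean(rr_rej)
  discard <- frac > max_reject_frac ||
    (!is.null(cyc_rej) && length(cyc_rej) > 0 &&
       mean(cyc_rej) > max_reject_frac)
  list(rr_rejected = rr_rej, cycle_rejected = cyc_rej,
       reject_fraction = frac, discard = discard)
}

# Full per-record quality mask: RR rules plus respiration-cycle rules mapped
# onto the beats falling inside rejected cycles.
record_quality_mask <- function(rr, rr_times, resp_filt, resp_fs, ...) {
  cycles <- resp_cycle_durations(resp_filt, resp_fs)
  af <- artifact_filter(rr, cycles, ...)
  mask <- af$rr_rejected
  if (nrow(cycles) > 0 && any(af$cycle_rejected)) {
    for (ci in which(af$cycle_rejected)) {
      inside <- rr_times >= cycles$start[ci] & rr_times < cycles$end[ci]
      mask[inside] <- TRUE
    }
  }
  list(mask = mask, rr_rejected = af$rr_rejected,
       cycle_rejected = af$cycle_rejected, cycles = cycles)
}

#' Build analysis-ready segment pairs from a cardiorespiratory record
#'
#' Runs the preprocessing chain: RR intervals from R peaks; respiration
#' band-passed (0.05-3.5 Hz) and resampled at each R-peak onset; artifact
#' rules applied to RR and to respiratory cycle durations (rejected cycles
#' flag the beats inside them); then, within each sleep-state bout,
#' consecutive non-overlapping windows of `L` beats are extracted
#' (earliest first). Windows with more than 5% flagged samples are
#' discarded; each emitted channel is z-normalized to zero mean and unit
#' (population) variance.
#'
#' @param record a `physio_record` (from [simulate_physio()] or
#'   [read_physio_record()]).
#' @param sleep_state optional state filter (e.g. `"QS"`); `NULL` keeps all.
#' @param L segment length in beats (default 300).
#' @param max_reject_frac flagged-sample fraction above which a window is
#'   discarded (default 0.05).
#' @return List of `segment_pair` objects: `rr` and `resp` (length `L`,
#'   z-normalized), plus provenance (`state`, `start_index`, `start_time`,
#'   `n_flagged`).
#' @export
segment_and_normalize <- function(record, sleep_state = NULL, L = 300,
                                  max_reject_frac = 0.05) {
  stopifnot(inherits(record, "physio_record"))
  if (is.null(record$sleep_states) || nrow(record$sleep_states) == 0)
    stop("record carries no sleep-state intervals")
  rr <- rr_from_peaks(record$rpeak_times)
  rr_times <- record$rpeak_times[-length(record$rpeak_times)]
  resp_filt <- bandpass_resp(record$resp, record$resp_fs)
  resp_beat <- resample_resp_at_peaks(resp_filt, record$resp_fs, rr_times)
  qm <- record_quality_mask(rr, rr_times, resp_filt, record$resp_fs)

  states <- record$sleep_states
  if (!is.null(sleep_state)) states <- states[states$state %in% sleep_state, ]
  segments <- list()
  for (b in seq_len(nrow(states))) {
    in_bout <- which(rr_times >= states$start[b] & rr_times < states$end[b])
    n_win <- length(in_bout) %/% L
    if (n_win < 1) next
    for (w in seq_len(n_win)) {
      idx <- in_bout[((w - 1) * L + 1):(w * L)]
      n_flag <- sum(qm$mask[idx])
      if (n_flag / L > max_reject_frac) next
      segments[[length(segments) + 1]] <- structure(
        list(rr = znorm(rr[idx]), resp = znorm(resp_beat[idx]),
             state = states$state[b], start_index = idx[1],
             start_time = rr_times[idx[1]], n_flagged = n_flag,
             L = L),
        class = "segment_pair")
    }
  }
  segments
}

#' @export
print.segment_pair <- function(x, ...) {
  cat("Segment pair (", x$L, " beats, state ", x$state, ", start beat ",
      x$start_index, ", ", x$n_flagged, " flagged)\n", sep = "")
  invisible(x)
}

#' Dominant breathing rate from a respiration waveform
#'
#' Periodogram peak within the respiratory band 0.2-2.0 Hz. The peak must
#' be prominent (peak power at least `prominence` times the median in-band
#' power); otherwise no dominant rhythm is declared and an error is raised.
#'
#' @param resp sampled waveform.
#' @param rate sampling rate in Hz.
#' @param window analysis window in seconds counted from the start of the
#'   signal; `NULL` uses the whole signal. At least 60 s are required.
#' @param band search band in Hz (default `c(0.2, 2.0)`).
#' @param prominence peak-to-median power ratio required to accept the peak
#'   (default 15).
#' @return Dominant respiratory frequency in Hz.
#' @export
breathing_rate <- function(resp, rate, window = NULL, band = c(0.2, 2.0),
                           prominence = 15) {
  if (!is.null(window)) resp <- resp[seq_len(min(length(resp), round(window * rate)))]
  if (length(resp) / rate < 60)
    stop("need at least 60 s of signal for a breathing-rate estimate")
  v <- resp - mean(resp)
  n <- length(v)
  pw <- Mod(fft(v))^2 / n
  freq <- (seq_len(n) - 1) * rate / n
  inband <- freq >= band[1] & freq <= band[2]
  if (!any(inband)) stop("no spectral support in the respiratory band")
  pk <- which.max(pw[inband])
  if (pw[inband][pk] < prominence * median(pw[inband]))
    stop("no dominant respiratory peak in ", band[1], "-", band[2], " Hz")
  freq[inband][pk]
}
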