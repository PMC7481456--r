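test_that("rr_from_peaks implements the inter-beat definition", {
  expect_equal(rr_from_peaks(c(0.0, 0.45, 0.91)), c(0.45, 0.46))
  expect_error(rr_from_peaks(1.0), "at least two")
  expect_error(rr_from_peaks(c(0, 0.5, 0.4)), "strictly increasing")
  expect_equal(rr_from_peaks(seq(0, 4, by = 0.4)), rep(0.4, 10))
})

test_that("band-pass keeps the respiratory band and rejects out-of-band", {
  rate <- 200
  t <- seq(0, 60, by = 1 / rate)
  inband <- sin(2 * pi * 0.7 * t)
  out <- bandpass_resp(inband, rate)
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  amp <- (max(out[mid]) - min(out[mid])) / 2
  expect_lt(abs(amp - 1), 0.05)
  # DC offset removed
  dc <- bandpass_resp(inband + 5, rate)
  expect_lt(abs(mean(dc[mid])), 0.05)
  # 20 Hz tone attenuated >= 20 dB
  hi <- sin(2 * pi * 20 * t)
  hout <- bandpass_resp(hi, rate)
  expect_lt(sqrt(mean(hout[mid]^2)) / sqrt(mean(hi[mid]^2)), 0.1)
  expect_error(bandpass_resp(inband, rate = 5), "too low")
})

test_that("resampling interpolates the waveform at event times", {
  rate <- 200
  t <- seq(0, 2, by = 1 / rate)
  w <- sin(2 * pi * t)
  expect_lt(abs(resample_resp_at_peaks(w, rate, 0.25) - 1), 1e-3)
  # exact grid point returns the sample
  expect_equal(resample_resp_at_peaks(w, rate, t[101]), w[101])
  # midpoint of a linear ramp
  ramp <- seq(0, 1, length.out = 201)
  expect_equal(resample_resp_at_peaks(ramp, 100, 0.005),
               (ramp[1] + ramp[2]) / 2, tolerance = 1e-12)
  expect_error(resample_resp_at_peaks(w, rate, 5), "outside")
})

test_that("artifact filter applies range and relative-change rules", {
  a <- artifact_filter(c(0.45, 0.46, 0.70, 0.45))
  expect_equal(which(a$rr_rejected), 3)
  expect_true(a$discard)  # 1/4 > 5%
  b <- artifact_filter(c(0.45, 0.55, 0.56, 0.55))
  expect_true(b$rr_rejected[2])  # 22% jump vs previous accepted
  # change is judged against the previous accepted sample (no cascade)
  c1 <- artifact_filter(c(0.45, 0.70, 0.46, 0.45))
  expect_equal(which(c1$rr_rejected), 2)
  clean <- artifact_filter(rep(c(0.44, 0.45, 0.46), 100))
  expect_equal(sum(clean$rr_rejected), 0)
  expect_false(clean$discard)
  # respiration cycle rules
  d <- artifact_filter(rep(0.45, 20), resp_cycles = c(1.2, 1.3, 3.0, 1.2))
  expect_equal(which(d$cycle_rejected), 3)
})

test_that("segmentation yields floor(n/300) windows and normalizes exactly", {
  rec <- simulate_physio(physio_sim_spec(duration = 600, bout_length = 300),
                         seed = 4)
  segs <- segment_and_normalize(rec)
  rr_t <- rec$rpeak_times[-length(rec$rpeak_times)]
  expected <- 0
  for (b in seq_len(nrow(rec$sleep_states)))
    expected <- expected +
      sum(rr_t >= rec$sleep_states$start[b] &
            rr_t < rec$sleep_states$end[b]) %/% 300
  expect_equal(length(segs), expected)
  s <- segs[[1]]
  expect_length(s$rr, 300)
  expect_lt(abs(mean(s$rr)), 1e-8)
  expect_lt(abs(sqrt(mean((s$rr - mean(s$rr))^2)) - 1), 1e-6)
  expect_lt(abs(mean(s$resp)), 1e-8)
  # state filtering
  qs <- segment_and_normalize(rec, sleep_state = "QS")
  expect_true(all(vapply(qs, function(x) x$state, "") == "QS"))
  expect_lt(length(qs), length(segs))
})

test_that("normalization is idempotent", {
  set.seed(5)
  v <- rnorm(300, 10, 4)
  z1 <- normalize_series(v)
  z2 <- normalize_series(z1)
  expect_lt(max(abs(z1 - z2)), 1e-12)
})

test_that("breathing_rate finds the dominant respiratory peak", {
  rate <- 200
  t <- seq(0, 120, by = 1 / rate)
  expect_lt(abs(breathing_rate(sin(2 * pi * 0.8 * t), rate) - 0.8), 0.02)
  two <- sin(2 * pi * 0.8 * t) + 0.3 * sin(2 * pi * 0.3 * t)
  expect_lt(abs(breathing_rate(two, rate) - 0.8), 0.02)
  set.seed(6)
  expect_error(breathing_rate(rnorm(length(t)), rate), "dominant")
  expect_error(breathing_rate(sin(2 * pi * 0.8 * t[1:2000]), rate),
               "60 s")
})

test_that("breathing rate differs by sleep state in the generator", {
  rec <- simulate_physio(physio_sim_spec(duration = 600, bout_length = 150),
                         seed = 7)
  tt <- (seq_along(rec$resp) - 1) / rec$resp_fs
  qs1 <- rec$resp[tt >= 0 & tt < 150]
  as1 <- rec$resp[tt >= 150 & tt < 300]
  f_qs <- breathing_rate(qs1, rec$resp_fs)
  f_as <- breathing_rate(as1, rec$resp_fs)
  expect_gt(f_as, f_qs)
})
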