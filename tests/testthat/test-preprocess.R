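test_that("bandpass attenuates out-of-band content and preserves length", {
  fs <- 250
  tt <- (0:5999) / fs
  slow <- sin(2 * pi * 0.1 * tt)
  out <- bandpass(slow, fs, PPG_BAND[1], PPG_BAND[2])
  expect_length(out, length(slow))
  expect_lt(sqrt(mean(out^2)), 0.1 * sqrt(mean(slow^2)))
  # DC is outside both bands
  dc <- rep(1, 3000)
  expect_lt(max(abs(bandpass(dc, fs, 5, 30))), 1e-3)
  expect_lt(max(abs(bandpass(dc, fs, 0.8, 11))), 1e-3)
  expect_error(bandpass(slow, fs, 5, 200), "band edges")
})

test_that("filtering is zero-phase: symmetric peaks stay put", {
  fs <- 250
  tt <- (0:4999) / fs
  # symmetric Gaussian pulse centered at a known sample
  k <- 2501
  pulse <- exp(-((tt - tt[k])^2) / (2 * 0.05^2))
  for (band in list(PPG_BAND, ECG_BAND)) {
    filt <- bandpass(pulse, fs, band[1], band[2])
    expect_lte(abs(which.max(filt) - k), 1)
  }
  # in-band tone: cross-correlation with the input peaks at lag 0
  tone <- sin(2 * pi * 4 * tt)
  filt <- bandpass(tone, fs, PPG_BAND[1], PPG_BAND[2])
  cc <- ccf(filt, tone, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("R-peak detection matches simulator truth at 60 and 120 bpm", {
  for (hr in c(60, 120)) {
    rec <- fixture_recording(seed = hr, heart_rate = hr)
    ecg_f <- bandpass(rec$ecg, rec$fs, ECG_BAND[1], ECG_BAND[2])
    peaks <- detect_r_peaks(ecg_f, rec$fs)
    truth <- rec$truth$r_peak_times
    expect_true(abs(length(peaks) - length(truth)) <= 1)
    err <- vapply((peaks - 1) / rec$fs,
                  function(t) min(abs(truth - t)) * rec$fs, 0)
    expect_true(all(err <= 1))
    expect_true(all(diff(peaks) / rec$fs >= 0.25))
  }
  expect_identical(detect_r_peaks(numeric(6000), 250), integer(0))
})

test_that("beat segmentation drops partial boundary beats", {
  rec <- fixture_recording(seed = 13)  # HR 60, ~24 peaks
  pp <- preprocess_recording(rec)
  np <- length(pp$r_peaks)
  beats <- segment_beats(pp$ecg_f, pp$ppg_f, pp$r_peaks, rec$fs)
  expect_equal(length(beats), np - 2)
  expect_true(length(beats) >= 21 && length(beats) <= 23)
  # uniform RR intervals give equal segment lengths
  peaks_u <- seq(100L, 5800L, by = 250L)
  x <- sin(2 * pi * (0:5999) / 250)
  beats_u <- segment_beats(x, x, peaks_u, 250)
  expect_length(unique(lengths(lapply(beats_u, `[[`, "ppg_segment"))), 1L)
  # every clean beat holds exactly one interior derivative maximum
  for (b in beats) {
    d <- diff(b$ppg_segment)
    expect_gt(which.max(d), 1)
    expect_lt(which.max(d), length(d))
  }
  expect_identical(segment_beats(x, x, c(10L, 400L), 250), list())
})

test_that("beat scoring selects the consistent beats and gates on quality", {
  # identical beats correlate perfectly
  seg <- fixture_pulse_segment()
  beats <- lapply(1:22, function(i)
    list(index = i, r_peak_index = i * 250L, r_peak_time = i,
         ecg_segment = seg, ppg_segment = seg, quality = NA_real_))
  ss <- score_and_select_beats(beats)
  expect_true(all(abs(ss$quality - 1) < 1e-12))
  expect_length(ss$selected, 10)
  expect_true(ss$qc$passed)

  # noise-burst beats are never selected and do not disturb the ranking
  set.seed(31)
  noisy <- lapply(23:25, function(i)
    list(index = i, r_peak_index = i * 250L, r_peak_time = i,
         ecg_segment = seg, ppg_segment = rnorm(length(seg)),
         quality = NA_real_))
  ss2 <- score_and_select_beats(c(beats, noisy))
  sel_idx <- vapply(ss2$selected, `[[`, 0L, "index")
  expect_true(all(sel_idx <= 22))

  # too few beats
  ss3 <- score_and_select_beats(beats[1:5])
  expect_false(ss3$qc$passed)
  expect_identical(ss3$qc$reject_reason, "too_few_beats")
  expect_length(ss3$selected, 0)
})

test_that("the gate applies an inclusive threshold", {
  qc <- structure(list(n_beats_selected = 10L, pairwise_corr_min = 0.99),
                  class = "bp_measurement_qc")
  expect_true(gate_measurement(qc, 0.90))
  qc$pairwise_corr_min <- 0.90
  expect_true(gate_measurement(qc, 0.90))   # boundary passes
  qc$pairwise_corr_min <- 0.40
  expect_false(gate_measurement(qc, 0.90))
  qc$pairwise_corr_min <- 0.99
  qc$n_beats_selected <- 9L
  expect_false(gate_measurement(qc, 0.90))
})

test_that("clean recordings always pass QC; heavily corrupted ones never do", {
  co <- simulate_cohort(cohort_spec(50, seed = 17))
  pass_clean <- logical(50)
  pass_bad <- logical(50)
  modes <- c("noise_burst", "flatline_segment", "saturation")
  for (i in 1:50) {
    rec <- simulate_recording(as.list(co[i, ]), seed = 1000 + i)
    pass_clean[i] <- preprocess_recording(rec)$qc$passed
    bad <- corrupt_recording(rec, modes[(i %% 3) + 1], seed = 2000 + i,
                             span_frac = 0.35)
    pass_bad[i] <- preprocess_recording(bad)$qc$passed
  }
  expect_true(all(pass_clean))
  expect_false(any(pass_bad))
})
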