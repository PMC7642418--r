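#' Default denoising bands
#'
#' Passbands used to denoise the two channels before beat separation:
#' 0.8--11 Hz for the PPG and 5--30 Hz for the ECG, applied as zero-phase
#' Butterworth filters.
#' @name bands
NULL

#' @rdname bands
#' @export
PPG_BAND <- c(0.8, 11)

#' @rdname bands
#' @export
ECG_BAND <- c(5, 30)

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth bandpass applied forward and backward
#' (`signal::filtfilt`), giving zero phase delay and an effective 8th-order
#' magnitude response. Output length equals input length, and symmetric
#' waveform peaks are not displaced.
#'
#' @param x Numeric sample series.
#' @param fs Sampling rate (Hz).
#' @param low,high Band edges (Hz), 0 < low < high < fs/2.
#' @param order Filter order before the forward-backward pass.
#' @return Filtered series, same length as `x`.
#' @export
bandpass <- function(x, fs, low, high, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  ## odd-reflection padding absorbs the forward-backward edge transients
  ## (the 0.8 Hz high-pass edge settles slowly relative to a 24-s record)
  n <- length(x)
  p <- min(n - 1, round(3 * fs / low))
  if (p > 0) {
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    y <- signal::filtfilt(bf, xp)
    as.numeric(y[(p + 1):(p + n)])
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

#' Detect ECG R-peaks
#'
#' Derivative-energy detector in the spirit of Pan-Tompkins: the squared
#' first difference of the (already bandpassed) ECG is smoothed with a
#' 100-ms moving average, regions above an adaptive threshold (a fraction
#' of the global maximum energy) are localized, each candidate is refined
#' to the local ECG maximum, and a 0.25-s refractory period is enforced
#' (strongest-peak-first).
#'
#' @param ecg Bandpassed ECG samples.
#' @param fs Sampling rate (Hz).
#' @param threshold_frac Energy threshold as a fraction of the maximum.
#' @param refractory_s Minimum spacing between accepted peaks (s).
#' @return Integer vector of strictly increasing peak indices (1-based);
#'   empty when no peak is found.
#' @export
detect_r_peaks <- function(ecg, fs, threshold_frac = 0.2, refractory_s = 0.25) {
  n <- length(ecg)
  if (n < 3 || max(abs(ecg)) < 1e-9) return(integer(0))
  energy <- c(0, diff(ecg))^2
  w <- max(3L, round(0.1 * fs))
  kern <- rep(1 / w, w)
  sm <- stats::filter(energy, kern, sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  thr <- threshold_frac * max(sm)
  above <- sm > thr
  if (!any(above)) return(integer(0))
  ## contiguous supra-threshold runs -> one candidate each
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  margin <- round(0.06 * fs)
  cand <- integer(0)
  for (k in runs) {
    lo <- max(1L, starts[k] - margin)
    hi <- min(n, ends[k] + margin)
    cand <- c(cand, lo - 1L + which.max(ecg[lo:hi]))
  }
  cand <- unique(cand)
  ## refractory: keep strongest first
  ord <- order(ecg[cand], decreasing = TRUE)
  keep <- integer(0)
  min_gap <- round(refractory_s * fs)
  for (i in cand[ord]) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Separate an ECG/PPG recording into per-beat segments
#'
#' One beat per R-peak, windowed from that R-peak to 90% (by default) of
#' the local RR interval, so the window always contains the beat's PPG
#' upstroke but not the next beat's. The first and last beats are dropped
#' as partial.
#'
#' @param ecg,ppg Bandpassed channels of equal length.
#' @param r_peaks Strictly increasing R-peak indices.
#' @param fs Sampling rate (Hz).
#' @param window_frac Fraction of the local RR interval retained.
#' @return List of beats, each a list with `index`, `r_peak_index`,
#'   `r_peak_time` (s), `ecg_segment`, `ppg_segment`, `quality` (filled by
#'   [score_and_select_beats()]). Fewer than 3 peaks give an empty list.
#' @export
segment_beats <- function(ecg, ppg, r_peaks, fs, window_frac = 0.9) {
  stopifnot(length(ecg) == length(ppg))
  np <- length(r_peaks)
  if (np < 3) return(list())
  beats <- list()
  for (i in 2:(np - 1)) {
    rr <- r_peaks[i + 1] - r_peaks[i]
    len <- floor(window_frac * rr)
    lo <- r_peaks[i]
    hi <- lo + len - 1L
    if (hi > length(ppg) || len < 4) next
    beats[[length(beats) + 1L]] <- list(
      index = length(beats) + 1L,
      r_peak_index = r_peaks[i],
      r_peak_time = (r_peaks[i] - 1) / fs,
      ecg_segment = ecg[lo:hi],
      ppg_segment = ppg[lo:hi],
      quality = NA_real_
    )
  }
  beats
}

## resample a segment onto a fixed grid over its own duration, so beats of
## unequal RR length become comparable
.resample_segment <- function(x, n_points = 100L) {
  if (length(x) == n_points) return(x)
  approx(seq(0, 1, length.out = length(x)), x,
         xout = seq(0, 1, length.out = n_points))$y
}

## Pearson correlation with the convention that a zero-variance segment
## correlates at 0 with everything (a flatlined beat is maximally unlike a
## pulse, not undefined)
.safe_cor <- function(m) {
  s <- apply(m, 2, sd)
  ok <- s > 1e-12
  cc <- matrix(0, ncol(m), ncol(m))
  if (any(ok)) cc[ok, ok] <- cor(m[, ok, drop = FALSE])
  diag(cc) <- 1
  cc
}

#' Score beats by inter-beat PPG correlation and select the best
#'
#' Each beat's PPG segment is resampled to a fixed 100-point grid and its
#' quality is the mean Pearson correlation against every other beat's
#' resampled segment ("spatial correlation" across beats). The `n_select`
#' highest-quality beats are returned, and the measurement-level QC record
#' summarizes the selected beats' qualities. Because quality is computed
#' against *all* beats, a measurement where a substantial fraction of beats
#' is corrupted drags every beat's quality down and fails the gate, even if
#' ten mutually consistent beats survive.
#'
#' @param beats Output of [segment_beats()] (non-empty).
#' @param n_select Number of beats to keep (default 10 per 24-s
#'   measurement).
#' @param threshold Quality threshold used to fill the QC `passed` flag
#'   (see [gate_measurement()]).
#' @return List with `selected` (list of beats, quality filled), `qc` (a
#'   `bp_measurement_qc` list: n_beats_detected, n_beats_selected,
#'   pairwise_corr_min, pairwise_corr_mean, passed, reject_reason) and
#'   `quality` (the score of every input beat, in input order).
#' @export
score_and_select_beats <- function(beats, n_select = 10L, threshold = 0.90) {
  if (length(beats) == 0) stop("beats must be non-empty")
  qc <- structure(list(n_beats_detected = length(beats),
                       n_beats_selected = 0L,
                       pairwise_corr_min = NA_real_,
                       pairwise_corr_mean = NA_real_,
                       passed = FALSE,
                       reject_reason = NA_character_),
                  class = "bp_measurement_qc")
  if (length(beats) < n_select) {
    qc$reject_reason <- "too_few_beats"
    return(list(selected = list(), qc = qc))
  }
  m <- vapply(beats, function(b) .resample_segment(b$ppg_segment),
              numeric(100L))
  cc <- .safe_cor(m)
  quality <- (rowSums(cc) - 1) / (length(beats) - 1)
  for (i in seq_along(beats)) beats[[i]]$quality <- quality[i]
  ord <- order(quality, decreasing = TRUE)
  sel <- sort(ord[seq_len(n_select)])  # keep temporal order
  qsel <- quality[sel]
  qc$n_beats_selected <- as.integer(n_select)
  qc$pairwise_corr_min <- min(qsel)
  qc$pairwise_corr_mean <- mean(qsel)
  qc$passed <- gate_measurement(qc, threshold)
  if (!qc$passed) qc$reject_reason <- "low_correlation"
  list(selected = beats[sel], qc = qc, quality = quality)
}

#' Gate a measurement on its quality-control record
#'
#' A measurement passes iff ten beats were selected and the minimum
#' selected-beat quality is at or above the threshold (a value exactly at
#' the threshold passes).
#'
#' @param qc A `bp_measurement_qc` record.
#' @param threshold Correlation threshold (default 0.90).
#' @return Logical.
#' @export
gate_measurement <- function(qc, threshold = 0.90) {
  isTRUE(qc$n_beats_selected == 10L) &&
    is.finite(qc$pairwise_corr_min) &&
    qc$pairwise_corr_min >= threshold
}

#' Run the full preprocessing chain on one recording
#'
#' Bandpass both channels, detect R-peaks, segment beats, score and select
#' the ten best.
#'
#' @param rec A `bp_recording`.
#' @param n_select,threshold See [score_and_select_beats()].
#' @return List with `selected`, `qc`, `r_peaks`, `heart_rate` (beats/min,
#'   from the median RR interval), `ecg_f`, `ppg_f`.
#' @export
preprocess_recording <- function(rec, n_select = 10L, threshold = 0.90) {
  ecg_f <- bandpass(rec$ecg, rec$fs, ECG_BAND[1], ECG_BAND[2])
  ppg_f <- bandpass(rec$ppg, rec$fs, PPG_BAND[1], PPG_BAND[2])
  r_peaks <- detect_r_peaks(ecg_f, rec$fs)
  beats <- segment_beats(ecg_f, ppg_f, r_peaks, rec$fs)
  hr <- if (length(r_peaks) >= 2) 60 / (median(diff(r_peaks)) / rec$fs) else NA_real_
  if (length(beats) == 0) {
    qc <- structure(list(n_beats_detected = 0L, n_beats_selected = 0L,
                         pairwise_corr_min = NA_real_,
                         pairwise_corr_mean = NA_real_,
                         passed = FALSE, reject_reason = "too_few_beats"),
                    class = "bp_measurement_qc")
    return(list(selected = list(), qc = qc, r_peaks = r_peaks,
                heart_rate = hr, ecg_f = ecg_f, ppg_f = ppg_f))
  }
  ss <- score_and_select_beats(beats, n_select = n_select, threshold = threshold)
  c(ss, list(r_peaks = r_peaks, heart_rate = hr, ecg_f = ecg_f, ppg_f = ppg_f))
}
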