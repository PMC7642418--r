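#' Pulse transit time of one beat
#'
#' PTT is the interval from the ECG R-peak to the peak of the PPG first
#' derivative within the same beat. Beat segments are anchored at the
#' R-peak, so PTT is simply the time of the derivative maximum within the
#' segment. The derivative is a central difference; a maximum at the
#' segment boundary (no interior upstroke, e.g. a pure ramp) flags the
#' beat invalid and returns `NA`.
#'
#' @param beat One beat from [segment_beats()].
#' @param fs Sampling rate (Hz).
#' @return PTT in seconds, or `NA_real_` for an invalid beat.
#' @export
compute_ptt <- function(beat, fs) {
  x <- beat$ppg_segment
  n <- length(x)
  if (n < 5) return(NA_real_)
  d <- (x[3:n] - x[1:(n - 2)]) / 2  # derivative at samples 2..n-1
  imax <- which.max(d)
  ## boundary or tied-flat derivative -> invalid
  if (imax == 1L || imax == length(d)) return(NA_real_)
  if (max(d) - min(d) < 1e-12 * max(abs(x), 1e-300)) return(NA_real_)
  ptt <- (imax + 1L - 1L) / fs  # derivative index i corresponds to sample i+1
  if (ptt <= 0) return(NA_real_)
  ptt
}

#' Normalized PPG band spectrum of a beat segment
#'
#' Power spectrum of the mean-removed segment at its natural frequency
#' resolution (rectangular window; a tone completing whole cycles in the
#' segment therefore lands in a single bin with no leakage), integrated
#' over `n_bands` equal-width bands spanning the PPG passband
#' 0.8--11 Hz and normalized to sum to 1. The normalization makes the
#' feature invariant to PPG gain.
#'
#' @param ppg_segment Beat PPG samples (length >= 16).
#' @param fs Sampling rate (Hz).
#' @param n_bands Number of bands (default 8).
#' @param band Frequency span (Hz).
#' @return Numeric vector of length `n_bands`, summing to 1.
#' @export
ppg_spectrum_features <- function(ppg_segment, fs, n_bands = 8L,
                                  band = PPG_BAND) {
  n <- length(ppg_segment)
  if (n < 16) stop("segment must have at least 16 samples")
  x <- ppg_segment - mean(ppg_segment)
  if (max(abs(x)) < 1e-300 || sd(ppg_segment) == 0) {
    stop("all-constant segment: spectrum normalization undefined")
  }
  nfft <- max(64L, n)  # pad only very short segments for band coverage
  xp <- c(x, numeric(nfft - n))
  mag <- Mod(fft(xp))[seq_len(nfft %/% 2 + 1L)]^2
  freq <- (seq_len(nfft %/% 2 + 1L) - 1) * fs / nfft
  edges <- seq(band[1], band[2], length.out = n_bands + 1L)
  out <- numeric(n_bands)
  for (k in seq_len(n_bands)) {
    inb <- freq >= edges[k] & (if (k == n_bands) freq <= edges[k + 1]
                               else freq < edges[k + 1])
    out[k] <- sum(mag[inb])
  }
  tot <- sum(out)
  if (tot <= 0) stop("no spectral mass inside the band")
  out / tot
}

#' Morphological descriptors of one PPG pulse
#'
#' Seven fixed descriptors of the beat's PPG segment, measured relative to
#' the segment minimum (baseline):
#' \describe{
#'   \item{sys_amp}{systolic amplitude, max - min (signal units)}
#'   \item{width_half}{pulse width at half height (s)}
#'   \item{rise_time}{foot (pre-peak minimum) to peak (s)}
#'   \item{decay_time}{peak to post-peak minimum (s)}
#'   \item{area_norm}{area under the pulse normalized by amplitude and
#'     duration (unitless, in \[0,1\])}
#'   \item{max_upslope}{maximum first derivative (signal units/s)}
#'   \item{downslope_ratio}{|minimum derivative| / maximum derivative
#'     (unitless)}
#' }
#' Amplitude and slope scale linearly with PPG gain; widths, times and
#' ratios are gain-invariant.
#'
#' @param ppg_segment Beat PPG samples.
#' @param fs Sampling rate (Hz).
#' @return Named numeric vector of length 7.
#' @export
morphological_features <- function(ppg_segment, fs) {
  x <- ppg_segment
  if (any(!is.finite(x))) stop("non-finite values in segment")
  n <- length(x)
  if (n < 5) stop("segment too short")
  base <- min(x)
  amp <- max(x) - base
  ipk <- which.max(x)
  foot <- which.min(x[seq_len(ipk)])
  tail_min <- if (ipk < n) ipk - 1L + which.min(x[ipk:n]) else n
  half <- base + amp / 2
  above <- which(x >= half)
  width <- if (length(above)) {
    i1 <- min(above); i2 <- max(above)
    # linear interpolation of the two half-height crossings
    left <- if (i1 > 1) i1 - (x[i1] - half) / (x[i1] - x[i1 - 1]) else i1
    right <- if (i2 < n) i2 + (x[i2] - half) / (x[i2] - x[i2 + 1]) else i2
    (right - left) / fs
  } else 0
  d <- if (n >= 3) (x[3:n] - x[1:(n - 2)]) * fs / 2 else c(0, 0)
  up <- max(d)
  down_ratio <- if (up > 0) abs(min(d)) / up else NA_real_
  c(sys_amp = amp,
    width_half = width,
    rise_time = (ipk - foot) / fs,
    decay_time = (tail_min - ipk) / fs,
    area_norm = if (amp > 0) mean(x - base) / amp else 0,
    max_upslope = up,
    downslope_ratio = down_ratio)
}

#' Feature schema
#'
#' Column names of the per-beat feature table, in order: PTT, the
#' `n_bands` spectral bands, the seven morphology descriptors, heart rate
#' and the four demographic entries.
#'
#' @param n_bands Number of spectral bands.
#' @return Character vector of feature names.
#' @export
feature_schema <- function(n_bands = 8L) {
  c("ptt", paste0("spec_", seq_len(n_bands)),
    "sys_amp", "width_half", "rise_time", "decay_time", "area_norm",
    "max_upslope", "downslope_ratio",
    "heart_rate", "age", "sex_code", "height", "weight")
}

#' Assemble per-beat feature vectors for one measurement
#'
#' Computes PTT, spectral and morphological features for each selected
#' beat and broadcasts the subject demographics (age, sex coded M=1/F=0,
#' height, weight) and the measurement heart rate to every beat. Beats
#' whose PTT is invalid or whose features are non-finite are dropped (on a
#' QC-passed clean measurement none are).
#'
#' @param beats Selected beats ([score_and_select_beats()]).
#' @param demographics List or one-row data frame with `age`, `sex`
#'   (`"M"`/`"F"` or 0/1), `height`, `weight`.
#' @param heart_rate Measurement heart rate (beats/min).
#' @param fs Sampling rate (Hz).
#' @param n_bands Number of spectral bands.
#' @return Data frame, one row per valid beat, columns per
#'   [feature_schema()].
#' @export
assemble_features <- function(beats, demographics, heart_rate, fs,
                              n_bands = 8L) {
  demographics <- as.list(demographics)
  need <- c("age", "sex", "height", "weight")
  miss <- setdiff(need, names(demographics))
  if (length(miss)) stop("missing demographic field(s): ",
                         paste(miss, collapse = ", "))
  sex_code <- if (is.character(demographics$sex)) {
    match(demographics$sex, c("F", "M")) - 1L
  } else as.numeric(demographics$sex)
  if (is.na(sex_code)) stop("sex must be 'M'/'F' or 0/1")
  rows <- lapply(beats, function(b) {
    ptt <- compute_ptt(b, fs)
    if (is.na(ptt)) return(NULL)
    sp <- ppg_spectrum_features(b$ppg_segment, fs, n_bands = n_bands)
    mo <- morphological_features(b$ppg_segment, fs)
    v <- c(ptt = ptt, sp, mo, heart_rate = heart_rate,
           age = demographics$age, sex_code = sex_code,
           height = demographics$height, weight = demographics$weight)
    if (any(!is.finite(v))) return(NULL)
    v
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    out <- as.data.frame(matrix(numeric(0), nrow = 0,
                                ncol = length(feature_schema(n_bands))))
    names(out) <- feature_schema(n_bands)
    return(out)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- feature_schema(n_bands)
  out
}
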