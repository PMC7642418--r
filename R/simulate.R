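#' Noise configuration for simulated recordings
#'
#' Describes the additive disturbances applied to a simulated ECG/PPG
#' recording: broadband white noise, low-frequency baseline wander
#' (respiration/motion), powerline interference on the ECG channel, and an
#' optional bad-contact corruption of the PPG (emulating unstable contact
#' between the optical sensor and the wrist).
#'
#' @param white_noise_sd Standard deviation of additive Gaussian noise, in
#'   signal units (the clean QRS and PPG pulse have unit amplitude).
#' @param baseline_wander_amp,baseline_wander_freq Amplitude (signal units)
#'   and frequency (Hz, must be below 0.8 Hz so the denoising band can
#'   remove it) of a sinusoidal baseline drift.
#' @param powerline_amp,powerline_freq Amplitude and frequency (45--65 Hz)
#'   of mains interference added to the ECG channel.
#' @param bad_contact Logical; if `TRUE` a contiguous noise burst covering
#'   `bad_contact_frac` of the PPG is applied (see [corrupt_recording()]).
#' @param bad_contact_frac Fraction of the PPG corrupted when
#'   `bad_contact` is `TRUE`.
#' @return An object of class `bp_noise_config`.
#' @export
noise_config <- function(white_noise_sd = 0,
                         baseline_wander_amp = 0, baseline_wander_freq = 0.25,
                         powerline_amp = 0, powerline_freq = 50,
                         bad_contact = FALSE, bad_contact_frac = 0.35) {
  stopifnot(white_noise_sd >= 0, baseline_wander_amp >= 0, powerline_amp >= 0)
  if (baseline_wander_freq <= 0 || baseline_wander_freq >= 0.8) {
    stop("baseline_wander_freq must lie in (0, 0.8) Hz")
  }
  if (powerline_freq < 45 || powerline_freq > 65) {
    stop("powerline_freq must lie within 45-65 Hz")
  }
  structure(list(white_noise_sd = white_noise_sd,
                 baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_freq = baseline_wander_freq,
                 powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq,
                 bad_contact = isTRUE(bad_contact),
                 bad_contact_frac = bad_contact_frac),
            class = "bp_noise_config")
}

#' Cohort specification for the synthetic study population
#'
#' BP marginals default to the manual-sphygmomanometer distribution of the
#' validation cohort the package emulates (SBP 129.6 +/- 23.6 mmHg,
#' DBP 69.5 +/- 12.9 mmHg), so simulated studies span a realistic range of
#' normotensive and hypertensive pressures.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd BP marginals in mmHg.
#' @param sbp_dbp_cor Correlation between SBP and DBP draws.
#' @param age_range Two-element vector of ages (years), sampled uniformly.
#' @param height_mean,height_sd,weight_mean,weight_sd Demographics (cm, kg).
#' @param hr_mean,hr_sd Resting heart rate (beats/min), clipped to
#'   \[40, 180\].
#' @param ptt_intercept_mean,ptt_intercept_sd Per-subject intercept `a` (s)
#'   of the pulse-transit-time relation PTT = a - b * SBP. The sd encodes
#'   inter-subject offsets of the PTT-BP relation that a factory-trained
#'   model cannot know and per-subject calibration must absorb
#'   (0.004 s is about 4 mmHg at the default slope).
#' @param ptt_slope Slope `b` in s/mmHg (positive; PTT falls as BP rises).
#' @param beat_jitter_sd Beat-to-beat RR-interval jitter (s).
#' @param noise_cfg A [noise_config()].
#' @param seed Integer seed; identical spec + seed gives identical cohorts.
#' @return An object of class `bp_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        sbp_mean = 129.6, sbp_sd = 23.6,
                        dbp_mean = 69.5, dbp_sd = 12.9,
                        sbp_dbp_cor = 0.6,
                        age_range = c(20, 85),
                        height_mean = 162.2, height_sd = 8.6,
                        weight_mean = 67.5, weight_sd = 12.3,
                        hr_mean = 70, hr_sd = 8,
                        ptt_intercept_mean = 0.45, ptt_intercept_sd = 0.004,
                        ptt_slope = 0.001,
                        beat_jitter_sd = 0.01,
                        noise_cfg = noise_config(),
                        seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1) stop("n_subjects must be >= 1")
  stopifnot(sbp_sd >= 0, dbp_sd >= 0, ptt_slope > 0,
            length(age_range) == 2, age_range[1] <= age_range[2])
  structure(as.list(environment()), class = "bp_cohort_spec")
}

#' Simulate a cohort of subject profiles
#'
#' Draws subjects with demographics, true BP, heart rate and an individual
#' PTT-BP relation. BP pairs are drawn from a correlated bivariate normal
#' and reject-resampled until SBP > DBP + 10 and the implied PTT is
#' positive across the subject's pressure, so the stated marginal means are
#' kept approximately.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per subject (class
#'   `bp_cohort`): subject_id, age, sex, height, weight, true_sbp,
#'   true_dbp, heart_rate, ptt_intercept, ptt_slope, beat_jitter_sd.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "bp_cohort_spec"))
  n <- as.integer(spec$n_subjects)
  withr::with_seed(spec$seed, {
    draw_bp <- function(m) {
      z1 <- rnorm(m)
      z2 <- spec$sbp_dbp_cor * z1 + sqrt(1 - spec$sbp_dbp_cor^2) * rnorm(m)
      cbind(sbp = spec$sbp_mean + spec$sbp_sd * z1,
            dbp = spec$dbp_mean + spec$dbp_sd * z2)
    }
    a <- rnorm(n, spec$ptt_intercept_mean, spec$ptt_intercept_sd)
    bp <- draw_bp(n)
    bad <- which(bp[, 1] <= bp[, 2] + 10 | a - spec$ptt_slope * bp[, 1] <= 0.05)
    while (length(bad) > 0) {
      bp[bad, ] <- draw_bp(length(bad))
      bad <- bad[bp[bad, 1] <= bp[bad, 2] + 10 |
                   a[bad] - spec$ptt_slope * bp[bad, 1] <= 0.05]
    }
    hr <- pmin(pmax(rnorm(n, spec$hr_mean, spec$hr_sd), 40), 180)
    cohort <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = round(runif(n, spec$age_range[1], spec$age_range[2]), 1),
      sex = sample(c("M", "F"), n, replace = TRUE),
      height = rnorm(n, spec$height_mean, spec$height_sd),
      weight = rnorm(n, spec$weight_mean, spec$weight_sd),
      true_sbp = bp[, 1],
      true_dbp = bp[, 2],
      heart_rate = hr,
      ptt_intercept = a,
      ptt_slope = spec$ptt_slope,
      beat_jitter_sd = spec$beat_jitter_sd,
      stringsAsFactors = FALSE
    )
    class(cohort) <- c("bp_cohort", "data.frame")
    cohort
  })
}

## PPG pulse template: gamma-shaped rise with exponential decay,
## g(t) = (t/tau)^k exp(-t/tau). Its first derivative peaks at
## t = tau * (k - sqrt(k)) after pulse onset (closed form), which anchors
## the ground-truth pulse transit time exactly.
.ppg_tau <- 0.045
.ppg_k <- 4

#' Evaluate the canonical PPG pulse template
#'
#' Unit-amplitude gamma-shaped pulse used by the simulator; exposed so
#' tests can build analytic oracles for the morphology features.
#'
#' @param t Time since pulse onset (s); values < 0 return 0.
#' @param tau,k Shape parameters.
#' @return Numeric vector of template values, peak normalized to 1.
#' @export
ppg_pulse_template <- function(t, tau = .ppg_tau, k = .ppg_k) {
  out <- numeric(length(t))
  pos <- t > 0
  u <- t[pos] / tau
  out[pos] <- (u^k * exp(-u)) / (k^k * exp(-k))
  out
}

#' Offset from pulse onset to the PPG first-derivative peak
#'
#' Closed form `tau * (k - sqrt(k))` for the template of
#' [ppg_pulse_template()].
#' @param tau,k Template parameters.
#' @return Offset in seconds.
#' @export
ppg_deriv_peak_offset <- function(tau = .ppg_tau, k = .ppg_k) {
  tau * (k - sqrt(k))
}

#' Simulate one two-channel ECG/PPG recording
#'
#' Generates a 24-s (by default) recording for one subject. The ECG is a
#' train of Gaussian bumps (P, QRS, T) per beat with the QRS dominant; the
#' PPG is a train of asymmetric pulses whose first-derivative peak lags
#' each R-peak by the subject's pulse transit time
#' PTT = a - b * SBP (plus small per-beat noise). A `truth` block carries
#' exact R-peak times, per-beat PTT and the momentary true BP, so
#' downstream detectors have an oracle.
#'
#' @param profile One row of a [simulate_cohort()] data frame (or a list
#'   with the same fields).
#' @param fs Sampling rate (Hz, >= 125).
#' @param duration Recording length (s).
#' @param noise A [noise_config()].
#' @param seed Integer seed.
#' @param bp_offset_mmhg Momentary BP offset (mmHg) applied to this
#'   measurement: the protocol simulator uses it to inject measurement-level
#'   BP fluctuation and device bias. The truth block reports the shifted
#'   (momentary) BP.
#' @param ptt_beat_noise_sd Per-beat PTT noise (s).
#' @return An object of class `bp_recording`: list with subject_id, fs,
#'   duration, ecg, ppg, and truth (r_peak_times, ptt, true_sbp, true_dbp).
#' @export
simulate_recording <- function(profile, fs = 250, duration = 24,
                               noise = noise_config(), seed = 1L,
                               bp_offset_mmhg = 0,
                               ptt_beat_noise_sd = 0.002) {
  profile <- as.list(profile)
  if (fs < 125) stop("fs must be >= 125 Hz")
  if (duration <= 2 * 60 / profile$heart_rate) {
    stop("duration must cover more than 2 beats")
  }
  sbp <- profile$true_sbp + bp_offset_mmhg
  dbp <- profile$true_dbp + bp_offset_mmhg
  ptt0 <- profile$ptt_intercept - profile$ptt_slope * sbp
  if (ptt0 <= 0) stop("implied pulse transit time is not positive")

  withr::with_seed(seed, {
    n <- round(fs * duration)
    tt <- (seq_len(n) - 1) / fs
    rr <- 60 / profile$heart_rate
    n_beats_max <- ceiling(duration / rr) + 2
    gaps <- rr + rnorm(n_beats_max, 0, profile$beat_jitter_sd)
    gaps <- pmax(gaps, 0.3)
    r_times <- 0.5 + cumsum(c(0, gaps))
    r_times <- r_times[r_times < duration - 0.2]
    nb <- length(r_times)
    ptt <- ptt0 + rnorm(nb, 0, ptt_beat_noise_sd)
    ptt <- pmax(ptt, 0.05)

    gauss <- function(centers, amps, width) {
      y <- numeric(n)
      for (i in seq_along(centers)) {
        lo <- max(1L, floor((centers[i] - 5 * width) * fs) + 1L)
        hi <- min(n, ceiling((centers[i] + 5 * width) * fs) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        y[idx] <- y[idx] + amps[i] * exp(-((tt[idx] - centers[i])^2) / (2 * width^2))
      }
      y
    }
    ecg <- gauss(r_times, rep(1, nb), 0.012) +
      gauss(r_times - 0.16, rep(0.15, nb), 0.025) +
      gauss(r_times + 0.25, rep(0.30, nb), 0.05)

    ## place each pulse so its derivative peak sits exactly at r + ptt
    onset <- r_times + ptt - ppg_deriv_peak_offset()
    ppg <- numeric(n)
    for (i in seq_len(nb)) {
      lo <- max(1L, floor(onset[i] * fs) + 1L)
      hi <- min(n, ceiling((onset[i] + 1.2) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      ppg[idx] <- ppg[idx] + ppg_pulse_template(tt[idx] - onset[i])
    }

    if (noise$white_noise_sd > 0) {
      ecg <- ecg + rnorm(n, 0, noise$white_noise_sd)
      ppg <- ppg + rnorm(n, 0, noise$white_noise_sd)
    }
    if (noise$baseline_wander_amp > 0) {
      phase <- runif(1, 0, 2 * pi)
      wander <- noise$baseline_wander_amp *
        sin(2 * pi * noise$baseline_wander_freq * tt + phase)
      ppg <- ppg + wander
      ecg <- ecg + 0.5 * wander
    }
    if (noise$powerline_amp > 0) {
      ecg <- ecg + noise$powerline_amp * sin(2 * pi * noise$powerline_freq * tt)
    }

    rec <- structure(list(
      subject_id = profile$subject_id, fs = fs, duration = duration,
      ecg = ecg, ppg = ppg,
      truth = list(r_peak_times = r_times, ptt = ptt,
                   true_sbp = sbp, true_dbp = dbp)
    ), class = "bp_recording")
    if (noise$bad_contact) {
      rec <- corrupt_recording(rec, "noise_burst", seed = seed + 1L,
                               span_frac = noise$bad_contact_frac)
    }
    rec
  })
}

#' @export
print.bp_recording <- function(x, ...) {
  cat(sprintf("<bp_recording> subject %s: %.0f s @ %g Hz (%d samples)\n",
              x$subject_id %||% "?", x$duration, x$fs, length(x$ecg)))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: %d beats, SBP/DBP %.1f/%.1f mmHg, mean PTT %.3f s\n",
                length(x$truth$r_peak_times), x$truth$true_sbp,
                x$truth$true_dbp, mean(x$truth$ptt)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Corrupt a contiguous span of a recording's PPG channel
#'
#' Emulates poor sensor contact: a flat segment, a high-amplitude noise
#' burst, or amplitude saturation over a contiguous PPG span. The ECG and
#' the truth block are untouched.
#'
#' @param rec A `bp_recording`.
#' @param mode One of `"flatline_segment"`, `"noise_burst"`,
#'   `"saturation"`.
#' @param seed Integer seed (placement of the span).
#' @param span_frac Fraction of samples corrupted; 0 returns the input
#'   unchanged.
#' @param start_frac Optional span start as a fraction of the recording;
#'   random if `NULL`.
#' @return A corrupted copy of `rec`.
#' @export
corrupt_recording <- function(rec, mode = c("flatline_segment", "noise_burst",
                                            "saturation"),
                              seed = 1L, span_frac = 0.3, start_frac = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "bp_recording"), span_frac >= 0, span_frac <= 1)
  if (span_frac == 0) return(rec)
  n <- length(rec$ppg)
  len <- round(span_frac * n)
  withr::with_seed(seed, {
    start <- if (is.null(start_frac)) {
      sample.int(n - len + 1L, 1L)
    } else {
      max(1L, min(n - len + 1L, round(start_frac * n) + 1L))
    }
    idx <- start:(start + len - 1L)
    amp <- max(diff(range(rec$ppg)), 1e-12)
    rec$ppg[idx] <- switch(mode,
      flatline_segment = rec$ppg[idx[1]],
      noise_burst = rec$ppg[idx] + rnorm(len, 0, 2 * amp),
      saturation = pmin(rec$ppg[idx], min(rec$ppg) + 0.05 * amp)
    )
  })
  rec$corruption <- list(mode = mode, start = start, length = len)
  rec
}

#' Simulate one full 7-measurement validation session
#'
#' Produces the alternating ESH-style sequence BP1..BP7
#' (manual, watch, manual, watch, manual, watch, manual) with strictly
#' increasing timestamps, plus (optionally) a preceding individual
#' calibration phase of paired manual/watch measurements.
#'
#' Manual readings are the subject's momentary true BP read independently
#' by two virtual observers (Gaussian error `observer_sd`); if the two
#' observers disagree by more than 4 mmHg the measurement is repeated, and
#' the recorded value is the observers' mean. Each watch event carries a
#' simulated [bp_recording][simulate_recording()] whose momentary BP is the
#' subject's true BP plus `device_bias_mmhg` plus N(0, `device_noise_sd`)
#' measurement-level fluctuation.
#'
#' @param profile One cohort row.
#' @param seed Integer seed.
#' @param fs,noise Passed to [simulate_recording()].
#' @param observer_sd Observer error sd (mmHg).
#' @param device_noise_sd Measurement-level BP fluctuation sd (mmHg) for
#'   watch measurements.
#' @param device_bias_mmhg Systematic device offset (mmHg) for this
#'   subject's watch measurements.
#' @param n_calibration Number of paired calibration measurements (default
#'   3, the minimum the calibration stage accepts).
#' @param spacing_s Seconds between consecutive events.
#' @return An object of class `bp_session`: list with `subject` (profile),
#'   `calibration` (list of paired events) and `events` (the 7 BP1..BP7
#'   events). Manual events have `sbp`/`dbp`; watch events have a
#'   `recording` and a `truth_sbp`/`truth_dbp` (momentary BP).
#' @export
simulate_protocol_session <- function(profile, seed = 1L, fs = 250,
                                      noise = noise_config(),
                                      observer_sd = 2,
                                      device_noise_sd = 6,
                                      device_bias_mmhg = 0,
                                      n_calibration = 3,
                                      spacing_s = 60) {
  profile <- as.list(profile)
  withr::with_seed(seed, {
    manual_reading <- function(sbp, dbp) {
      read_one <- function(true_val) {
        repeat {
          obs <- true_val + rnorm(2, 0, observer_sd)
          if (abs(obs[1] - obs[2]) <= 4) return(mean(obs))
        }
      }
      list(sbp = read_one(sbp), dbp = read_one(dbp))
    }
    watch_event <- function(time, idx) {
      offset <- device_bias_mmhg + rnorm(1, 0, device_noise_sd)
      rec <- simulate_recording(profile, fs = fs, noise = noise,
                                seed = sample.int(.Machine$integer.max, 1L),
                                bp_offset_mmhg = offset)
      list(type = "watch", label = idx, time = time, recording = rec,
           truth_sbp = profile$true_sbp + offset,
           truth_dbp = profile$true_dbp + offset)
    }
    manual_event <- function(time, idx) {
      m <- manual_reading(profile$true_sbp, profile$true_dbp)
      list(type = "manual", label = idx, time = time,
           sbp = m$sbp, dbp = m$dbp)
    }

    t0 <- 0
    calibration <- list()
    if (n_calibration > 0) {
      for (i in seq_len(n_calibration)) {
        m <- manual_event(t0, sprintf("Manual C%d", i))
        w <- watch_event(t0 + spacing_s / 2, sprintf("Watch C%d", i))
        calibration[[i]] <- list(manual = m, watch = w)
        t0 <- t0 + spacing_s
      }
      t0 <- t0 + 5 * 60  # 5-10 min rest between calibration and primary data
    }
    types <- c("manual", "watch", "manual", "watch", "manual", "watch", "manual")
    events <- vector("list", 7L)
    for (i in seq_len(7L)) {
      time <- t0 + (i - 1) * spacing_s
      events[[i]] <- if (types[i] == "manual") {
        manual_event(time, sprintf("BP%d", i))
      } else {
        watch_event(time, sprintf("BP%d", i))
      }
    }
    structure(list(subject = profile, calibration = calibration,
                   events = events),
              class = "bp_session")
  })
}
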