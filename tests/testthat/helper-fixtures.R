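# shared fixtures: a deterministic subject and clean recordings

fixture_profile <- function(true_sbp = 130, true_dbp = 75, heart_rate = 60,
                            ptt_intercept = 0.40, ptt_slope = 0.001,
                            beat_jitter_sd = 0.01) {
  list(subject_id = "T001", age = 55, sex = "M", height = 170, weight = 70,
       true_sbp = true_sbp, true_dbp = true_dbp, heart_rate = heart_rate,
       ptt_intercept = ptt_intercept, ptt_slope = ptt_slope,
       beat_jitter_sd = beat_jitter_sd)
}

fixture_recording <- function(seed = 1, noise = noise_config(), ...) {
  simulate_recording(fixture_profile(...), seed = seed, noise = noise)
}

# a standalone sampled pulse segment built from the simulator's template,
# with a known onset inside the segment
fixture_pulse_segment <- function(fs = 250, dur = 0.9, onset = 0.27) {
  tt <- (seq_len(round(dur * fs)) - 1) / fs
  ppg_pulse_template(tt - onset)
}
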