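#' Build a per-beat training table from simulated recordings
#'
#' Simulates `meas_per_subject` 24-s measurements per subject, runs the
#' preprocessing chain, and assembles per-beat features labelled with the
#' momentary true BP of each measurement (each measurement's BP fluctuates
#' around the subject's resting value with sd `meas_noise_sd`, as repeated
#' clinic readings do). QC-failed measurements are dropped.
#'
#' @param cohort A [simulate_cohort()] data frame.
#' @param meas_per_subject Measurements per subject.
#' @param seed Integer seed.
#' @param noise A [noise_config()] for the recordings.
#' @param fs Sampling rate (Hz).
#' @param meas_noise_sd Measurement-level BP fluctuation sd (mmHg).
#' @return List: `features` (data frame), `targets` (data frame sbp/dbp),
#'   `subject_ids` (vector), `n_dropped` (QC-failed measurements).
#' @export
simulate_training_table <- function(cohort, meas_per_subject = 4, seed = 1L,
                                    noise = noise_config(white_noise_sd = 0.02),
                                    fs = 250, meas_noise_sd = 6) {
  feats <- list(); targs <- list(); sids <- character(0)
  dropped <- 0L
  withr::with_seed(seed, {
    for (i in seq_len(nrow(cohort))) {
      prof <- as.list(cohort[i, ])
      for (m in seq_len(meas_per_subject)) {
        offset <- rnorm(1, 0, meas_noise_sd)
        rec <- simulate_recording(prof, fs = fs, noise = noise,
                                  seed = sample.int(.Machine$integer.max, 1L),
                                  bp_offset_mmhg = offset)
        pp <- preprocess_recording(rec)
        if (!isTRUE(pp$qc$passed)) { dropped <- dropped + 1L; next }
        fv <- assemble_features(pp$selected, prof, pp$heart_rate, fs)
        if (!nrow(fv)) { dropped <- dropped + 1L; next }
        feats[[length(feats) + 1L]] <- fv
        targs[[length(targs) + 1L]] <- data.frame(
          sbp = rep(rec$truth$true_sbp, nrow(fv)),
          dbp = rep(rec$truth$true_dbp, nrow(fv)))
        sids <- c(sids, rep(prof$subject_id, nrow(fv)))
      }
    }
  })
  list(features = do.call(rbind, feats), targets = do.call(rbind, targs),
       subject_ids = sids, n_dropped = dropped)
}

#' Estimate all watch events of a session
#'
#' Runs [estimate_measurement()] on every watch event (optionally with
#' per-subject calibration terms) and stores `device_sbp` / `device_dbp`
#' on the events, ready for [pair_readings()].
#'
#' @param model A `bp_model`.
#' @param session A `bp_session`.
#' @param terms Optional calibration terms.
#' @param qc_threshold Quality-gate threshold.
#' @return The session with estimates filled in; watch events that fail QC
#'   get `device_sbp = NA`.
#' @export
estimate_session <- function(model, session, terms = NULL,
                             qc_threshold = 0.90) {
  demo <- session$subject
  for (i in seq_along(session$events)) {
    ev <- session$events[[i]]
    if (ev$type != "watch") next
    est <- estimate_measurement(model, ev$recording, demo, terms = terms,
                                qc_threshold = qc_threshold)
    session$events[[i]]$device_sbp <- if (est$ok) est$sbp else NA_real_
    session$events[[i]]$device_dbp <- if (est$ok) est$dbp else NA_real_
    session$events[[i]]$qc_passed <- est$ok
  }
  session
}

#' Fit calibration terms from a session's calibration phase
#'
#' Estimates the calibration watch measurements with the uncalibrated
#' general model and fits the per-subject correction terms against the
#' paired manual readings.
#'
#' @param model A `bp_model`.
#' @param session A `bp_session` with >= 3 calibration pairs.
#' @param lambda Ridge penalty (see [fit_calibration()]).
#' @return `bp_calibration_terms`, or `NULL` if fewer than 3 calibration
#'   watch measurements pass QC.
#' @export
calibrate_session <- function(model, session, lambda = 50) {
  rows <- lapply(session$calibration, function(cp) {
    est <- estimate_measurement(model, cp$watch$recording, session$subject)
    if (!est$ok) return(NULL)
    data.frame(device_sbp = est$sbp, device_dbp = est$dbp,
               manual_sbp = cp$manual$sbp, manual_dbp = cp$manual$dbp)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) < 3) return(NULL)
  fit_calibration(model, do.call(rbind, rows), lambda = lambda)
}

#' Run a complete synthetic validation study
#'
#' End-to-end emulation of a cuff-less device validation: a training
#' cohort is simulated and preprocessed, features are screened (3-sigma +
#' autoencoder), the general model is trained with a cross-validated
#' architecture search, and then a separate held-out test cohort undergoes
#' the full protocol -- per-subject calibration from 3 paired
#' measurements followed by the alternating 7-measurement sequence -- and
#' the validation statistics are computed on the nearest-manual pairs.
#'
#' Default sizes (40 training subjects x 4 measurements, 35 test subjects,
#' a reduced architecture search) are chosen to keep a full run in the
#' low minutes on one core while leaving every stage active.
#'
#' @param seed Integer seed for the whole study.
#' @param n_train_subjects,meas_per_train Training cohort size.
#' @param n_test_subjects Test cohort size (35 emulates the reference
#'   protocol; gives 3 pairs/subject).
#' @param device_noise_sd Measurement-level BP fluctuation of watch
#'   measurements (mmHg).
#' @param cfg A [train_config()]; defaults to a reduced desk-scale search
#'   (1-2 layers of 16 nodes, relu, 3 folds).
#' @param noise Recording noise for both cohorts.
#' @param fs Sampling rate (Hz).
#' @return List: `model`, `screen_report`, `report`
#'   (`bp_validation_report` vs the manual readings), `pairs` (data
#'   frame), `truth` (per watch measurement: estimate, nominal and
#'   momentary true BP), `truth_metrics` (r and accuracy of estimates vs
#'   nominal truth), `n_test_qc_failures`.
#' @export
run_synthetic_study <- function(seed = 1L,
                                n_train_subjects = 40, meas_per_train = 4,
                                n_test_subjects = 35,
                                device_noise_sd = 6,
                                cfg = NULL,
                                noise = noise_config(white_noise_sd = 0.02),
                                fs = 250) {
  if (is.null(cfg)) {
    cfg <- train_config(layers = c(1, 2), nodes = 16, activations = "relu",
                        cv_folds = 3, max_epochs = 300, seed = seed)
  }
  train_cohort <- simulate_cohort(cohort_spec(n_train_subjects, seed = seed))
  tr <- simulate_training_table(train_cohort, meas_per_train,
                                seed = seed + 1L, noise = noise, fs = fs,
                                meas_noise_sd = device_noise_sd)
  sc <- screen_features(tr$features, seed = seed + 2L)
  model <- train_general_model(tr$features[sc$mask, , drop = FALSE],
                               tr$targets[sc$mask, , drop = FALSE],
                               tr$subject_ids[sc$mask], cfg)

  test_cohort <- simulate_cohort(cohort_spec(n_test_subjects,
                                             seed = seed + 10L))
  pair_list <- list(); truth_rows <- list()
  qc_failures <- 0L
  for (i in seq_len(nrow(test_cohort))) {
    prof <- as.list(test_cohort[i, ])
    session <- simulate_protocol_session(prof, seed = seed + 100L + i,
                                         fs = fs, noise = noise,
                                         device_noise_sd = device_noise_sd)
    terms <- calibrate_session(model, session)
    session <- estimate_session(model, session, terms = terms)
    ok <- vapply(session$events, function(ev)
      ev$type != "watch" || isTRUE(ev$qc_passed), TRUE)
    qc_failures <- qc_failures + sum(!ok)
    if (all(ok)) pair_list[[length(pair_list) + 1L]] <- pair_readings(session)
    for (ev in session$events) {
      if (ev$type != "watch" || !isTRUE(ev$qc_passed)) next
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        subject_id = prof$subject_id,
        est_sbp = ev$device_sbp, est_dbp = ev$device_dbp,
        true_sbp = prof$true_sbp, true_dbp = prof$true_dbp,
        momentary_sbp = ev$truth_sbp, momentary_dbp = ev$truth_dbp)
    }
  }
  pairs <- do.call(rbind, pair_list)
  truth <- do.call(rbind, truth_rows)
  truth_metrics <- list(
    sbp_r = cor(truth$est_sbp, truth$true_sbp),
    dbp_r = cor(truth$est_dbp, truth$true_dbp),
    sbp_within_10 = mean(abs(truth$est_sbp - truth$true_sbp) <= 10),
    sbp_err_sd = sd(truth$est_sbp - truth$true_sbp),
    sbp_bias = mean(truth$est_sbp - truth$true_sbp)
  )
  list(model = model, screen_report = sc$report,
       report = validation_report(pairs), pairs = pairs,
       truth = truth, truth_metrics = truth_metrics,
       n_test_qc_failures = qc_failures)
}

#' Calibration bias-recovery experiment
#'
#' Repeats, for `n_reps` seeded replicates, the per-subject calibration of
#' a subject whose device readings carry a systematic offset
#' (`bias_mmhg`): 3 calibration pairs are used to fit correction terms and
#' the absolute mean error over `n_heldout` further measurements is
#' compared before and after calibration.
#'
#' @param model A trained `bp_model`.
#' @param seed Integer seed.
#' @param n_reps Number of replicates.
#' @param bias_mmhg Injected systematic device offset (mmHg).
#' @param n_heldout Held-out measurements per replicate.
#' @param device_noise_sd Measurement-level fluctuation (mmHg).
#' @param noise,fs Recording settings.
#' @return List: `improved` (logical per replicate: |bias| strictly
#'   reduced), `pre_bias`, `post_bias`, `pre_mae`, `post_mae`.
#' @export
calibration_improvement_experiment <- function(model, seed = 1L, n_reps = 20,
                                               bias_mmhg = 8, n_heldout = 10,
                                               device_noise_sd = 6,
                                               noise = noise_config(white_noise_sd = 0.02),
                                               fs = 250) {
  pre_bias <- post_bias <- pre_mae <- post_mae <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    ## controlled subjects: no intrinsic intercept deviation, so the
    ## injected bias is the one systematic offset under test
    cohort <- simulate_cohort(cohort_spec(1, ptt_intercept_sd = 0,
                                          seed = seed + 31L * r))
    prof <- as.list(cohort[1, ])
    session <- simulate_protocol_session(prof, seed = seed + 31L * r + 1L,
                                         fs = fs, noise = noise,
                                         device_noise_sd = device_noise_sd,
                                         device_bias_mmhg = bias_mmhg)
    terms <- calibrate_session(model, session)
    pre <- post <- numeric(0)
    withr::with_seed(seed + 31L * r + 2L, {
      for (h in seq_len(n_heldout)) {
        offset <- bias_mmhg + rnorm(1, 0, device_noise_sd)
        rec <- simulate_recording(prof, fs = fs, noise = noise,
                                  seed = sample.int(.Machine$integer.max, 1L),
                                  bp_offset_mmhg = offset)
        e0 <- estimate_measurement(model, rec, prof)
        e1 <- estimate_measurement(model, rec, prof, terms = terms)
        if (e0$ok && e1$ok) {
          pre <- c(pre, e0$sbp - prof$true_sbp)
          post <- c(post, e1$sbp - prof$true_sbp)
        }
      }
    })
    pre_bias[r] <- mean(pre); post_bias[r] <- mean(post)
    pre_mae[r] <- mean(abs(pre)); post_mae[r] <- mean(abs(post))
  }
  list(improved = abs(post_bias) < abs(pre_bias),
       pre_bias = pre_bias, post_bias = post_bias,
       pre_mae = pre_mae, post_mae = post_mae)
}
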