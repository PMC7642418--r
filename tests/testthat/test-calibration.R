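# a tiny stand-in model: only the hash is needed for term binding
stub_model <- function(hash = "h8-1.0e+00") {
  structure(list(hash = hash, final_hidden_dim = 8), class = "bp_model")
}

test_that("calibration reproduces identity and constant-offset fixtures", {
  m <- stub_model()
  p <- data.frame(device_sbp = c(120, 135, 150), device_dbp = c(70, 80, 90))
  # device already equals manual
  same <- cbind(p, manual_sbp = p$device_sbp, manual_dbp = p$device_dbp)
  t1 <- fit_calibration(m, same)
  expect_equal(t1$sbp_gain, 1, tolerance = 1e-6)
  expect_equal(t1$sbp_offset, 0, tolerance = 1e-6)
  expect_equal(unname(t1$fit_residual_rmse["sbp"]), 0, tolerance = 1e-9)
  # device uniformly 10 mmHg below manual
  off <- cbind(p, manual_sbp = p$device_sbp + 10,
               manual_dbp = p$device_dbp + 10)
  t2 <- fit_calibration(m, off)
  expect_equal(t2$sbp_gain, 1, tolerance = 1e-9)
  expect_equal(t2$sbp_offset, 10, tolerance = 1e-6)
  expect_equal(t2$dbp_offset, 10, tolerance = 1e-6)
})

test_that("fewer than 3 pairs is refused and collinear devices fall back", {
  m <- stub_model()
  two <- data.frame(device_sbp = c(120, 130), device_dbp = c(70, 80),
                    manual_sbp = c(121, 131), manual_dbp = c(71, 81))
  expect_error(fit_calibration(m, two), "at least 3")
  # identical device predictions: gain fixed at 1, offset = mean difference
  flat <- data.frame(device_sbp = rep(130, 3), device_dbp = rep(80, 3),
                     manual_sbp = c(135, 140, 145), manual_dbp = c(82, 84, 86))
  tf <- fit_calibration(m, flat)
  expect_equal(tf$sbp_gain, 1)
  expect_equal(tf$sbp_offset, 10)
  expect_equal(tf$dbp_offset, 4)
})

test_that("applying terms is the declared affine map and checks binding", {
  m <- stub_model()
  pairs <- data.frame(device_sbp = c(120, 135, 150),
                      device_dbp = c(70, 80, 90),
                      manual_sbp = c(130, 145, 160),
                      manual_dbp = c(72, 82, 92))
  terms <- fit_calibration(m, pairs)
  out <- calibrate_predictions(terms, c(100, 140), c(60, 95))
  expect_equal(out$sbp,
               terms$sbp_gain * c(100, 140) + terms$sbp_offset)
  expect_equal(out$dbp,
               terms$dbp_gain * c(60, 95) + terms$dbp_offset)
  expect_error(calibrate_predictions(terms, 120, 80, model_hash = "other"),
               "different model")
})

test_that("terms fold into the output layer exactly", {
  fx_seed <- 81
  co <- simulate_cohort(cohort_spec(6, seed = fx_seed))
  tr <- simulate_training_table(co, meas_per_subject = 2, seed = fx_seed + 1,
                                meas_noise_sd = 3)
  cfg <- train_config(layers = 1, nodes = 8, activations = "relu",
                      cv_folds = 2, max_epochs = 100, seed = 4)
  m <- train_general_model(tr$features, tr$targets, tr$subject_ids, cfg)
  pairs <- data.frame(device_sbp = c(118, 131, 149),
                      device_dbp = c(71, 79, 88),
                      manual_sbp = c(125, 139, 158),
                      manual_dbp = c(73, 80, 91))
  terms <- fit_calibration(m, pairs)
  fv <- tr$features[1:20, ]
  via_terms <- apply_calibration(m, terms, fv)
  folded <- fold_calibration_into_model(m, terms)
  via_model <- predict_bp(folded, fv)
  expect_equal(via_terms$sbp, via_model$sbp, tolerance = 1e-12)
  expect_equal(via_terms$dbp, via_model$dbp, tolerance = 1e-12)
  # the original model is untouched by fitting/folding (subject isolation)
  pr0 <- predict_bp(m, fv)
  expect_equal(pr0$sbp, (via_terms$sbp - terms$sbp_offset) / terms$sbp_gain,
               tolerance = 1e-9)
})

test_that("calibration never degrades fit on its own pairs", {
  m <- stub_model()
  withr::with_seed(83, {
    for (i in 1:25) {
      dev_s <- runif(4, 100, 160)
      pairs <- data.frame(
        device_sbp = dev_s, device_dbp = dev_s * 0.6,
        manual_sbp = dev_s + rnorm(4, 5, 4),
        manual_dbp = dev_s * 0.6 + rnorm(4, -2, 3))
      terms <- fit_calibration(m, pairs)
      cal <- calibrate_predictions(terms, pairs$device_sbp, pairs$device_dbp)
      rmse_cal <- sqrt(mean((cal$sbp - pairs$manual_sbp)^2))
      rmse_raw <- sqrt(mean((pairs$device_sbp - pairs$manual_sbp)^2))
      expect_lte(rmse_cal, rmse_raw + 1e-9)
    }
  })
})

test_that("gains outside the sanity range trigger the offset-only fallback", {
  m <- stub_model()
  # wildly inverted relation would fit a negative gain
  pairs <- data.frame(device_sbp = c(100, 130, 160),
                      device_dbp = c(60, 75, 90),
                      manual_sbp = c(160, 130, 100),
                      manual_dbp = c(90, 75, 60))
  terms <- fit_calibration(m, pairs, lambda = 0)
  expect_equal(terms$sbp_gain, 1)
  expect_equal(terms$sbp_offset, 0, tolerance = 1e-9)
})
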