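# small tabular fixture: SBP/DBP linear in PTT plus nuisance features
make_linear_fixture <- function(n_subjects = 40, beats = 10, noise_sd = 3,
                                seed = 61) {
  withr::with_seed(seed, {
    n <- n_subjects * beats
    subj <- rep(sprintf("P%02d", seq_len(n_subjects)), each = beats)
    ptt <- rep(runif(n_subjects, 0.25, 0.40), each = beats) +
      rnorm(n, 0, 0.002)
    X <- data.frame(ptt = ptt, a = rnorm(n), b = rnorm(n), c = rnorm(n))
    Y <- data.frame(sbp = 220 - 280 * ptt + rnorm(n, 0, noise_sd),
                    dbp = 120 - 140 * ptt + rnorm(n, 0, noise_sd))
    list(X = X, Y = Y, subj = subj)
  })
}

test_that("cross-validated training recovers a linear PTT relation", {
  fx <- make_linear_fixture()
  cfg <- train_config(layers = 1, nodes = c(8, 16), activations = "relu",
                      cv_folds = 5, max_epochs = 300, seed = 11)
  m <- train_general_model(fx$X, fx$Y, fx$subj, cfg)
  expect_equal(nrow(m$search_log), 2)
  expect_true(all(is.finite(m$search_log$cv_loss)))
  # held-out subjects
  withr::with_seed(71, {
    ptt2 <- runif(120, 0.25, 0.40)
    X2 <- data.frame(ptt = ptt2, a = rnorm(120), b = rnorm(120),
                     c = rnorm(120))
  })
  pr <- predict_bp(m, X2)
  expect_lt(sqrt(mean((pr$sbp - (220 - 280 * ptt2))^2)), 6)
  expect_gt(cor(pr$sbp, 220 - 280 * ptt2), 0.9)
})

test_that("training is deterministic and realizes constant targets", {
  fx <- make_linear_fixture(n_subjects = 12, seed = 62)
  cfg <- train_config(layers = 1, nodes = 8, activations = "relu",
                      cv_folds = 3, max_epochs = 150, seed = 5)
  m1 <- train_general_model(fx$X, fx$Y, fx$subj, cfg)
  m2 <- train_general_model(fx$X, fx$Y, fx$subj, cfg)
  expect_identical(m1$net, m2$net)
  expect_identical(m1$search_log, m2$search_log)

  Yc <- data.frame(sbp = rep(120, nrow(fx$X)), dbp = rep(80, nrow(fx$X)))
  mc <- train_general_model(fx$X, Yc, fx$subj, cfg)
  pc <- predict_bp(mc, fx$X)
  expect_true(all(abs(pc$sbp - 120) < 1))
  expect_true(all(abs(pc$dbp - 80) < 1))
})

test_that("outputs are exactly the affine read-out of the final hidden layer", {
  fx <- make_linear_fixture(n_subjects = 10, seed = 63)
  cfg <- train_config(layers = 2, nodes = 8, activations = "tanh",
                      cv_folds = 2, max_epochs = 100, seed = 3)
  m <- train_general_model(fx$X, fx$Y, fx$subj, cfg)
  pr <- predict_bp(m, fx$X)
  manual_sbp <- pr$hidden %*% m$net$W_out[, 1] + m$net$b_out[1]
  manual_dbp <- pr$hidden %*% m$net$W_out[, 2] + m$net$b_out[2]
  expect_equal(as.numeric(manual_sbp), pr$sbp, tolerance = 1e-12)
  expect_equal(as.numeric(manual_dbp), pr$dbp, tolerance = 1e-12)
  expect_equal(ncol(pr$hidden), m$final_hidden_dim)
  # forced output: zero weights, fixed bias
  m$net$W_out[] <- 0
  m$net$b_out <- c(120, 80)
  pf <- predict_bp(m, fx$X)
  expect_true(all(pf$sbp == 120) && all(pf$dbp == 80))
  expect_error(predict_bp(m, fx$X[, 1:3]), "schema")
})

test_that("fold assignment is subject-grouped and exhaustive", {
  ids <- rep(sprintf("S%02d", 1:23), times = sample(5:12, 23, replace = TRUE))
  f <- grouped_folds(ids, 5, seed = 9)
  expect_length(f, length(ids))
  per_subject <- tapply(f, ids, function(v) length(unique(v)))
  expect_true(all(per_subject == 1))
  expect_setequal(unique(f), 1:5)
})

test_that("measurement estimation aggregates by median and refuses bad QC", {
  fx <- make_linear_fixture(n_subjects = 12, seed = 64)
  cfg <- train_config(layers = 1, nodes = 8, activations = "relu",
                      cv_folds = 3, max_epochs = 100, seed = 2)
  # model over the real feature schema, trained on simulated beats
  co <- simulate_cohort(cohort_spec(8, seed = 65))
  tr <- simulate_training_table(co, meas_per_subject = 2, seed = 66,
                                meas_noise_sd = 3)
  m <- train_general_model(tr$features, tr$targets, tr$subject_ids, cfg)

  prof <- fixture_profile()
  rec <- simulate_recording(prof, seed = 67)
  est <- estimate_measurement(m, rec, prof)
  expect_true(est$ok)
  expect_equal(est$sbp, median(est$per_beat$sbp))
  expect_equal(nrow(est$per_beat), 10)

  bad <- corrupt_recording(rec, "noise_burst", seed = 68, span_frac = 0.35)
  est_bad <- estimate_measurement(m, bad, prof)
  expect_false(est_bad$ok)
  expect_identical(est_bad$reason, "low_correlation")
  expect_null(est_bad$sbp)
})

test_that("training rejects an empty search space and non-finite targets", {
  fx <- make_linear_fixture(n_subjects = 6, seed = 69)
  expect_error(train_config(layers = integer(0)))
  expect_error(train_config(activations = "sigmoid"))
  expect_error(train_config(cv_folds = 1))
})
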