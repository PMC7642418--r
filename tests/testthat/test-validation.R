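# hand-built session skeleton with explicit times and device values
make_stub_session <- function(watch_times = c(120), manual_times = c(60, 300),
                              device = 130, manual = c(128, 132)) {
  mk_manual <- function(t, v) list(type = "manual", time = t, sbp = v,
                                   dbp = v - 50)
  mk_watch <- function(t, v) list(type = "watch", time = t, device_sbp = v,
                                  device_dbp = v - 50)
  ev <- c(lapply(seq_along(manual_times),
                 function(i) mk_manual(manual_times[i], manual[i])),
          lapply(seq_along(watch_times),
                 function(i) mk_watch(watch_times[i], device[i])))
  ev <- ev[order(vapply(ev, `[[`, 0, "time"))]
  list(subject = list(subject_id = "X1"), events = ev)
}

test_that("pairing picks the temporally closest manual, previous on ties", {
  s <- make_stub_session(watch_times = 120, manual_times = c(60, 300))
  p <- pair_readings(s)
  expect_equal(nrow(p), 1)
  expect_identical(p$manual_source, "previous")
  expect_equal(p$manual_sbp, 128)

  s2 <- make_stub_session(watch_times = 180, manual_times = c(60, 300))
  p2 <- pair_readings(s2)
  expect_identical(p2$manual_source, "previous")  # exact tie -> previous

  s3 <- make_stub_session(watch_times = 250, manual_times = c(60, 300))
  expect_identical(pair_readings(s3)$manual_source, "next")

  # unbracketed watch event errors
  s4 <- make_stub_session(watch_times = 30, manual_times = c(60, 300))
  expect_error(pair_readings(s4), "bracketing")
})

test_that("a full simulated study yields 105 pairs from 35 sessions", {
  co <- simulate_cohort(cohort_spec(35, seed = 91))
  pairs <- list()
  for (i in 1:35) {
    s <- simulate_protocol_session(as.list(co[i, ]), seed = 900 + i,
                                   n_calibration = 0, fs = 125)
    # stand-in estimates: the momentary truth (pairing is what is under test)
    for (j in seq_along(s$events)) {
      if (s$events[[j]]$type == "watch") {
        s$events[[j]]$device_sbp <- s$events[[j]]$truth_sbp
        s$events[[j]]$device_dbp <- s$events[[j]]$truth_dbp
      }
    }
    pairs[[i]] <- pair_readings(s)
  }
  all_pairs <- do.call(rbind, pairs)
  expect_equal(nrow(all_pairs), 105)
  expect_equal(nrow(unique(all_pairs[c("subject_id", "time")])), 105)
})

test_that("Bland-Altman statistics match hand computation", {
  ba0 <- bland_altman(c(0, 0, 0))
  expect_equal(c(ba0$bias, ba0$sd, ba0$lower, ba0$upper), c(0, 0, 0, 0))
  ba <- bland_altman(c(-2, 0, 2), means = c(100, 110, 120))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 2)
  expect_equal(ba$lower, -3.92)
  expect_equal(ba$upper, 3.92)
  expect_equal(ba$points$mean, c(100, 110, 120))
  expect_error(bland_altman(1), "at least 2")
})

test_that("accuracy bins count inclusively and nest", {
  expect_equal(unname(accuracy_bins(c(0, 4, 9, 16))), c(50, 75, 75))
  expect_equal(unname(accuracy_bins(c(0, 0))), c(100, 100, 100))
  expect_equal(unname(accuracy_bins(c(5, 10, 15))), c(100 / 3, 200 / 3, 100))
  withr::with_seed(93, {
    for (i in 1:50) {
      b <- accuracy_bins(rnorm(40, 0, 8))
      expect_true(b["within_5"] <= b["within_10"] &&
                    b["within_10"] <= b["within_15"])
    }
  })
})

test_that("RMSE and its bias/SD decomposition agree to machine precision", {
  expect_equal(rmse(c(3, -3)), 3)
  withr::with_seed(95, {
    for (i in 1:50) {
      d <- rnorm(sample(3:200, 1), sample(-5:5, 1), runif(1, 0.5, 8))
      n <- length(d)
      expect_equal(rmse(d)^2, mean(d)^2 + (n - 1) / n * sd(d)^2,
                   tolerance = 1e-12)
      expect_equal(rmse(d), rmse_from_bias_sd(mean(d), sd(d), n),
                   tolerance = 1e-12)
      expect_gte(rmse(d), abs(mean(d)) - 1e-12)
    }
  })
})

test_that("correlation/t-test handle exact agreement and degenerate diffs", {
  x <- c(110, 125, 140, 155)
  ct <- correlation_and_ttest(x, x)
  expect_equal(ct$r, 1)
  expect_equal(ct$t_statistic, 0)
  expect_equal(ct$p_value, 1)
  ct2 <- correlation_and_ttest(x + 1, x)   # constant nonzero difference
  expect_true(ct2$degenerate)
  expect_true(is.na(ct2$t_statistic))
  ct3 <- correlation_and_ttest(rep(120, 4), x)  # zero variance device
  expect_true(is.na(ct3$r))
  expect_error(correlation_and_ttest(1:2, 1:2), "at least 3")
})

test_that("the 2-of-3 hypertension rule follows the strict 135/85 cut", {
  # published panel, subject 1: device not hypertensive, manual hypertensive
  p <- hypertension_panel()
  expect_false(classify_hypertension(
    unlist(p[1, c("device_sbp_1", "device_sbp_2", "device_sbp_3")]),
    unlist(p[1, c("device_dbp_1", "device_dbp_2", "device_dbp_3")])))
  expect_true(classify_hypertension(c(138, 138, 139), c(72, 70, 79)))
  # one high SBP + one high DBP reading across the triplet counts as 2
  expect_true(classify_hypertension(c(136, 120, 120), c(60, 60, 86)))
  # boundary values are not high (strict inequality)
  expect_false(classify_hypertension(c(135, 135, 120), c(85, 85, 60)))
  expect_error(classify_hypertension(c(120, 130), c(80, 80)), "exactly 3")
})

test_that("diagnostic concordance and discordance counting work", {
  expect_equal(diagnostic_concordance(TRUE, FALSE, 35)$accuracy_pct,
               100 * 34 / 35)
  expect_equal(diagnostic_concordance(c(TRUE, FALSE), c(TRUE, FALSE),
                                      35)$accuracy_pct, 100)
  expect_error(diagnostic_concordance(c(TRUE, TRUE), c(TRUE, TRUE), 1),
               "n_total")
  expect_equal(count_threshold_discordance(140, 130, 135), 1)
  expect_equal(count_threshold_discordance(c(140, 150), c(140, 130), 135), 1)
})

test_that("a stats-level 35-subject recovery matches the injected error model", {
  withr::with_seed(97, {
    truth <- rnorm(105, 129.6, 23.6)
    pairs <- data.frame(
      device_sbp = truth + rnorm(105, 0, 6), manual_sbp = truth,
      device_dbp = truth * 0.5 + rnorm(105, 0, 4),
      manual_dbp = truth * 0.5)
    rep <- validation_report(pairs)
    se <- 6 / sqrt(105)
    expect_lt(abs(rep$sbp$mean_diff), 3 * se)
    p10 <- 2 * pnorm(10 / 6) - 1
    expect_lt(abs(rep$sbp$bins[["within_10"]] / 100 - p10),
              3 * sqrt(p10 * (1 - p10) / 105))
    expect_gt(rep$sbp$pearson_r, 0.9)
  })
})
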