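#' Pair watch estimates with their closest manual reference
#'
#' Implements the sequential-protocol pairing rule: each watch estimate is
#' compared with the temporally closest of the bracketing (previous and
#' next) manual readings; an exact tie resolves to the previous manual.
#' A well-formed 7-measurement session (M,W,M,W,M,W,M) yields exactly
#' three pairs.
#'
#' @param session A `bp_session` whose watch events carry `device_sbp` /
#'   `device_dbp` (see [estimate_session()]), or any list with `subject`
#'   and `events` of the same shape.
#' @return Data frame of `PairedReading` rows: subject_id, time,
#'   device_sbp/dbp, manual_sbp/dbp, manual_source ("previous"/"next"),
#'   diff_sbp/dbp (device - manual).
#' @export
pair_readings <- function(session) {
  ev <- session$events
  types <- vapply(ev, `[[`, "", "type")
  times <- vapply(ev, `[[`, 0, "time")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("event timestamps must be strictly increasing")
  }
  manual_idx <- which(types == "manual")
  watch_idx <- which(types == "watch")
  rows <- lapply(watch_idx, function(i) {
    prev <- manual_idx[manual_idx < i]
    nxt <- manual_idx[manual_idx > i]
    if (!length(prev) || !length(nxt)) {
      stop("watch event without bracketing manual measurements")
    }
    prev <- max(prev); nxt <- min(nxt)
    d_prev <- times[i] - times[prev]
    d_next <- times[nxt] - times[i]
    ref <- if (d_prev <= d_next) prev else nxt  # tie -> previous
    if (is.null(ev[[i]]$device_sbp)) {
      stop("watch event has no device estimate; run estimate_session() first")
    }
    data.frame(
      subject_id = session$subject$subject_id %||% NA_character_,
      time = times[i],
      device_sbp = ev[[i]]$device_sbp, device_dbp = ev[[i]]$device_dbp,
      manual_sbp = ev[[ref]]$sbp, manual_dbp = ev[[ref]]$dbp,
      manual_source = if (ref == prev) "previous" else "next",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$diff_sbp <- out$device_sbp - out$manual_sbp
  out$diff_dbp <- out$device_dbp - out$manual_dbp
  out
}

#' Bland-Altman statistics
#'
#' Bias (mean difference), sample SD of the differences and the 95% limits
#' of agreement bias +/- 1.96 SD, with per-pair plotting coordinates.
#'
#' @param diffs Device-minus-reference differences (n >= 2).
#' @param means Optional per-pair means of the two methods (for the plot
#'   coordinates).
#' @return List with `bias`, `sd`, `lower`, `upper`, and `points` (data
#'   frame of mean/diff coordinates when `means` is supplied).
#' @export
bland_altman <- function(diffs, means = NULL) {
  if (length(diffs) < 2) stop("need at least 2 differences")
  bias <- mean(diffs)
  s <- sd(diffs)
  out <- list(bias = bias, sd = s,
              lower = bias - 1.96 * s, upper = bias + 1.96 * s)
  if (!is.null(means)) out$points <- data.frame(mean = means, diff = diffs)
  out
}

#' Accuracy bins (within 5/10/15 mmHg)
#'
#' Percentage of readings whose absolute difference is at or below 5, 10
#' and 15 mmHg (inclusive boundary).
#'
#' @param diffs Differences (mmHg), non-empty.
#' @return Named numeric vector `within_5`, `within_10`, `within_15` (%).
#' @export
accuracy_bins <- function(diffs) {
  if (!length(diffs)) stop("empty input")
  c(within_5 = 100 * mean(abs(diffs) <= 5),
    within_10 = 100 * mean(abs(diffs) <= 10),
    within_15 = 100 * mean(abs(diffs) <= 15))
}

#' Root mean squared error of paired differences
#'
#' @param diffs Differences (mmHg), non-empty.
#' @return `sqrt(mean(diffs^2))`.
#' @export
rmse <- function(diffs) {
  if (!length(diffs)) stop("empty input")
  sqrt(mean(diffs^2))
}

#' RMSE implied by a printed bias and sample SD
#'
#' The exact decomposition `rmse^2 = bias^2 + (n-1)/n * sd^2` (sample SD,
#' denominator n-1; RMSE over n), used to check reported summary triplets
#' for internal consistency.
#'
#' @param bias Mean difference (mmHg).
#' @param sd Sample SD of the differences (mmHg).
#' @param n Number of pairs.
#' @return Implied RMSE (mmHg).
#' @export
rmse_from_bias_sd <- function(bias, sd, n) {
  sqrt(bias^2 + (n - 1) / n * sd^2)
}

#' Pearson correlation and paired t-test for a device comparison
#'
#' Pearson r between device and reference series (r > 0.90 flags high
#' correlation), and a two-sided paired Student t-test on the differences.
#' Zero variance in either series makes r undefined (`NA`); zero variance
#' of the differences makes the t-test degenerate: t = 0, p = 1 when the
#' constant difference is zero, otherwise t and p are `NA` and
#' `degenerate` is set.
#'
#' @param device,manual Paired readings (n >= 3).
#' @return List: `r`, `high_correlation`, `t_statistic`, `p_value`,
#'   `degenerate`.
#' @export
correlation_and_ttest <- function(device, manual) {
  stopifnot(length(device) == length(manual))
  if (length(device) < 3) stop("need at least 3 pairs")
  r <- if (sd(device) == 0 || sd(manual) == 0) NA_real_ else cor(device, manual)
  d <- device - manual
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(list(r = r, high_correlation = isTRUE(r > 0.90),
                  t_statistic = 0, p_value = 1, degenerate = FALSE))
    }
    return(list(r = r, high_correlation = isTRUE(r > 0.90),
                t_statistic = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  }
  tt <- t.test(device, manual, paired = TRUE)
  list(r = r, high_correlation = isTRUE(r > 0.90),
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       degenerate = FALSE)
}

#' 2-of-3 hypertension classification
#'
#' A reading is "high" iff SBP > 135 mmHg or DBP > 85 mmHg (strict
#' inequality); a subject is classified hypertensive iff at least 2 of the
#' 3 readings are high.
#'
#' @param sbp,dbp Exactly three readings each (mmHg).
#' @param sbp_thr,dbp_thr Thresholds (strict).
#' @return Logical.
#' @export
classify_hypertension <- function(sbp, dbp, sbp_thr = 135, dbp_thr = 85) {
  if (length(sbp) != 3 || length(dbp) != 3) {
    stop("exactly 3 readings are required")
  }
  sum(sbp > sbp_thr | dbp > dbp_thr) >= 2
}

#' Count device/manual threshold discordances
#'
#' Number of reading pairs where exactly one of the device and manual
#' values exceeds the (strict) threshold.
#'
#' @param device,manual Paired readings.
#' @param threshold Strict threshold.
#' @return Integer count.
#' @export
count_threshold_discordance <- function(device, manual, threshold) {
  stopifnot(length(device) == length(manual))
  sum(xor(device > threshold, manual > threshold))
}

#' Diagnostic concordance of hypertension classification
#'
#' Accuracy of the device's subject-level hypertension call against the
#' manual reference: subjects not listed are counted concordant (the
#' published panels tabulate only subjects with at least one discordant
#' reading).
#'
#' @param device_cls,manual_cls Logical classifications for the listed
#'   subjects.
#' @param n_total Total subjects in the study (>= number listed).
#' @return List: `accuracy_pct`, `n_discordant_subjects`.
#' @export
diagnostic_concordance <- function(device_cls, manual_cls, n_total) {
  stopifnot(length(device_cls) == length(manual_cls))
  if (n_total < length(device_cls)) {
    stop("n_total must be at least the number of listed subjects")
  }
  disc <- sum(device_cls != manual_cls)
  list(accuracy_pct = 100 * (n_total - disc) / n_total,
       n_discordant_subjects = disc)
}

#' Full validation report for a set of paired readings
#'
#' Assembles, per channel (SBP, DBP): n, mean difference and sample SD,
#' Pearson r, paired t-test, Bland-Altman bias and limits of agreement,
#' accuracy bins and RMSE.
#'
#' @param pairs Data frame from [pair_readings()] (possibly row-bound over
#'   subjects).
#' @return Object of class `bp_validation_report` (nested list).
#' @export
validation_report <- function(pairs) {
  channel <- function(dev, man) {
    d <- dev - man
    ct <- correlation_and_ttest(dev, man)
    list(n = length(d),
         mean_diff = mean(d), sd_diff = sd(d),
         pearson_r = ct$r, high_correlation = ct$high_correlation,
         t_statistic = ct$t_statistic, p_value = ct$p_value,
         bland_altman = bland_altman(d, (dev + man) / 2),
         bins = accuracy_bins(d),
         rmse = rmse(d))
  }
  structure(list(
    n_pairs = nrow(pairs),
    sbp = channel(pairs$device_sbp, pairs$manual_sbp),
    dbp = channel(pairs$device_dbp, pairs$manual_dbp)
  ), class = "bp_validation_report")
}

#' @export
print.bp_validation_report <- function(x, ...) {
  fmt <- function(ch, nm) {
    cat(sprintf(
      "  %s: diff %+.1f +/- %.1f mmHg, r = %.3f, RMSE %.1f mmHg\n",
      nm, ch$mean_diff, ch$sd_diff, ch$pearson_r, ch$rmse))
    cat(sprintf("       within 5/10/15 mmHg: %.1f%% / %.1f%% / %.1f%%\n",
                ch$bins["within_5"], ch$bins["within_10"],
                ch$bins["within_15"]))
  }
  cat(sprintf("<bp_validation_report> %d paired readings\n", x$n_pairs))
  fmt(x$sbp, "SBP")
  fmt(x$dbp, "DBP")
  invisible(x)
}
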