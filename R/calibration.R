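#' Fit per-subject calibration terms
#'
#' Individualizes the general model by inserting an affine correction
#' between the final hidden layer and each output node. Because each
#' output is a linear read-out of the final hidden activations, a
#' per-output gain and offset on the prediction is exactly equivalent to
#' rescaling and shifting that read-out. For each channel independently,
#' `manual = gain * device + offset` is fitted by least squares over the
#' calibration pairs, with ridge shrinkage of the gain toward 1
#' (penalty `lambda * (gain - 1)^2`) so that the minimum of three pairs
#' cannot produce a degenerate slope. Collinear or identical device
#' predictions fall back to `gain = 1`, `offset = mean(manual - device)`;
#' a fitted gain outside the sanity range (0.25, 4) triggers the same
#' fallback.
#'
#' @param model The `bp_model` the terms bind to.
#' @param pairs Data frame with at least 3 rows and columns
#'   `device_sbp`, `device_dbp` (uncalibrated measurement estimates),
#'   `manual_sbp`, `manual_dbp` (reference readings, mmHg).
#' @param lambda Ridge penalty on (gain - 1), in mmHg^2 (default 50).
#' @return Object of class `bp_calibration_terms`: sbp/dbp gain and
#'   offset, `n_pairs_used`, `fit_residual_rmse`, and the model hash.
#' @export
fit_calibration <- function(model, pairs, lambda = 50) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 3) {
    stop("calibration refused: at least 3 paired measurements are required")
  }
  need <- c("device_sbp", "device_dbp", "manual_sbp", "manual_dbp")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  fit_channel <- function(p, m) {
    pc <- p - mean(p); mc <- m - mean(m)
    sxx <- sum(pc^2)
    if (sxx < 1e-9) {
      g <- 1
    } else {
      g <- (sum(pc * mc) + lambda) / (sxx + lambda)
      if (g <= 0.25 || g >= 4) g <- 1
    }
    o <- mean(m) - g * mean(p)
    resid <- m - (g * p + o)
    list(gain = g, offset = o, rmse = sqrt(mean(resid^2)))
  }
  fs <- fit_channel(pairs$device_sbp, pairs$manual_sbp)
  fd <- fit_channel(pairs$device_dbp, pairs$manual_dbp)
  structure(list(sbp_gain = fs$gain, sbp_offset = fs$offset,
                 dbp_gain = fd$gain, dbp_offset = fd$offset,
                 n_pairs_used = nrow(pairs),
                 fit_residual_rmse = c(sbp = fs$rmse, dbp = fd$rmse),
                 model_hash = model$hash),
            class = "bp_calibration_terms")
}

#' Apply calibration terms to raw channel predictions
#'
#' @param terms `bp_calibration_terms`.
#' @param sbp,dbp Uncalibrated predictions (mmHg).
#' @param model_hash Optional model hash to verify the terms bind to the
#'   predicting model.
#' @return List with calibrated `sbp`, `dbp`.
#' @export
calibrate_predictions <- function(terms, sbp, dbp, model_hash = NULL) {
  stopifnot(inherits(terms, "bp_calibration_terms"))
  if (!is.null(model_hash) && !identical(model_hash, terms$model_hash)) {
    stop("calibration terms were fitted against a different model")
  }
  list(sbp = terms$sbp_gain * sbp + terms$sbp_offset,
       dbp = terms$dbp_gain * dbp + terms$dbp_offset)
}

#' Predict with per-subject calibration
#'
#' Convenience wrapper: [predict_bp()] followed by the affine correction.
#' Equivalent (to machine precision) to predicting with a model whose
#' output-layer weights and bias have been rescaled/shifted by the terms.
#'
#' @param model A `bp_model`.
#' @param terms `bp_calibration_terms` fitted against this model.
#' @param features Feature vector(s).
#' @return List with `sbp`, `dbp`, `hidden`.
#' @export
apply_calibration <- function(model, terms, features) {
  if (!identical(model$hash, terms$model_hash)) {
    stop("calibration terms were fitted against a different model")
  }
  pr <- predict_bp(model, features)
  cal <- calibrate_predictions(terms, pr$sbp, pr$dbp)
  list(sbp = cal$sbp, dbp = cal$dbp, hidden = pr$hidden)
}

#' Fold calibration terms into the model's output layer
#'
#' Returns a copy of the model whose output-layer weights and bias have
#' been modified by the calibration gains/offsets; predicting with it
#' equals applying the terms to the original model's predictions. Exposed
#' to make the "correction terms between final hidden and output layers"
#' equivalence explicit and testable.
#'
#' @param model A `bp_model`.
#' @param terms `bp_calibration_terms` for this model.
#' @return A calibrated `bp_model`.
#' @export
fold_calibration_into_model <- function(model, terms) {
  if (!identical(model$hash, terms$model_hash)) {
    stop("calibration terms were fitted against a different model")
  }
  gains <- c(terms$sbp_gain, terms$dbp_gain)
  offsets <- c(terms$sbp_offset, terms$dbp_offset)
  model$net$W_out <- sweep(model$net$W_out, 2, gains, "*")
  model$net$b_out <- model$net$b_out * gains + offsets
  model$calibrated <- TRUE
  model
}
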