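#' Training configuration for the general BP model
#'
#' Defines the cross-validated architecture search: candidate numbers of
#' hidden layers, nodes per layer and activation functions, the number of
#' folds, and the optimizer settings (full-batch gradient descent with a
#' fixed learning rate and early stopping).
#'
#' @param layers Candidate hidden-layer counts.
#' @param nodes Candidate nodes-per-layer counts.
#' @param activations Candidate activations (`"relu"`, `"tanh"`).
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param max_epochs Epoch budget per fit.
#' @param lr Learning rate.
#' @param seed Integer seed controlling fold assignment and weight
#'   initialization.
#' @return Object of class `bp_train_config`.
#' @export
train_config <- function(layers = c(1, 2, 3), nodes = c(8, 16, 32),
                         activations = c("relu", "tanh"),
                         cv_folds = 5L, max_epochs = 500L, lr = 0.05,
                         seed = 1L) {
  stopifnot(length(layers) >= 1, length(nodes) >= 1,
            all(activations %in% c("relu", "tanh")), cv_folds >= 2)
  structure(list(layers = as.integer(layers), nodes = as.integer(nodes),
                 activations = activations, cv_folds = as.integer(cv_folds),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 seed = as.integer(seed)),
            class = "bp_train_config")
}

#' Subject-grouped fold assignment
#'
#' All rows (beats) of one subject share a fold, so no subject's beats
#' appear in both the training and validation side of any split.
#'
#' @param subject_ids Character/factor vector, one entry per row.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per row.
#' @export
grouped_folds <- function(subject_ids, k, seed = 1L) {
  subjects <- unique(subject_ids)
  withr::with_seed(seed, {
    shuffled <- sample(subjects)
    fold_of <- setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
    as.integer(fold_of[as.character(subject_ids)])
  })
}

.standardize_cols <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, s, "/"), center = mu, scale = s)
}

## light structural fingerprint binding calibration terms to a model
.model_hash <- function(final_hidden_dim, W_out) {
  sprintf("h%d-%.6e", final_hidden_dim, sum(W_out^2))
}

#' Train the general BP estimation model
#'
#' For every candidate architecture in the search space, the k-fold
#' (subject-grouped) cross-validated loss -- mean squared error summed
#' over the SBP and DBP outputs, in mmHg^2 -- is computed; the argmin
#' architecture is then refit on all rows (with an internal 15%
#' subject-grouped split for early stopping). Inputs are z-scored with
#' training statistics stored in the model; targets are standardized
#' during optimization and the scaling is folded back into the output
#' layer, so the stored read-out maps final-hidden activations directly
#' to mmHg.
#'
#' @param features Numeric feature table (screened), one row per beat.
#' @param targets Two-column table/matrix of reference `sbp`, `dbp`
#'   (mmHg), row-aligned with `features`.
#' @param subject_ids Subject id per row (fold grouping).
#' @param cfg A [train_config()].
#' @return Object of class `bp_model`, with `search_log` (one row per
#'   candidate: layers, nodes, activation, cv_loss) attached.
#' @export
train_general_model <- function(features, targets, subject_ids,
                                cfg = train_config()) {
  X <- as.matrix(features)
  Y <- as.matrix(targets)[, 1:2, drop = FALSE]
  colnames(Y) <- c("sbp", "dbp")
  stopifnot(nrow(X) == nrow(Y), nrow(X) == length(subject_ids))
  grid <- expand.grid(layers = cfg$layers, nodes = cfg$nodes,
                      activation = cfg$activations,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0) stop("empty architecture search space")
  folds <- grouped_folds(subject_ids, cfg$cv_folds, seed = cfg$seed)

  sx <- .standardize_cols(X)
  sy <- .standardize_cols(Y)

  cv_loss <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hidden <- rep(grid$nodes[g], grid$layers[g])
    fold_losses <- numeric(cfg$cv_folds)
    for (f in seq_len(cfg$cv_folds)) {
      tr <- folds != f
      if (!any(tr) || all(tr)) { fold_losses[f] <- NA_real_; next }
      fit <- .mlp_fit(sx$x[tr, , drop = FALSE], sy$x[tr, , drop = FALSE],
                      hidden, grid$activation[g], lr = cfg$lr,
                      max_epochs = cfg$max_epochs,
                      seed = cfg$seed + 1000L * g + f,
                      X_val = sx$x[!tr, , drop = FALSE],
                      Y_val = sy$x[!tr, , drop = FALSE])
      pv <- .mlp_forward(fit$net, sx$x[!tr, , drop = FALSE],
                         grid$activation[g], training = FALSE)$pred
      pv <- sweep(sweep(pv, 2, sy$scale, "*"), 2, sy$center, "+")
      fold_losses[f] <- mean(rowSums((pv - Y[!tr, , drop = FALSE])^2))
    }
    cv_loss[g] <- mean(fold_losses, na.rm = TRUE)
    if (!is.finite(cv_loss[g])) stop("non-finite cross-validation loss")
  }
  best <- which.min(cv_loss)
  hidden <- rep(grid$nodes[best], grid$layers[best])
  activation <- grid$activation[best]

  ## final refit on everything, early-stopped on a held-out subject split
  val_fold <- grouped_folds(subject_ids, 7L, seed = cfg$seed + 99L) == 1L
  if (all(val_fold) || !any(val_fold)) val_fold <- rep(FALSE, nrow(X))
  fit <- if (any(val_fold)) {
    .mlp_fit(sx$x[!val_fold, , drop = FALSE], sy$x[!val_fold, , drop = FALSE],
             hidden, activation, lr = cfg$lr, max_epochs = cfg$max_epochs,
             seed = cfg$seed + 7L,
             X_val = sx$x[val_fold, , drop = FALSE],
             Y_val = sy$x[val_fold, , drop = FALSE])
  } else {
    .mlp_fit(sx$x, sy$x, hidden, activation, lr = cfg$lr,
             max_epochs = cfg$max_epochs, seed = cfg$seed + 7L)
  }
  net <- fit$net
  ## fold target standardization into the output layer: mmHg read-out
  net$W_out <- sweep(net$W_out, 2, sy$scale, "*")
  net$b_out <- net$b_out * sy$scale + sy$center

  search_log <- cbind(grid, cv_loss = cv_loss)
  structure(list(
    net = net, activation = activation,
    layer_sizes = c(ncol(X), hidden, 2L),
    final_hidden_dim = tail(hidden, 1),
    x_center = sx$center, x_scale = sx$scale,
    schema = colnames(X),
    hash = .model_hash(tail(hidden, 1), net$W_out),
    search_log = search_log,
    cfg = cfg
  ), class = "bp_model")
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model> %s, layers %s (final hidden dim %d)\n",
              x$activation, paste(x$layer_sizes, collapse = "-"),
              x$final_hidden_dim))
  invisible(x)
}

#' Predict SBP/DBP for feature vectors
#'
#' Applies the general model in inference mode (stored batch-norm
#' statistics) and returns, besides the two outputs, the final-hidden-layer
#' activations: the outputs are exactly the two affine read-outs
#' `hidden %*% W_out + b_out`, which is the hook the per-subject
#' calibration corrects.
#'
#' @param model A `bp_model`.
#' @param features Feature vector, matrix or data frame (schema-checked).
#' @return List with `sbp`, `dbp` (numeric, one per row) and `hidden`
#'   (matrix of final-hidden activations).
#' @export
predict_bp <- function(model, features) {
  X <- if (is.null(dim(features))) matrix(as.numeric(features), nrow = 1,
                                          dimnames = list(NULL, names(features)))
       else as.matrix(features)
  if (ncol(X) != length(model$x_center)) stop("feature schema mismatch")
  if (!is.null(colnames(X)) && !is.null(model$schema) &&
      !identical(colnames(X), model$schema)) {
    stop("feature schema mismatch")
  }
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  fw <- .mlp_forward(model$net, Xs, model$activation, training = FALSE)
  list(sbp = fw$pred[, 1], dbp = fw$pred[, 2], hidden = fw$hidden)
}

#' Estimate BP for one 24-s measurement
#'
#' Full chain: denoise, detect beats, quality-gate, extract features,
#' predict per beat, optionally apply per-subject calibration terms, and
#' aggregate by the median over the selected beats. A measurement that
#' fails the quality gate yields an explicit no-estimate result, never a
#' silent default.
#'
#' @param model A `bp_model`.
#' @param recording A `bp_recording`.
#' @param demographics Subject demographics (see [assemble_features()]).
#' @param terms Optional `bp_calibration_terms` from [fit_calibration()].
#' @param qc_threshold Quality-gate threshold.
#' @return List with `ok`; if `TRUE` also `sbp`, `dbp`, `per_beat` (data
#'   frame of per-beat predictions), `hidden_mean` (measurement-aggregated
#'   final-hidden activations) and `qc`; if `FALSE`, `reason` and `qc`.
#' @export
estimate_measurement <- function(model, recording, demographics,
                                 terms = NULL, qc_threshold = 0.90) {
  pp <- preprocess_recording(recording, threshold = qc_threshold)
  if (!isTRUE(pp$qc$passed)) {
    return(list(ok = FALSE, reason = pp$qc$reject_reason %||% "qc_failed",
                qc = pp$qc))
  }
  fv <- assemble_features(pp$selected, demographics, pp$heart_rate,
                          recording$fs)
  if (nrow(fv) < 2) {
    return(list(ok = FALSE, reason = "too_few_valid_beats", qc = pp$qc))
  }
  pr <- predict_bp(model, fv)
  sbp <- pr$sbp
  dbp <- pr$dbp
  if (!is.null(terms)) {
    cal <- calibrate_predictions(terms, sbp, dbp, model_hash = model$hash)
    sbp <- cal$sbp
    dbp <- cal$dbp
  }
  list(ok = TRUE, sbp = median(sbp), dbp = median(dbp),
       per_beat = data.frame(sbp = sbp, dbp = dbp),
       hidden_mean = colMeans(pr$hidden), qc = pp$qc)
}
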