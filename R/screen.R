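#' Univariate 3-sigma outlier filter
#'
#' First screening stage: per-feature means and standard deviations are
#' computed over the input table in a single pass, and a row is retained
#' iff every feature lies within mean +/- 3 SD (boundary inclusive).
#' Zero-variance features never trigger exclusion.
#'
#' @param x Numeric data frame or matrix (>= 2 rows).
#' @param k Sigma multiplier (default 3).
#' @return List with `mask` (logical, `TRUE` = retained) and `bounds`
#'   (data frame of per-feature mean and sd).
#' @export
three_sigma_filter <- function(x, k = 3) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  ok <- s > 0
  dev <- abs(sweep(x, 2, mu))
  lim <- sweep(dev, 2, k * s)
  lim[, !ok] <- -Inf  # zero-variance features never exclude
  mask <- apply(lim, 1, function(r) all(r <= 0))
  list(mask = as.logical(mask),
       bounds = data.frame(feature = colnames(x), mean = mu, sd = s,
                           row.names = NULL))
}

#' Fit an undercomplete autoencoder for reconstruction-error screening
#'
#' Single-hidden-layer autoencoder with a bottleneck strictly smaller than
#' the feature dimension, fitted on standardized features by full-batch
#' gradient descent with momentum until the relative loss change falls
#' below `tol` or `max_epochs` is reached. The bottleneck is deliberately
#' undercomplete (default ceiling(d/2)): the code must fail to reconstruct
#' rows inconsistent with the bulk correlation structure, which is what
#' makes reconstruction error an anomaly score.
#'
#' @param x Numeric data frame or matrix of retained features.
#' @param bottleneck_dim Hidden width; must be < ncol(x).
#' @param seed Integer seed (weight initialization).
#' @param lr Learning rate.
#' @param max_epochs Epoch budget.
#' @param tol Relative-loss convergence tolerance.
#' @return Object of class `bp_autoencoder` (centering/scaling, weights,
#'   training loss trace).
#' @export
fit_autoencoder <- function(x, bottleneck_dim = NULL, seed = 1L,
                            lr = 0.05, max_epochs = 2000L, tol = 1e-5) {
  x <- as.matrix(x)
  d <- ncol(x)
  if (is.null(bottleneck_dim)) bottleneck_dim <- ceiling(d / 2)
  if (bottleneck_dim >= d) {
    stop("bottleneck_dim must be smaller than the feature dimension")
  }
  n <- nrow(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, s, "/")
  withr::with_seed(seed, {
    W <- matrix(rnorm(d * bottleneck_dim, 0, 0.1), d, bottleneck_dim)
    V <- matrix(rnorm(bottleneck_dim * d, 0, 0.1), bottleneck_dim, d)
    be <- numeric(bottleneck_dim)
    bd <- numeric(d)
    vW <- W * 0; vV <- V * 0; vbe <- be; vbd <- bd
    mom <- 0.9
    losses <- numeric(0)
    prev <- Inf
    for (ep in seq_len(max_epochs)) {
      H <- sweep(xs %*% W, 2, be, "+")
      R <- sweep(H %*% V, 2, bd, "+")
      E <- R - xs
      loss <- mean(E^2)
      losses <- c(losses, loss)
      gR <- 2 * E / (n * d)
      gV <- crossprod(H, gR); gbd <- colSums(gR)
      gH <- gR %*% t(V)
      gW <- crossprod(xs, gH); gbe <- colSums(gH)
      vW <- mom * vW - lr * gW;  W <- W + vW
      vV <- mom * vV - lr * gV;  V <- V + vV
      vbe <- mom * vbe - lr * gbe; be <- be + vbe
      vbd <- mom * vbd - lr * gbd; bd <- bd + vbd
      if (is.finite(prev) && prev > 0 &&
          abs(prev - loss) / prev < tol) break
      prev <- loss
    }
    structure(list(center = mu, scale = s, W = W, V = V, b_enc = be,
                   b_dec = bd, bottleneck_dim = bottleneck_dim,
                   schema = colnames(x), losses = losses),
              class = "bp_autoencoder")
  })
}

#' Per-row autoencoder reconstruction error
#'
#' Mean of squared feature-wise differences between the (standardized)
#' features and their reconstruction.
#'
#' @param ae A fitted [fit_autoencoder()] object.
#' @param x Feature table with the schema the autoencoder was fitted on.
#' @return Numeric vector, one MSE per row.
#' @export
autoencoder_mse <- function(ae, x) {
  x <- as.matrix(x)
  if (!is.null(ae$schema) && !is.null(colnames(x)) &&
      !identical(colnames(x), ae$schema)) {
    stop("feature schema does not match the autoencoder's")
  }
  if (ncol(x) != length(ae$center)) stop("feature dimension mismatch")
  xs <- sweep(sweep(x, 2, ae$center), 2, ae$scale, "/")
  R <- sweep(sweep(xs %*% ae$W, 2, ae$b_enc, "+") %*% ae$V, 2, ae$b_dec, "+")
  rowMeans((R - xs)^2)
}

#' Autoencoder reconstruction-error outlier filter
#'
#' Second screening stage: a row is excluded iff its reconstruction MSE
#' exceeds mean(MSE) + 3 SD(MSE). The cut is one-sided (an unusually *low*
#' error is never anomalous) and a value exactly at the 3-sigma bound is
#' retained.
#'
#' @param x Feature table.
#' @param ae Autoencoder fitted on a compatible schema.
#' @param k Sigma multiplier.
#' @return List with `mask` (`TRUE` = retained), `mse`, `threshold`.
#' @export
autoencoder_filter <- function(x, ae, k = 3) {
  mse <- autoencoder_mse(ae, x)
  # the small floor keeps numerically-zero reconstruction error (data the
  # code reconstructs perfectly) from excluding anything
  thr <- mean(mse) + k * sd(mse) + 1e-12
  list(mask = mse <= thr, mse = mse, threshold = thr)
}

#' Two-stage training-set outlier screen
#'
#' Applies the univariate 3-sigma filter, refits the autoencoder on the
#' retained rows, and applies the reconstruction-error filter. Counts
#' along the chain are monotone non-increasing.
#'
#' @param x Feature table.
#' @param bottleneck_dim,seed Passed to [fit_autoencoder()].
#' @return List with `mask` (over the original rows), `report` (a
#'   `bp_screen_report`: n_input, n_after_sigma, n_after_autoencoder,
#'   excluded_ids, sigma_bounds, ae_mse_threshold) and `ae` (the fitted
#'   autoencoder).
#' @export
screen_features <- function(x, bottleneck_dim = NULL, seed = 1L) {
  x <- as.data.frame(x)
  ids <- rownames(x)
  s1 <- three_sigma_filter(x)
  x1 <- x[s1$mask, , drop = FALSE]
  ae <- fit_autoencoder(x1, bottleneck_dim = bottleneck_dim, seed = seed)
  s2 <- autoencoder_filter(x1, ae)
  mask <- s1$mask
  mask[mask] <- s2$mask
  report <- structure(list(
    n_input = nrow(x),
    n_after_sigma = sum(s1$mask),
    n_after_autoencoder = sum(mask),
    excluded_ids = ids[!mask],
    sigma_bounds = s1$bounds,
    ae_mse_threshold = s2$threshold
  ), class = "bp_screen_report")
  list(mask = mask, report = report, ae = ae)
}
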