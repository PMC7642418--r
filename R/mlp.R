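## Internal fully-connected network with per-hidden-layer batch
## normalization, trained by full-batch gradient descent with momentum.
## Hidden layers: linear -> batch norm (gamma, beta) -> activation.
## Output layer: plain affine map to 2 nodes (SBP, DBP). Running
## batch-norm statistics (momentum 0.1) are stored for inference.

.mlp_act <- function(a, activation) {
  switch(activation, relu = pmax(a, 0), tanh = tanh(a),
         stop("unknown activation"))
}
.mlp_act_grad <- function(a, h, activation) {
  switch(activation, relu = (a > 0) * 1, tanh = 1 - h^2)
}

.mlp_init <- function(d_in, hidden, d_out = 2L, seed = 1L) {
  withr::with_seed(seed, {
    dims <- c(d_in, hidden)
    layers <- lapply(seq_along(hidden), function(l) {
      list(W = matrix(rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
                      dims[l], dims[l + 1]),
           gamma = rep(1, dims[l + 1]), beta = rep(0, dims[l + 1]),
           run_mean = rep(0, dims[l + 1]), run_var = rep(1, dims[l + 1]))
    })
    W_out <- matrix(rnorm(tail(dims, 1) * d_out, 0, sqrt(1 / tail(dims, 1))),
                    tail(dims, 1), d_out)
    list(layers = layers, W_out = W_out, b_out = rep(0, d_out))
  })
}

## forward pass; training = TRUE uses batch statistics and caches
## intermediates for backprop, FALSE uses stored running statistics
.mlp_forward <- function(net, X, activation, training = FALSE,
                         bn_momentum = 0.1, eps = 1e-5) {
  H <- X
  cache <- list()
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- H %*% ly$W
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(sweep(Z, 2, mu)^2)
      net$layers[[l]]$run_mean <- (1 - bn_momentum) * ly$run_mean + bn_momentum * mu
      net$layers[[l]]$run_var <- (1 - bn_momentum) * ly$run_var + bn_momentum * v
    } else {
      mu <- ly$run_mean
      v <- ly$run_var
    }
    Zc <- sweep(Z, 2, mu)
    inv_sd <- 1 / sqrt(v + eps)
    Zh <- sweep(Zc, 2, inv_sd, "*")
    A <- sweep(sweep(Zh, 2, ly$gamma, "*"), 2, ly$beta, "+")
    Hn <- .mlp_act(A, activation)
    cache[[l]] <- list(H_in = H, Z = Z, Zc = Zc, inv_sd = inv_sd, Zh = Zh,
                       A = A, H_out = Hn)
    H <- Hn
  }
  P <- sweep(H %*% net$W_out, 2, net$b_out, "+")
  list(net = net, pred = P, hidden = H, cache = cache)
}

.mlp_grad <- function(net, fw, Y, activation) {
  n <- nrow(Y)
  dP <- 2 * (fw$pred - Y) / n             # d(mean_row sum_k sq)/dP
  gW_out <- crossprod(fw$hidden, dP)
  gb_out <- colSums(dP)
  dH <- dP %*% t(net$W_out)
  g_layers <- vector("list", length(net$layers))
  for (l in rev(seq_along(net$layers))) {
    cc <- fw$cache[[l]]
    dA <- dH * .mlp_act_grad(cc$A, cc$H_out, activation)
    g_gamma <- colSums(dA * cc$Zh)
    g_beta <- colSums(dA)
    dZh <- sweep(dA, 2, net$layers[[l]]$gamma, "*")
    m <- nrow(dZh)
    ## batch-norm backprop (batch statistics)
    t1 <- sweep(dZh, 2, colMeans(dZh))
    t2 <- sweep(cc$Zh, 2, colMeans(dZh * cc$Zh), "*")
    dZ <- sweep(t1 - t2, 2, cc$inv_sd, "*")
    gW <- crossprod(cc$H_in, dZ)
    dH <- dZ %*% t(net$layers[[l]]$W)
    g_layers[[l]] <- list(W = gW, gamma = g_gamma, beta = g_beta)
  }
  list(layers = g_layers, W_out = gW_out, b_out = gb_out)
}

## full-batch training with momentum, optional validation-based early
## stopping (best-parameters restore, patience in epochs)
.mlp_fit <- function(X, Y, hidden, activation, lr = 0.05, max_epochs = 500L,
                     seed = 1L, X_val = NULL, Y_val = NULL, patience = 50L,
                     tol = 1e-7, momentum = 0.9) {
  net <- .mlp_init(ncol(X), hidden, ncol(Y), seed = seed)
  vel <- list(layers = lapply(net$layers, function(ly)
    list(W = ly$W * 0, gamma = ly$gamma * 0, beta = ly$beta * 0)),
    W_out = net$W_out * 0, b_out = net$b_out * 0)
  best <- list(loss = Inf, net = net, epoch = 0L)
  prev_loss <- Inf
  stall <- 0L
  losses <- numeric(0)
  for (ep in seq_len(max_epochs)) {
    fw <- .mlp_forward(net, X, activation, training = TRUE)
    net <- fw$net  # updated running stats
    loss <- mean(rowSums((fw$pred - Y)^2))
    if (!is.finite(loss)) stop("non-finite training loss")
    losses <- c(losses, loss)
    g <- .mlp_grad(net, fw, Y, activation)
    for (l in seq_along(net$layers)) {
      vel$layers[[l]]$W <- momentum * vel$layers[[l]]$W - lr * g$layers[[l]]$W
      vel$layers[[l]]$gamma <- momentum * vel$layers[[l]]$gamma - lr * g$layers[[l]]$gamma
      vel$layers[[l]]$beta <- momentum * vel$layers[[l]]$beta - lr * g$layers[[l]]$beta
      net$layers[[l]]$W <- net$layers[[l]]$W + vel$layers[[l]]$W
      net$layers[[l]]$gamma <- net$layers[[l]]$gamma + vel$layers[[l]]$gamma
      net$layers[[l]]$beta <- net$layers[[l]]$beta + vel$layers[[l]]$beta
    }
    vel$W_out <- momentum * vel$W_out - lr * g$W_out
    vel$b_out <- momentum * vel$b_out - lr * g$b_out
    net$W_out <- net$W_out + vel$W_out
    net$b_out <- net$b_out + vel$b_out

    monitor <- if (!is.null(X_val)) {
      fv <- .mlp_forward(net, X_val, activation, training = FALSE)
      mean(rowSums((fv$pred - Y_val)^2))
    } else loss
    if (monitor < best$loss - 1e-12) {
      best <- list(loss = monitor, net = net, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
    if (is.finite(prev_loss) && prev_loss > 0 &&
        abs(prev_loss - loss) / prev_loss < tol) break
    prev_loss <- loss
  }
  list(net = best$net, best_loss = best$loss, losses = losses,
       epochs = length(losses))
}
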