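# Minimal feed-forward network engine for the taxonomy refiner.
#
# Architecture: for each hidden layer, linear -> batch normalization ->
# leaky ReLU -> dropout; then a linear output layer of width N_l (one logit
# per tree leaf). Training uses Adam on the hierarchical softmax loss.
#
# Activations are stored transposed (units x batch) so that per-unit
# vector operations (bias, batch-norm scale/shift) recycle down columns in
# R's column-major layout, avoiding sweep() copies; matrix products go
# through BLAS.

nn_init <- function(d_in, hidden_sizes, n_out) {
  sizes <- c(d_in, hidden_sizes)
  layers <- vector("list", length(hidden_sizes))
  for (i in seq_along(hidden_sizes)) {
    fan_in <- sizes[i]
    bound <- 1 / sqrt(fan_in)
    layers[[i]] <- list(
      W = matrix(stats::runif(fan_in * sizes[i + 1], -bound, bound),
                 fan_in, sizes[i + 1]),
      b = stats::runif(sizes[i + 1], -bound, bound),
      gamma = rep(1, sizes[i + 1]),
      beta = rep(0, sizes[i + 1]),
      run_mean = rep(0, sizes[i + 1]),
      run_var = rep(1, sizes[i + 1]))
  }
  bound <- 1 / sqrt(sizes[length(sizes)])
  list(layers = layers,
       W_out = matrix(stats::runif(sizes[length(sizes)] * n_out, -bound, bound),
                      sizes[length(sizes)], n_out),
       b_out = stats::runif(n_out, -bound, bound))
}

# Forward pass on transposed input Xt (features x batch). Returns logits as
# batch x N_l. With training = TRUE the running batch-norm statistics on the
# returned $params are updated and per-layer caches are kept for backprop.
nn_forward <- function(params, Xt, config, training = FALSE) {
  caches <- vector("list", length(params$layers))
  A <- Xt
  eps <- config$batchnorm_eps
  mom <- config$batchnorm_momentum
  keep <- 1 - config$dropout_p
  n <- ncol(Xt)
  for (i in seq_along(params$layers)) {
    L <- params$layers[[i]]
    Z <- crossprod(L$W, A) + L$b              # units x batch
    if (training) {
      mu <- rowMeans(Z)
      v <- rowMeans(Z * Z) - mu * mu
      v[v < 0] <- 0                           # guard against cancellation
      inv_sd <- 1 / sqrt(v + eps)
      Xhat <- (Z - mu) * inv_sd
      params$layers[[i]]$run_mean <- (1 - mom) * L$run_mean + mom * mu
      params$layers[[i]]$run_var <- (1 - mom) * L$run_var + mom * v
    } else {
      inv_sd <- 1 / sqrt(L$run_var + eps)
      Xhat <- (Z - L$run_mean) * inv_sd
    }
    B <- Xhat * L$gamma + L$beta
    H <- B
    neg <- B < 0
    H[neg] <- config$leaky_slope * B[neg]
    if (training && config$dropout_p > 0) {
      mask <- matrix((stats::runif(length(H)) < keep) / keep, nrow(H), n)
      A_next <- H * mask
    } else {
      mask <- NULL
      A_next <- H
    }
    if (training)
      caches[[i]] <- list(A_in = A, Xhat = Xhat, inv_sd = inv_sd,
                          neg = neg, mask = mask)
    A <- A_next
  }
  logits <- t(crossprod(params$W_out, A) + params$b_out)
  list(logits = logits, A_last = A, caches = caches, params = params)
}

# Backward pass; d_logits is batch x N_l (gradient of the mean batch loss).
nn_backward <- function(params, fwd, d_logits, config) {
  grads <- list(layers = vector("list", length(params$layers)))
  G_out <- t(d_logits)                        # N_l x batch
  grads$W_out <- tcrossprod(fwd$A_last, G_out)
  grads$b_out <- rowSums(G_out)
  dA <- params$W_out %*% G_out                # units x batch
  n <- ncol(G_out)
  for (i in rev(seq_along(params$layers))) {
    L <- params$layers[[i]]
    cache <- fwd$caches[[i]]
    if (!is.null(cache$mask)) dA <- dA * cache$mask
    dB <- dA
    dB[cache$neg] <- config$leaky_slope * dA[cache$neg]
    dgamma <- rowSums(dB * cache$Xhat)
    dbeta <- rowSums(dB)
    dXhat <- dB * L$gamma
    # batch-norm backward (population statistics)
    dZ <- (dXhat - rowSums(dXhat) / n -
             cache$Xhat * (rowSums(dXhat * cache$Xhat) / n)) * cache$inv_sd
    grads$layers[[i]] <- list(W = tcrossprod(cache$A_in, dZ),
                              b = rowSums(dZ),
                              gamma = dgamma, beta = dbeta)
    if (i > 1) dA <- L$W %*% dZ
  }
  grads
}

adam_init <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
    else numeric(length(x))
  state <- list(t = 0, m = list(layers = list()), v = list(layers = list()))
  for (i in seq_along(params$layers)) {
    tmpl <- params$layers[[i]][c("W", "b", "gamma", "beta")]
    state$m$layers[[i]] <- lapply(tmpl, zero_like)
    state$v$layers[[i]] <- lapply(tmpl, zero_like)
  }
  state$m$W_out <- zero_like(params$W_out); state$v$W_out <- zero_like(params$W_out)
  state$m$b_out <- zero_like(params$b_out); state$v$b_out <- zero_like(params$b_out)
  state
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(params$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      u <- upd(params$layers[[i]][[nm]], grads$layers[[i]][[nm]],
               state$m$layers[[i]][[nm]], state$v$layers[[i]][[nm]])
      params$layers[[i]][[nm]] <- u$p
      state$m$layers[[i]][[nm]] <- u$m
      state$v$layers[[i]][[nm]] <- u$v
    }
  }
  for (nm in c("W_out", "b_out")) {
    u <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- u$p; state$m[[nm]] <- u$m; state$v[[nm]] <- u$v
  }
  list(params = params, state = state)
}

# Row-wise numerically stabilized softmax.
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Hierarchical softmax loss and its gradient w.r.t. the logits.
#
# For each sample, the loss is the summed negative log-likelihood along the
# ancestor path of the true node (the true node included), where a node's
# likelihood is the sum of softmax leaf probabilities over its descendant
# leaves. `paths` is a list of integer node-id vectors; `incidence` is the
# sparse N_l x n_nodes descendant-leaf map. Likelihoods are clamped at
# `clamp` before the log. Returns the mean loss over the batch and the
# gradient of that mean.
hier_loss_grad <- function(logits, paths, incidence, clamp = 1e-12,
                           want_grad = TRUE) {
  P <- softmax_rows(logits)
  Q <- as.matrix(P %*% incidence)
  n <- nrow(logits)
  lens <- lengths(paths)
  ii <- rep(seq_len(n), lens)
  jj <- unlist(paths)
  q_path <- pmax(Q[cbind(ii, jj)], clamp)
  loss <- sum(-log(q_path)) / n
  if (!want_grad) return(list(loss = loss))
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = 1 / q_path,
                            dims = dim(Q))
  G <- as.matrix(Matrix::tcrossprod(C, incidence))   # B x N_l
  grad <- P * (lens - G) / n
  list(loss = loss, grad = grad)
}
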