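# Minimal dense-network engine: tanh hidden layers, linear output, squared
# error loss, full-batch Adam, hand-written backpropagation. Deliberately
# small and deterministic (seeded init, no stochastic minibatching) so every
# training run is exactly reproducible.

.mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      s <- sqrt(2 / (sizes[l] + sizes[l + 1L]))
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0, s),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    list(W = W, b = b, sizes = sizes)
  })
}

# Forward pass; returns list of activations A[[1]] = X .. A[[L+1]] = output.
.mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  A
}

# Backward pass given dL/d(output); returns parameter grads and dL/dX.
.mlp_grads <- function(net, A, dOut) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dOut
  for (l in L:1) {
    dW[[l]] <- crossprod(A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (1 - A[[l]]^2)
    } else {
      delta <- delta %*% t(net$W[[l]])
    }
  }
  list(dW = dW, db = db, dX = delta)
}

.adam_new <- function(net) {
  z <- function(p) lapply(p, function(x) x * 0)
  list(mW = z(net$W), vW = z(net$W), mb = z(net$b), vb = z(net$b), t = 0L)
}

.adam_step <- function(net, st, dW, db, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * dW[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * dW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * db[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * db[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, st = st)
}

# Train an MSE regression network X -> Y. Returns the fitted net with a
# `loss` vector (one entry per epoch).
nn_train <- function(X, Y, hidden, epochs = 300L, lr = 1e-2, seed = 0L, l2 = 0) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  net <- .mlp_init(c(ncol(X), hidden, ncol(Y)), seed)
  st <- .adam_new(net)
  loss <- numeric(epochs)
  ny <- length(Y)
  for (e in seq_len(epochs)) {
    A <- .mlp_forward(net, X)
    err <- A[[length(A)]] - Y
    loss[e] <- mean(err^2)
    if (!is.finite(loss[e])) {
      rlang::abort(sprintf("training diverged at iteration %d (loss is not finite)", e),
                   class = c("eegsweep_training_error", "eegsweep_error"))
    }
    g <- .mlp_grads(net, A, 2 * err / ny)
    if (l2 > 0) for (l in seq_along(g$dW)) g$dW[[l]] <- g$dW[[l]] + l2 * net$W[[l]]
    up <- .adam_step(net, st, g$dW, g$db, lr)
    net <- up$net; st <- up$st
  }
  net$loss <- loss
  net
}

nn_predict <- function(net, X) {
  A <- .mlp_forward(net, as.matrix(X))
  A[[length(A)]]
}

# Variational autoencoder trained on X (reconstruction target = X).
# Returns list(enc, dec, latent, loss); scoring uses the deterministic
# mean-latent reconstruction.
vae_train <- function(X, latent_dim = 4L, hidden = 32L, epochs = 300L,
                      lr = 1e-2, beta = 1, seed = 0L) {
  X <- as.matrix(X)
  d <- ncol(X); n <- nrow(X)
  enc <- .mlp_init(c(d, hidden, 2L * latent_dim), sub_seed(seed, 1))
  dec <- .mlp_init(c(latent_dim, hidden, d), sub_seed(seed, 2))
  st_e <- .adam_new(enc); st_d <- .adam_new(dec)
  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    eps <- with_seed(sub_seed(seed, 3, e), matrix(stats::rnorm(n * latent_dim), n, latent_dim))
    Ae <- .mlp_forward(enc, X)
    eo <- Ae[[length(Ae)]]
    mu <- eo[, seq_len(latent_dim), drop = FALSE]
    lv <- pmin(eo[, latent_dim + seq_len(latent_dim), drop = FALSE], 10)
    z <- mu + eps * exp(lv / 2)
    Ad <- .mlp_forward(dec, z)
    err <- Ad[[length(Ad)]] - X
    recon <- mean(err^2)
    kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv)) / n
    loss[e] <- recon + beta * kl
    if (!is.finite(loss[e])) {
      rlang::abort(sprintf("VAE training diverged at iteration %d", e),
                   class = c("eegsweep_training_error", "eegsweep_error"))
    }
    gd <- .mlp_grads(dec, Ad, 2 * err / length(err))
    dz <- gd$dX
    dmu <- dz + beta * mu / n
    dlv <- dz * eps * exp(lv / 2) / 2 + beta * (-0.5) * (1 - exp(lv)) / n
    ge <- .mlp_grads(enc, Ae, cbind(dmu, dlv))
    up <- .adam_step(dec, st_d, gd$dW, gd$db, lr); dec <- up$net; st_d <- up$st
    up <- .adam_step(enc, st_e, ge$dW, ge$db, lr); enc <- up$net; st_e <- up$st
  }
  list(enc = enc, dec = dec, latent = latent_dim, loss = loss)
}

vae_reconstruct <- function(v, X) {
  X <- as.matrix(X)
  eo <- .mlp_forward(v$enc, X)
  mu <- eo[[length(eo)]][, seq_len(v$latent), drop = FALSE]
  nn_predict(v$dec, mu)
}
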