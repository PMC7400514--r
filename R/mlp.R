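# Minimal dense-network engine: forward/backward passes, inverted dropout and
# an Adam optimizer, written against base matrix ops. The whole package's
# model zoo (per-tile regressor, transcriptomic encoder, classifiers,
# autoencoders) runs on this engine.

ACTIVATIONS <- c("relu", "sigmoid", "linear")

apply_act <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         sigmoid = stats::plogis(z),
         linear = z,
         stop("unknown activation: ", act))
}

# derivative wrt pre-activation, expressed via z and the activation output a
act_grad <- function(z, a, act) {
  switch(act,
         relu = (z > 0) * 1,
         sigmoid = a * (1 - a),
         linear = 1,
         stop("unknown activation: ", act))
}

#' Initialize a multilayer perceptron
#'
#' Weights use He initialization for rectified-linear layers and Glorot-style
#' `1/sqrt(fan_in)` scaling otherwise; biases start at zero.
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @param acts character vector of activations, one per weight layer
#'   (`"relu"`, `"sigmoid"` or `"linear"`).
#' @param seed integer seed for reproducible initialization, or `NULL`.
#' @return an object of class `mlp`.
#' @export
mlp_init <- function(sizes, acts, seed = NULL) {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 2L, all(sizes >= 1L),
            length(acts) == length(sizes) - 1L, all(acts %in% ACTIVATIONS))
  with_seed(seed, {
    W <- vector("list", length(acts))
    b <- vector("list", length(acts))
    for (l in seq_along(acts)) {
      fan_in <- sizes[l]
      sd <- if (acts[l] == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
      W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L], 0, sd),
                       fan_in, sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    structure(list(W = W, b = b, acts = acts, sizes = sizes), class = "mlp")
  })
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

#' Forward pass through an MLP
#'
#' @param net an `mlp` object.
#' @param X numeric matrix, rows are samples (or tiles).
#' @param dropout dropout probability applied to hidden activations; only
#'   active when `training = TRUE` (inverted dropout, inference needs no
#'   rescaling).
#' @param training logical; enables dropout masks.
#' @return list with `out` (output matrix) and, when `cache = TRUE`,
#'   intermediate quantities for backpropagation.
#' @param cache keep intermediates for [mlp_backward()]?
#' @export
mlp_forward <- function(net, X, dropout = 0, training = FALSE, cache = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != net$sizes[1L]) {
    stop_data("feature width ", ncol(X), " does not match model input width ",
              net$sizes[1L])
  }
  L <- length(net$W)
  A_in <- if (cache) vector("list", L) else NULL
  Zs <- if (cache) vector("list", L) else NULL
  As <- if (cache) vector("list", L) else NULL
  masks <- if (cache) vector("list", L) else NULL
  H <- X
  for (l in seq_len(L)) {
    if (cache) A_in[[l]] <- H
    Z <- add_bias(H %*% net$W[[l]], net$b[[l]])
    A <- apply_act(Z, net$acts[l])
    if (training && dropout > 0 && l < L) {
      keep <- 1 - dropout
      mask <- matrix(stats::runif(length(A)) < keep, nrow(A), ncol(A)) / keep
      A <- A * mask
      if (cache) masks[[l]] <- mask
    }
    if (cache) { Zs[[l]] <- Z; As[[l]] <- A }
    H <- A
  }
  if (cache) list(out = H, A_in = A_in, Z = Zs, A = As, masks = masks)
  else list(out = H)
}

# Backward pass. `dOut` is the loss gradient wrt the network output; if
# `dZ_out` is given instead it is taken as the gradient wrt the output
# pre-activation (the usual shortcut for sigmoid + cross-entropy).
mlp_backward <- function(net, fwd, dOut = NULL, dZ_out = NULL) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  for (l in L:1) {
    if (l == L && !is.null(dZ_out)) {
      dZ <- dZ_out
    } else {
      G <- if (l == L) dOut else G
      dZ <- G * act_grad(fwd$Z[[l]], fwd$A[[l]], net$acts[l])
    }
    dW[[l]] <- crossprod(fwd$A_in[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      G <- dZ %*% t(net$W[[l]])
      if (!is.null(fwd$masks[[l - 1L]])) G <- G * fwd$masks[[l - 1L]]
    }
  }
  list(dW = dW, db = db)
}

adam_init <- function(net) {
  zw <- lapply(net$W, function(w) array(0, dim(w)))
  zb <- lapply(net$b, function(b) numeric(length(b)))
  list(mW = zw, vW = zw, mb = zb, vb = zb, t = 0L)
}

adam_step <- function(net, grads, state, lr = 3e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

#' Fit an MLP on plain (X, Y) data
#'
#' Minibatch Adam on mean squared error or binary cross-entropy. Used for the
#' pooled-input models of the transfer module; the per-tile regressor has its
#' own loop around the same engine.
#'
#' @param net an `mlp` object (fresh or warm).
#' @param X,Y input and target matrices (rows aligned).
#' @param loss `"mse"` or `"bce"`; `"bce"` requires a sigmoid output layer.
#' @param epochs,batch_size,lr optimizer settings.
#' @param dropout hidden-layer dropout probability during training.
#' @param seed RNG seed for shuffling and dropout.
#' @return list with the trained `net` and a per-epoch `loss` vector.
#' @export
mlp_fit <- function(net, X, Y, loss = c("mse", "bce"), epochs = 50L,
                    batch_size = 16L, lr = 3e-4, dropout = 0, seed = NULL) {
  loss <- match.arg(loss)
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (loss == "bce" && net$acts[length(net$acts)] != "sigmoid") {
    stop_config("binary cross-entropy requires a sigmoid output layer")
  }
  n <- nrow(X)
  state <- adam_init(net)
  hist <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        rows <- idx[start:min(start + batch_size - 1L, n)]
        Xb <- X[rows, , drop = FALSE]
        Yb <- Y[rows, , drop = FALSE]
        fwd <- mlp_forward(net, Xb, dropout = dropout, training = TRUE,
                           cache = TRUE)
        P <- fwd$out
        m <- length(P)
        if (loss == "mse") {
          lval <- mean((P - Yb)^2)
          grads <- mlp_backward(net, fwd, dOut = 2 * (P - Yb) / m)
        } else {
          Pc <- pmin(pmax(P, 1e-12), 1 - 1e-12)
          lval <- -mean(Yb * log(Pc) + (1 - Yb) * log(1 - Pc))
          grads <- mlp_backward(net, fwd, dZ_out = (P - Yb) / m)
        }
        if (!is.finite(lval)) {
          stop_data("non-finite training loss at epoch ", ep)
        }
        st <- adam_step(net, grads, state, lr = lr)
        net <- st$net; state <- st$state
        ep_loss <- ep_loss + lval
        nb <- nb + 1L
      }
      hist[ep] <- ep_loss / max(nb, 1L)
    }
    list(net = net, loss = hist)
  })
}

#' Activations of a chosen hidden layer
#'
#' @param net an `mlp` object.
#' @param X input matrix.
#' @param layer index of the weight layer whose activation output to return.
#' @return matrix of activations (no dropout).
#' @export
mlp_activations <- function(net, X, layer) {
  stopifnot(layer >= 1L, layer <= length(net$W))
  X <- as.matrix(X)
  H <- X
  for (l in seq_len(layer)) {
    H <- apply_act(add_bias(H %*% net$W[[l]], net$b[[l]]), net$acts[l])
  }
  H
}
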