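# Minimal dense feed-forward networks with hand-written backprop and Adam.
# Batches are rows; weights W[[l]] are (fan_in x fan_out).

activation_fns <- function(name) {
  switch(name,
    relu = list(
      f = function(x) pmax(x, 0),
      df = function(x, y) (x > 0) * 1
    ),
    elu = list(
      f = function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
      df = function(x, y) ifelse(x > 0, 1, y + 1)
    ),
    tanh = list(
      f = tanh,
      df = function(x, y) 1 - y^2
    ),
    linear = list(
      f = identity,
      df = function(x, y) 1
    ),
    abort_imusac(sprintf("unknown activation '%s'", name), "config")
  )
}

#' Initialize a dense feed-forward network
#'
#' He-style initialization for hidden layers; the output layer uses a
#' small uniform range so freshly initialized critics/policies start near
#' zero output (mid-box actions after squashing).
#'
#' @param sizes Integer vector of layer widths, input first.
#' @param hidden_act Hidden activation: "relu", "elu" or "tanh".
#' @param seed Optional integer seed.
#' @param out_scale Half-range of the uniform output-layer init.
#' @return List with `W`, `b`, `sizes`, `hidden_act`.
#' @noRd
nn_init <- function(sizes, hidden_act = "relu", seed = NULL,
                    out_scale = 3e-3) {
  stopifnot(length(sizes) >= 2)
  with_local_seed(seed, {
    L <- length(sizes) - 1
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- sizes[l]
      if (l < L) {
        W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1],
                                      sd = sqrt(2 / fan_in)),
                         fan_in, sizes[l + 1])
      } else {
        W[[l]] <- matrix(stats::runif(fan_in * sizes[l + 1],
                                      -out_scale, out_scale),
                         fan_in, sizes[l + 1])
      }
      b[[l]] <- numeric(sizes[l + 1])
    }
    list(W = W, b = b, sizes = sizes, hidden_act = hidden_act)
  })
}

#' Forward pass
#'
#' @param net A network from `nn_init`.
#' @param X Matrix (batch x input) or vector.
#' @return List `out` (batch x output) and `cache` for backprop.
#' @noRd
nn_forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != net$sizes[1]) {
    abort_imusac(sprintf("network expects %d inputs, got %d",
                         net$sizes[1], ncol(X)), "shape")
  }
  act <- activation_fns(net$hidden_act)
  L <- length(net$W)
  A <- vector("list", L + 1)
  Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- A[[l]] %*% net$W[[l]] +
      matrix(net$b[[l]], nrow(X), length(net$b[[l]]), byrow = TRUE)
    A[[l + 1]] <- if (l < L) act$f(Z[[l]]) else Z[[l]]
  }
  list(out = A[[L + 1]], cache = list(A = A, Z = Z))
}

#' Backward pass
#'
#' @param net Network.
#' @param cache Cache from `nn_forward`.
#' @param dout Gradient of the loss w.r.t. the network output
#'   (batch x output).
#' @return List `dW`, `db` (parameter gradients) and `dX` (gradient
#'   w.r.t. the input, batch x input).
#' @noRd
nn_backward <- function(net, cache, dout) {
  act <- activation_fns(net$hidden_act)
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- dout
  for (l in rev(seq_len(L))) {
    if (l < L) {
      delta <- delta * act$df(cache$Z[[l]], cache$A[[l + 1]])
    }
    dW[[l]] <- crossprod(cache$A[[l]], delta)
    db[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
  }
  list(dW = dW, db = db, dX = delta)
}

#' Rescale gradients to a maximum global L2 norm
#' @noRd
clip_grads <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads$dW, function(g) sum(g^2), numeric(1))) +
                  sum(vapply(grads$db, function(g) sum(g^2), numeric(1))))
  if (total > max_norm) {
    sc <- max_norm / total
    grads$dW <- lapply(grads$dW, `*`, sc)
    grads$db <- lapply(grads$db, `*`, sc)
  }
  grads
}

#' Adam optimizer state for a network
#' @noRd
adam_init <- function(net) {
  list(
    mW = lapply(net$W, function(w) w * 0), vW = lapply(net$W, function(w) w * 0),
    mb = lapply(net$b, function(b) b * 0), vb = lapply(net$b, function(b) b * 0),
    t = 0L
  )
}

#' One Adam update step (returns updated net and state)
#' @noRd
adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}
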