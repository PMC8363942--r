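## Minimal fully connected network: three weight layers with rectified linear
## units between them, trained by stochastic gradient descent with momentum on
## a mean-squared-error criterion. All operations are batched matrix products
## so training runs at BLAS speed on a single CPU.

mlp_init <- function(d_in, hidden, d_out, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- c(d_in, hidden, d_out)
  layers <- vector("list", length(dims) - 1L)
  for (k in seq_along(layers)) {
    fan_in <- dims[k]
    ## He initialisation, appropriate for rectified linear units
    layers[[k]] <- list(
      W = matrix(stats::rnorm(fan_in * dims[k + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, dims[k + 1L]),
      b = rep(0, dims[k + 1L])
    )
  }
  structure(list(layers = layers, dims = dims), class = "soma_mlp")
}

relu <- function(x) (x + abs(x)) / 2

mlp_forward <- function(net, X, cache = FALSE) {
  L <- length(net$layers)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  a <- X
  for (k in seq_len(L)) {
    z <- a %*% net$layers[[k]]$W
    z <- sweep(z, 2L, net$layers[[k]]$b, `+`)
    a <- if (k < L) relu(z) else z
    acts[[k + 1L]] <- a
  }
  if (cache) list(y = a, acts = acts) else a
}

## gradient of mean((Y - T)^2) (mean over all n * d_out entries)
mlp_backward <- function(net, acts, Tgt) {
  L <- length(net$layers)
  n <- nrow(Tgt)
  grads <- vector("list", L)
  delta <- 2 * (acts[[L + 1L]] - Tgt) / (n * ncol(Tgt))
  for (k in L:1) {
    grads[[k]] <- list(W = crossprod(acts[[k]], delta), b = colSums(delta))
    if (k > 1L) {
      delta <- (delta %*% t(net$layers[[k]]$W)) * (acts[[k]] > 0)
    }
  }
  grads
}

mlp_sgd_step <- function(net, grads, state, lr, momentum) {
  for (k in seq_along(net$layers)) {
    state[[k]]$W <- momentum * state[[k]]$W - lr * grads[[k]]$W
    state[[k]]$b <- momentum * state[[k]]$b - lr * grads[[k]]$b
    net$layers[[k]]$W <- net$layers[[k]]$W + state[[k]]$W
    net$layers[[k]]$b <- net$layers[[k]]$b + state[[k]]$b
  }
  list(net = net, state = state)
}

mlp_zero_state <- function(net) {
  lapply(net$layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

mlp_loss <- function(net, X, Tgt) {
  y <- mlp_forward(net, X)
  mean((y - Tgt)^2)
}
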