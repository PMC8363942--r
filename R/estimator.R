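#' Train the neural-network parameter estimator on synthetic signals
#'
#' Trains a three-layer fully connected network (rectified linear activations)
#' that maps the per-shell T2-normalised powder means plus the per-measurement
#' noise level sigma to the four logit-transformed model parameters
#' ([params_to_logits()]). Training data are purely synthetic: tissue
#' parameters from the uniform simplex priors ([sample_tissue_params()]),
#' sigma from the log-uniform prior ([sample_sigma()]), signals from the
#' idealised forward model ([powder_signal()]). Fresh Gaussian noise at each
#' sample's sigma (scaled per shell by `1/sqrt(n_dirs)` for the powder mean)
#' is injected into every batch at every epoch, which regularises the network
#' and gives it an intrinsic denoising behaviour. Optimisation is stochastic
#' gradient descent with momentum on a mean-squared-error criterion.
#'
#' @param protocol a `soma_protocol`; must span at least two distinct
#'   b-tensor shapes, otherwise the four parameters are not identifiable
#' @param n_samples number of synthetic parameter sets (75 percent train,
#'   25 percent validation)
#' @param epochs number of passes over the training set
#' @param batch_size samples per gradient step
#' @param hidden widths of the two hidden layers
#' @param lr initial learning rate
#' @param lr_milestones,lr_factors step-decay schedule: when the epoch passes
#'   fraction `lr_milestones[k]` of `epochs`, the learning rate becomes
#'   `lr * lr_factors[k]`. The default anneals twice; set
#'   `lr_factors = c(1, 1)` for a constant rate
#' @param momentum momentum coefficient
#' @param seed RNG seed; fixes sampling, initialisation and noise injection,
#'   so equal seeds give bitwise-identical models
#' @param noise_model `"gaussian"` (default) or `"rician"` noise injected
#'   during training
#' @param verbose print validation loss during training
#' @return object of class `soma_estimator` carrying the network weights, the
#'   protocol fingerprint, the training configuration and the loss history
#' @export
train_estimator <- function(protocol, n_samples = 2^16, epochs = 1100,
                            batch_size = 1024, hidden = c(128, 128),
                            lr = 0.1, lr_milestones = c(0.7, 0.9),
                            lr_factors = c(0.2, 0.04),
                            momentum = 0.9, seed = 1L,
                            noise_model = c("gaussian", "rician"),
                            verbose = FALSE) {
  stopifnot(inherits(protocol, "soma_protocol"))
  noise_model <- match.arg(noise_model)
  sh <- protocol$shells
  if (length(unique(sh$b_delta)) < 2L) {
    stop("protocol must contain at least two distinct b-tensor shapes (e.g. LTE and STE)")
  }
  m <- nrow(sh)
  set.seed(seed)
  p <- sample_tissue_params(n_samples)
  sigma <- sample_sigma(n_samples)
  S <- powder_signal(p, protocol)
  Z <- params_to_logits(p)
  sig_shell <- shell_sigma(protocol, sigma)  # n x m

  n_train <- floor(0.75 * n_samples)
  idx_train <- seq_len(n_train)
  idx_val <- (n_train + 1L):n_samples

  net <- mlp_init(d_in = m + 1L, hidden = hidden, d_out = 4L)
  state <- mlp_zero_state(net)

  noisy_input <- function(idx) {
    noise <- matrix(stats::rnorm(length(idx) * m), length(idx), m) * sig_shell[idx, , drop = FALSE]
    s <- if (noise_model == "gaussian") {
      S[idx, , drop = FALSE] + noise
    } else {
      noise2 <- matrix(stats::rnorm(length(idx) * m), length(idx), m) * sig_shell[idx, , drop = FALSE]
      sqrt((S[idx, , drop = FALSE] + noise)^2 + noise2^2)
    }
    cbind(s, sigma[idx])
  }

  n_batches <- max(1L, n_train %/% batch_size)
  history <- data.frame(epoch = integer(0), val_loss = numeric(0))
  check_every <- max(1L, epochs %/% 50L)

  for (ep in seq_len(epochs)) {
    lr_ep <- lr
    for (k in seq_along(lr_milestones)) {
      if (ep > lr_milestones[k] * epochs) lr_ep <- lr * lr_factors[k]
    }
    perm <- sample(idx_train)
    for (bb in seq_len(n_batches)) {
      idx <- perm[((bb - 1L) * batch_size + 1L):min(bb * batch_size, n_train)]
      X <- noisy_input(idx)
      fw <- mlp_forward(net, X, cache = TRUE)
      grads <- mlp_backward(net, fw$acts, Z[idx, , drop = FALSE])
      upd <- mlp_sgd_step(net, grads, state, lr_ep, momentum)
      net <- upd$net; state <- upd$state
    }
    if (ep %% check_every == 0L || ep == epochs) {
      vl <- mlp_loss(net, noisy_input(idx_val), Z[idx_val, , drop = FALSE])
      if (!is.finite(vl)) {
        stop("training diverged at epoch ", ep,
             " (validation loss not finite); try a lower learning rate")
      }
      history <- rbind(history, data.frame(epoch = ep, val_loss = vl))
      if (verbose) message(sprintf("epoch %d  val loss %.5f", ep, vl))
    }
  }

  structure(list(
    net = net,
    fingerprint = protocol$fingerprint,
    protocol = protocol,
    config = list(n_samples = n_samples, epochs = epochs,
                  batch_size = batch_size, hidden = hidden, lr = lr,
                  lr_milestones = lr_milestones, lr_factors = lr_factors,
                  momentum = momentum, seed = seed, noise_model = noise_model),
    history = history,
    val_loss = utils::tail(history$val_loss, 1)
  ), class = "soma_estimator")
}

#' @export
print.soma_estimator <- function(x, ...) {
  cat("Soma-density estimator:", paste(x$net$dims, collapse = " -> "),
      "network\n  protocol:", x$fingerprint,
      "\n  final validation loss:", format(x$val_loss, digits = 4), "\n")
  invisible(x)
}

#' Estimate tissue parameters from powder-averaged signals
#'
#' Forward pass of a trained estimator followed by the inverse logit
#' transform, so every estimate lies in the biophysically plausible range by
#' construction. Also returns the derived extra-cellular diffusivities from
#' the tortuosity model.
#'
#' @param model a `soma_estimator`
#' @param signals n x n_shell matrix of T2-normalised powder means, ordered as
#'   in the training protocol
#' @param sigma per-measurement noise standard deviation; scalar or length-n
#' @param protocol optional `soma_protocol` of the data. Must match the
#'   training protocol in b-values, shapes, echo time and relative direction
#'   split; a protocol that differs only in the total direction count is
#'   accepted, with `sigma` rescaled by `sqrt(n_model / n_data)` so that the
#'   powder-mean noise the network assumes matches the data (the network sees
#'   only powder means, so the direction count enters through their noise)
#' @return tissue parameter table with derived columns `lambda_par_ext`,
#'   `lambda_perp_ext`
#' @export
estimate_params <- function(model, signals, sigma, protocol = NULL) {
  stopifnot(inherits(model, "soma_estimator"))
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "soma_protocol"))
    if (protocol$fingerprint != model$fingerprint) {
      if (compat_fingerprint(protocol) != compat_fingerprint(model$protocol)) {
        stop("protocol fingerprint mismatch: model trained on\n  ",
             model$fingerprint, "\nbut data uses\n  ", protocol$fingerprint)
      }
      sigma <- sigma * sqrt(sum(model$protocol$shells$n_dirs) /
                              sum(protocol$shells$n_dirs))
    }
  }
  signals <- rbind(signals)
  d_in <- model$net$dims[1L]
  if (ncol(signals) != d_in - 1L) {
    stop("expected ", d_in - 1L, " shell signals per voxel, got ", ncol(signals))
  }
  sigma <- rep_len(sigma, nrow(signals))
  X <- cbind(signals, sigma)
  if (!all(is.finite(X))) stop("non-finite inputs rejected")
  z <- mlp_forward(model$net, X)
  p <- logits_to_params(z)
  ext <- tortuosity(p$v_cyl, p$v_sph, p$v_ext, p$lambda_cyl)
  p$lambda_par_ext <- ext$lambda_par
  p$lambda_perp_ext <- ext$lambda_perp
  p
}

#' Non-linear least-squares baseline fit
#'
#' Classical per-voxel fitting of the idealised powder model by bounded
#' least squares: Levenberg-Marquardt minimisation of the variance-weighted
#' residuals between [powder_signal()] predictions and the measured shell
#' means, with per-shell weights `n_dirs / sigma^2` (the powder mean over a
#' shell has variance `sigma^2 / n_dirs`; unweighted when `sigma = 0`).
#' The search runs in the unbounded logit space, which enforces all parameter
#' constraints. The objective has flat, curved valleys and genuine local
#' minima, so many random restarts are needed for global convergence;
#' around 50 recover noise-free signals to machine precision. Serves as the
#' independent classical baseline for the network estimator.
#'
#' @param signals n x n_shell matrix of powder means
#' @param sigma per-measurement noise level (scalar or length-n); 0 for
#'   noise-free data
#' @param protocol a `soma_protocol`
#' @param n_restarts number of random restarts per voxel (in addition to a
#'   deterministic centre start)
#' @param seed RNG seed for the restart draws
#' @return tissue parameter table with extra columns `rss` (weighted residual
#'   sum of squares) and `converged`
#' @export
fit_nlls <- function(signals, sigma = 0, protocol = default_protocol(),
                     n_restarts = 25, seed = 1L) {
  stopifnot(inherits(protocol, "soma_protocol"))
  signals <- rbind(signals)
  sh <- protocol$shells
  stopifnot(ncol(signals) == nrow(sh))
  sigma <- rep_len(sigma, nrow(signals))
  set.seed(seed)
  starts <- params_to_logits(sample_tissue_params(max(n_restarts, 1)))

  b <- b_to_internal(sh$b)
  bd <- sh$b_delta

  ## fast scalar-voxel forward model in logit space (no data.frame overhead)
  predict_z <- function(z) {
    sig3 <- 1 / (1 + exp(-z))
    vtot <- sig3[1]
    v_cyl <- vtot * sig3[2]; v_sph <- vtot - v_cyl; v_ext <- 1 - vtot
    l_cyl <- LAMBDA_FREE * sig3[3]; l_sph <- l_cyl * sig3[4]
    e <- v_sph + v_cyl
    if (e > 0) {
      lp <- l_cyl * v_ext^(0.5 * v_sph / e)
      lq <- l_cyl * v_ext^((0.5 * v_sph + v_cyl) / e)
    } else {
      lp <- lq <- l_cyl
    }
    v_cyl * compartment_powder_term(b, bd, l_cyl, 0) +
      v_sph * exp(-b * ((1 - bd) / 3 + (2 + bd) / 3) * l_sph) +
      v_ext * compartment_powder_term(b, bd, lp, lq)
  }

  fit_one <- function(y, sig) {
    ## weights: powder mean over a shell has variance sigma^2 / n_dirs
    sw <- if (sig > 0) sqrt(sh$n_dirs) / sig else rep(1, nrow(sh))
    resid <- function(z) sw * (predict_z(z) - y)
    best <- NULL
    z0s <- rbind(c(0, 0, 0, 0), starts[seq_len(n_restarts), , drop = FALSE])
    ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                      ptol = 1e-15, gtol = 0)
    for (r in seq_len(nrow(z0s))) {
      res <- try(minpack.lm::nls.lm(z0s[r, ], fn = resid, control = ctl),
                 silent = TRUE)
      if (inherits(res, "try-error")) next
      val <- sum(res$fvec^2)
      if (is.null(best) || val < best$val) {
        best <- list(par = res$par, val = val, conv = res$info %in% 1:4)
      }
    }
    if (is.null(best)) return(list(z = rep(NA_real_, 4), rss = NA_real_, conv = FALSE))
    list(z = best$par, rss = best$val, conv = best$conv)
  }

  fits <- lapply(seq_len(nrow(signals)), function(i) fit_one(signals[i, ], sigma[i]))
  z <- do.call(rbind, lapply(fits, `[[`, "z"))
  p <- logits_to_params(z)
  p$rss <- vapply(fits, `[[`, numeric(1), "rss")
  p$converged <- vapply(fits, `[[`, logical(1), "conv")
  p
}
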