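#' Construct an axially symmetric b-tensor from b-value, shape and direction
#'
#' An axially symmetric b-tensor is parameterised by its trace `b`, its shape
#' `b_delta` and its symmetry axis `n`:
#' `B = b_delta * b * n n^T + (b/3) * (1 - b_delta) * I`.
#' `b_delta = 1` gives linear tensor encoding (LTE, rank-1), `b_delta = 0`
#' spherical tensor encoding (STE, isotropic) and `b_delta = -1/2` planar
#' encoding.
#'
#' @param b b-value (trace of the tensor), s/mm^2
#' @param b_delta b-tensor shape, in `[-1/2, 1]`
#' @param n symmetry axis, length-3 numeric; must have unit norm (tolerance
#'   1e-6). Irrelevant when `b_delta = 0`.
#' @return 3x3 symmetric positive semi-definite matrix, s/mm^2 per element
#' @export
make_btensor <- function(b, b_delta, n = c(0, 0, 1)) {
  stopifnot(is.numeric(b), length(b) == 1L, is.numeric(b_delta), length(b_delta) == 1L)
  if (b < 0) stop("b must be non-negative")
  if (b_delta < -0.5 || b_delta > 1) {
    stop("b_delta must lie in [-1/2, 1], got ", b_delta)
  }
  n <- as.numeric(n)
  if (length(n) != 3L) stop("n must be a length-3 vector")
  nrm <- sqrt(sum(n^2))
  if (abs(nrm - 1) > 1e-6) {
    stop("n must be a unit vector (|n| = ", format(nrm), "); normalise it first")
  }
  n <- n / nrm
  bt <- b_delta * b * tcrossprod(n) + (b / 3) * (1 - b_delta) * diag(3)
  (bt + t(bt)) / 2
}

#' Recover (b, b_delta) from an axially symmetric b-tensor
#'
#' Inverse of [make_btensor()] for axially symmetric tensors: `b` is the trace
#' and `b_delta = (lambda_axis - lambda_radial) / b` where `lambda_axis` is the
#' unique eigenvalue and `lambda_radial` the doubly degenerate one.
#'
#' @param bt 3x3 symmetric b-tensor
#' @param tol relative tolerance for axial symmetry of the two degenerate
#'   eigenvalues
#' @return list with elements `b`, `b_delta` and `n` (symmetry axis; arbitrary
#'   for isotropic tensors)
#' @export
btensor_shape <- function(bt, tol = 1e-6) {
  stopifnot(is.matrix(bt), all(dim(bt) == c(3L, 3L)))
  if (max(abs(bt - t(bt))) > tol * max(1, max(abs(bt)))) stop("b-tensor must be symmetric")
  e <- eigen(bt, symmetric = TRUE)
  ev <- e$values  # decreasing
  b <- sum(ev)
  scale <- max(abs(ev), 1e-12)
  ## the degenerate pair is either the two largest or the two smallest
  gap12 <- abs(ev[1] - ev[2])
  gap23 <- abs(ev[2] - ev[3])
  if (min(gap12, gap23) > tol * scale && gap12 > tol * scale && gap23 > tol * scale) {
    stop("b-tensor is not axially symmetric within tolerance")
  }
  if (gap23 <= gap12) {
    ## unique eigenvalue is the largest (prolate / linear-like)
    ax <- ev[1]; rad <- (ev[2] + ev[3]) / 2; n <- e$vectors[, 1]
  } else {
    ## unique eigenvalue is the smallest (oblate / planar-like)
    ax <- ev[3]; rad <- (ev[1] + ev[2]) / 2; n <- e$vectors[, 3]
  }
  b_delta <- if (b > 0) (ax - rad) / b else 0
  list(b = b, b_delta = b_delta, n = as.numeric(n))
}

#' Diffusion-encoding gradient waveform
#'
#' A free gradient waveform sampled on a uniform time grid, with the index of
#' the 180-degree refocusing pulse recorded so that the effective dephasing
#' vector q(t) changes sign for samples after it (spin-echo convention).
#'
#' @param samples 3 x N numeric matrix of gradient amplitudes, mT/m
#' @param dt sample spacing, s
#' @param rf_flip_index sample index after which the sign of q is inverted;
#'   use 0 for no refocusing pulse (signs already effective)
#' @return object of class `gradient_waveform`
#' @export
gradient_waveform <- function(samples, dt, rf_flip_index = 0L) {
  stopifnot(is.matrix(samples), nrow(samples) == 3L, dt > 0)
  structure(list(samples = samples, dt = dt, rf_flip_index = as.integer(rf_flip_index)),
            class = "gradient_waveform")
}

## gyromagnetic ratio of 1H, rad s^-1 T^-1
GAMMA_H <- 2.6752218744e8

#' Compute the b-tensor of a gradient waveform by numerical quadrature
#'
#' Integrates `q(t) = gamma * int G dt` (with sign inversion after the
#' refocusing pulse) and then `B = int q q^T dt` with the trapezoidal rule.
#' The waveform must rephase: `q(TE) = 0` within tolerance.
#'
#' @param w a [gradient_waveform()]
#' @param tol relative tolerance on the residual `|q(TE)| / max |q|`
#' @return 3x3 symmetric b-tensor in s/mm^2
#' @export
btensor_from_waveform <- function(w, tol = 1e-6) {
  stopifnot(inherits(w, "gradient_waveform"))
  g <- w$samples * 1e-3           # mT/m -> T/m
  n <- ncol(g)
  sgn <- rep(1, n)
  if (w$rf_flip_index > 0L && w$rf_flip_index < n) {
    sgn[(w$rf_flip_index + 1L):n] <- -1
  }
  ge <- sweep(g, 2L, sgn, `*`)
  ## cumulative trapezoid per axis: q in rad/m
  q <- matrix(0, 3, n)
  for (ax in 1:3) {
    q[ax, ] <- GAMMA_H * c(0, cumsum((ge[ax, -1] + ge[ax, -n]) / 2) * w$dt)
  }
  qmax <- max(abs(q), 1e-300)
  resid <- sqrt(sum(q[, n]^2)) / qmax
  if (resid > tol) {
    stop("waveform does not rephase: |q(TE)|/max|q| = ", format(resid))
  }
  bt <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    f <- q[i, ] * q[j, ]
    bt[i, j] <- bt[j, i] <- sum((f[-1] + f[-n]) / 2) * w$dt
  }
  bt * 1e-6  # s/m^2 * 1e-6 -> s/mm^2
}
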