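#' Add measurement noise to signals
#'
#' Gaussian: `s + N(0, sigma)`. Rician (magnitude of a complex signal with
#' independent Gaussian noise on both channels): `sqrt((s + N(0, sigma))^2 +
#' N(0, sigma)^2)`.
#'
#' @param s numeric vector/matrix/array of noise-free signals
#' @param sigma noise standard deviation; scalar, or an object recycled /
#'   conformable with `s` (e.g. a per-shell matrix)
#' @param model `"gaussian"` or `"rician"`
#' @param seed optional RNG seed for reproducibility
#' @return noisy signals, same shape as `s`
#' @export
add_noise <- function(s, sigma, model = c("gaussian", "rician"), seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (all(sigma == 0)) return(s)
  n <- length(s)
  out <- if (model == "gaussian") {
    s + stats::rnorm(n) * sigma
  } else {
    sqrt((s + stats::rnorm(n) * sigma)^2 + (stats::rnorm(n) * sigma)^2)
  }
  attributes(out) <- attributes(s)
  out
}

#' Per-shell noise level of the powder mean
#'
#' The powder mean over a shell's `n_dirs` directions averages independent
#' per-measurement noise, so its standard deviation is `sigma / sqrt(n_dirs)`.
#'
#' @param protocol a `soma_protocol` or shells data.frame
#' @param sigma per-measurement noise standard deviation (scalar or vector)
#' @return matrix with one row per `sigma` and one column per shell
#' @export
shell_sigma <- function(protocol, sigma) {
  sh <- shells_of(protocol)
  outer(sigma, 1 / sqrt(sh$n_dirs))
}

#' Expected magnitude of a Rician-distributed measurement
#'
#' `E[m | s, sigma]` for a Rician with underlying signal `s` and Gaussian
#' channel noise `sigma`, via the Laguerre-polynomial closed form evaluated
#' with exponentially scaled Bessel functions for numerical stability.
#'
#' @param s underlying (noise-free) signal, >= 0
#' @param sigma noise standard deviation
#' @return expected measured magnitude; equals `sigma * sqrt(pi/2)` at `s = 0`
#' @export
rician_expectation <- function(s, sigma) {
  if (all(sigma == 0)) return(s)
  t <- s^2 / (2 * sigma^2)
  i0 <- besselI(t / 2, 0, expon.scaled = TRUE)
  i1 <- besselI(t / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * ((1 + t) * i0 + t * i1)
}

#' Correct the Rician noise bias of measured powder means
#'
#' Numerically inverts [rician_expectation()] in `s` for each measured value.
#' Measurements at or below the zero-signal noise floor
#' `sigma * sqrt(pi/2)` map to 0.
#'
#' @param m measured (biased) signal, >= 0; vector or array
#' @param sigma noise standard deviation (scalar or conformable)
#' @return bias-corrected signal estimate, same shape as `m`
#' @export
rician_bias_correct <- function(m, sigma) {
  if (all(sigma == 0)) return(m)
  sig <- rep_len(as.numeric(sigma), length(m))
  out <- vapply(seq_along(m), function(i) {
    mi <- m[i]; si <- sig[i]
    if (si == 0) return(mi)
    floor_i <- si * sqrt(pi / 2)
    if (mi <= floor_i) return(0)
    upper <- mi + 5 * si
    stats::uniroot(function(s) rician_expectation(s, si) - mi,
                   lower = 0, upper = upper, tol = 1e-10)$root
  }, numeric(1))
  attributes(out) <- attributes(m)
  out
}
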