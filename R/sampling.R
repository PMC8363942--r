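#' Draw tissue parameters from the training prior
#'
#' Volume fractions `(v_cyl, v_sph, v_ext)` are uniform on the 2-simplex
#' (Dirichlet(1,1,1)). Diffusivities are uniform on a 2-simplex of the scaled
#' increments `(lambda_sph, lambda_cyl - lambda_sph, lambda_free - lambda_cyl)
#' / lambda_free`, which is the uniform prior over the ordered constraint
#' `0 <= lambda_sph <= lambda_cyl <= 3` um^2/ms.
#'
#' @param n number of draws
#' @param seed optional RNG seed
#' @return tissue parameter table with `n` rows
#' @export
sample_tissue_params <- function(n, seed = NULL) {
  stopifnot(n > 0)
  if (!is.null(seed)) set.seed(seed)
  ## Dirichlet(1,1,1) via normalised unit-rate exponentials
  e <- matrix(stats::rexp(3 * n), n, 3)
  v <- e / rowSums(e)
  d <- matrix(stats::rexp(3 * n), n, 3)
  d <- d / rowSums(d)
  lambda_sph <- LAMBDA_FREE * d[, 1]
  lambda_cyl <- LAMBDA_FREE * (d[, 1] + d[, 2])
  tissue_params(v_cyl = v[, 1], v_sph = v[, 2],
                lambda_cyl = lambda_cyl, lambda_sph = lambda_sph)
}

#' Draw noise levels from the scale-invariant prior
#'
#' `log(sigma)` uniform on `[log(0.01), log(1)]`: a non-informative prior
#' covering single-measurement SNR between 1 and 100 for unit b = 0 signal.
#'
#' @param n number of draws
#' @param seed optional RNG seed
#' @param range sigma range, default `c(0.01, 1)`
#' @return numeric vector of noise standard deviations
#' @export
sample_sigma <- function(n, seed = NULL, range = c(0.01, 1)) {
  stopifnot(n > 0, all(range > 0), range[1] < range[2])
  if (!is.null(seed)) set.seed(seed)
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Regular grid on the volume-fraction simplex
#'
#' All non-negative triples `(v_cyl, v_sph, v_ext)` on a grid of the given
#' step that sum to 1; 231 points at step 0.05.
#'
#' @param step grid increment; `1/step` must be an integer
#' @return data.frame with columns `v_cyl`, `v_sph`, `v_ext`
#' @export
simplex_grid <- function(step = 0.05) {
  k <- round(1 / step)
  stopifnot(abs(k * step - 1) < 1e-9)
  g <- expand.grid(i = 0:k, j = 0:k)
  g <- g[g$i + g$j <= k, ]
  out <- data.frame(v_cyl = g$i * step, v_sph = g$j * step,
                    v_ext = 1 - (g$i + g$j) * step)
  out$v_ext <- pmax(out$v_ext, 0)
  rownames(out) <- NULL
  out
}
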