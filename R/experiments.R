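#' Box-plot statistics of estimation errors
#'
#' Summarises a vector of signed errors (estimate minus ground truth) the way
#' the simulation studies report them: mean bias, standard deviation, the
#' 25th/50th/75th percentiles, and whiskers extending 1.5 times the
#' interquartile range beyond the box (clipped to the data range).
#'
#' @param err numeric vector of signed errors
#' @return one-row data.frame: `mean_bias`, `sd`, `p25`, `p50`, `p75`,
#'   `whisker_lo`, `whisker_hi`, `iqr`, `n`
#' @export
error_stats <- function(err) {
  err <- err[is.finite(err)]
  q <- stats::quantile(err, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  data.frame(mean_bias = mean(err), sd = stats::sd(err),
             p25 = q[1], p50 = q[2], p75 = q[3],
             whisker_lo = max(min(err), q[1] - 1.5 * iqr),
             whisker_hi = min(max(err), q[3] + 1.5 * iqr),
             iqr = iqr, n = length(err))
}

param_names <- c("v_cyl", "v_sph", "v_ext", "lambda_cyl", "lambda_sph")

## stack per-parameter error_stats rows for estimate/truth tables
stats_by_param <- function(est, truth) {
  out <- do.call(rbind, lapply(param_names, function(nm) {
    s <- error_stats(est[[nm]] - truth[[nm]])
    cbind(data.frame(parameter = nm), s)
  }))
  rownames(out) <- NULL
  out
}

## generate noisy powder signals for given params/violation and estimate
run_estimate <- function(model, p, violation_cfg = violation("none"),
                         snr = 25, seed = 1L, noise_model = "gaussian") {
  proto <- model$protocol
  S <- violated_powder_signal(p, proto, violation_cfg, seed = seed + 1L)
  sigma <- if (is.finite(snr)) 1 / snr else 0
  sig_shell <- shell_sigma(proto, rep(sigma, nrow(p)))
  Sn <- add_noise(S, sig_shell, model = noise_model, seed = seed)
  estimate_params(model, Sn, sigma)
}

#' Bias and precision maps over the volume-fraction simplex
#'
#' For each point of the volume-fraction simplex grid crossed with a grid of
#' diffusivity pairs, synthesises `n_noise` noisy signal instances at the
#' given SNR, estimates parameters, and records per-parameter error
#' statistics.
#'
#' @param model trained `soma_estimator`
#' @param step simplex grid step (231 points at 0.05)
#' @param diffusivities vector of diffusivities (um^2/ms) crossed into
#'   `(lambda_cyl, lambda_sph)` pairs with `lambda_sph <= lambda_cyl`
#' @param n_noise noise instances per grid point
#' @param snr signal-to-noise ratio of a single measurement (`Inf` for
#'   noise-free)
#' @param seed RNG seed
#' @return data.frame: one row per (grid point, parameter) with the
#'   [error_stats()] columns plus the generating parameter values
#' @export
run_simplex_evaluation <- function(model, step = 0.05,
                                   diffusivities = seq(0.5, 3, by = 0.5),
                                   n_noise = 10000, snr = 25, seed = 1L) {
  stopifnot(inherits(model, "soma_estimator"))
  g <- simplex_grid(step)
  pairs <- expand.grid(lambda_cyl = diffusivities, lambda_sph = diffusivities)
  pairs <- pairs[pairs$lambda_sph <= pairs$lambda_cyl, ]
  out <- list()
  set.seed(seed)
  for (k in seq_len(nrow(pairs))) {
    for (i in seq_len(nrow(g))) {
      p1 <- tissue_params(g$v_cyl[i], g$v_sph[i],
                          pairs$lambda_cyl[k], pairs$lambda_sph[k])
      p <- p1[rep(1, n_noise), ]
      est <- run_estimate(model, p, snr = snr,
                          seed = sample.int(.Machine$integer.max %/% 2, 1))
      s <- stats_by_param(est, p)
      out[[length(out) + 1L]] <- cbind(p1[rep(1, nrow(s)), ], s)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimation-error sweeps over SNR or direction count
#'
#' Draws `n_samples` parameter sets from the full constrained prior and, for
#' each value of the sweep axis, synthesises noisy powder means and estimates
#' parameters. For the `"n_dirs"` axis the per-measurement SNR is held fixed
#' and the total direction budget per encoding is split over its shells, so
#' the powder-mean noise shrinks as `1/sqrt(n_dirs per shell)`. The same
#' trained network serves every direction count -- its inputs are powder
#' means, so only their noise level changes -- with the sigma input rescaled
#' as in [estimate_params()].
#'
#' @param model trained `soma_estimator`
#' @param axis `"snr"` or `"n_dirs"`
#' @param values sweep values: SNRs, or total directions per encoding
#' @param n_samples parameter draws per sweep value
#' @param snr fixed per-measurement SNR for the direction sweep
#' @param seed RNG seed
#' @return data.frame with one row per (axis value, parameter)
#' @export
run_sweep <- function(model, axis = c("snr", "n_dirs"),
                      values = if (axis == "snr") c(1, 5, 25, 50, 75, 100)
                               else c(16, 32, 48, 64, 96, 128, 224),
                      n_samples = 10000, snr = 25, seed = 1L) {
  axis <- match.arg(axis)
  stopifnot(inherits(model, "soma_estimator"))
  p <- sample_tissue_params(n_samples, seed = seed)
  n_total_model <- sum(model$protocol$shells$n_dirs)
  out <- list()
  for (v in values) {
    if (axis == "snr") {
      est <- run_estimate(model, p, snr = v, seed = seed + round(v))
    } else {
      ## same network; data acquired with v directions per encoding type
      ## (2 * v in total) instead of the trained budget
      sh <- model$protocol$shells
      scale <- sum(sh$n_dirs) / (2 * v)
      n_per_shell <- (2 * v) * sh$n_dirs / sum(sh$n_dirs)
      S <- violated_powder_signal(p, model$protocol, violation("none"))
      sigma <- 1 / snr
      sig_shell <- outer(rep(sigma, nrow(p)), 1 / sqrt(n_per_shell))
      Sn <- add_noise(S, sig_shell, seed = seed + round(v))
      est <- estimate_params(model, Sn, sigma * sqrt(scale))
    }
    s <- stats_by_param(est, p)
    out[[length(out) + 1L]] <- cbind(data.frame(axis = axis, value = v), s)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bias under systematic model violations
#'
#' Applies an idealised-model-trained estimator to synthetic data generated
#' under a sweep of one model violation, and reports per-parameter error
#' statistics against the appropriate gold standard ([gold_standard()]):
#' CSF errors are referenced to `v_ext + v_csf` for the extra-cellular
#' fraction, myelin errors to the `(1 - v_myelin)`-renormalised fractions.
#'
#' @param model trained `soma_estimator`
#' @param kind violation kind, see [violation()]
#' @param magnitudes vector of violation magnitudes (meaning depends on
#'   `kind`: `v_csf`, extra-cellular T2 in s, `lambda_perp_cyl`, `v_myelin`,
#'   `alpha`, `beta`, `var_sph`, or `k_t`)
#' @param n_samples uniform parameter draws per magnitude
#' @param snr per-measurement SNR
#' @param seed RNG seed
#' @param ... further arguments to [violation()] (e.g. `n_draws`)
#' @return data.frame with one row per (magnitude, parameter)
#' @export
run_violation_experiment <- function(model, kind, magnitudes,
                                     n_samples = 107520, snr = 25, seed = 1L,
                                     ...) {
  stopifnot(inherits(model, "soma_estimator"))
  mag_field <- switch(kind,
    csf = "v_csf", compartmental_t2 = "t2_ext", perp_stick = "lambda_perp_cyl",
    myelin = "v_myelin", tortuosity_perp = "alpha", tortuosity_both = "beta",
    gamma_sph = "var_sph", kurtosis = "k_t",
    stop("unknown violation kind: ", kind))
  p <- sample_tissue_params(n_samples, seed = seed)
  out <- list()
  for (j in seq_along(magnitudes)) {
    args <- list(kind = kind, ...)
    args[[mag_field]] <- magnitudes[j]
    vcfg <- do.call(violation, args)
    pj <- p
    if (kind == "kurtosis" && vcfg$k_t > 0) {
      ## keep the sphere signal monotone up to b_max, as in the generative model
      lmax <- 3 / (b_to_internal(vcfg$b_max) * vcfg$k_t)
      pj$lambda_sph <- pmin(pj$lambda_sph, lmax)
    }
    est <- run_estimate(model, pj, violation_cfg = vcfg, snr = snr,
                        seed = seed + 1000L * j)
    s <- stats_by_param(est, gold_standard(pj, vcfg))
    out[[length(out) + 1L]] <- cbind(data.frame(kind = kind, magnitude = magnitudes[j]), s)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' CSF-contamination bias as a function of the stick fraction
#'
#' Holds the CSF fraction fixed (default 0.1, representative of CSF partial
#' volume in grey matter) and varies the stick fraction over fixed bins; the
#' remaining parameters are sampled uniformly. With sticks present, the
#' extra-cellular tensor is anisotropic and cannot absorb free water, so the
#' CSF signal is instead attributed to high-diffusivity spheres -- the bias
#' grows with `v_cyl`.
#'
#' @param model trained `soma_estimator`
#' @param v_csf fixed CSF volume fraction
#' @param v_cyl_values stick-fraction bins
#' @param n_samples draws per bin
#' @param snr per-measurement SNR
#' @param seed RNG seed
#' @return data.frame with one row per (v_cyl bin, parameter)
#' @export
csf_vcyl_dependence <- function(model, v_csf = 0.1,
                                v_cyl_values = seq(0, 0.9, by = 0.1),
                                n_samples = 5000, snr = 25, seed = 1L) {
  stopifnot(inherits(model, "soma_estimator"))
  vcfg <- violation("csf", v_csf = v_csf)
  out <- list()
  for (j in seq_along(v_cyl_values)) {
    vc <- v_cyl_values[j]
    set.seed(seed + j)
    ## v_cyl fixed; split the remainder uniformly between sphere and
    ## extra-cellular space; diffusivities from the ordered-simplex prior
    u <- stats::runif(n_samples)
    base <- sample_tissue_params(n_samples)
    p <- tissue_params(v_cyl = rep(vc, n_samples), v_sph = (1 - vc) * u,
                       lambda_cyl = base$lambda_cyl, lambda_sph = base$lambda_sph)
    est <- run_estimate(model, p, violation_cfg = vcfg, snr = snr, seed = seed + 100L * j)
    s <- stats_by_param(est, gold_standard(p, vcfg))
    out[[length(out) + 1L]] <- cbind(data.frame(v_cyl_bin = vc), s)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
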