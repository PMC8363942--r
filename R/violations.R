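#' Configure a departure from the idealised model
#'
#' Describes one generative violation of the three-compartment model
#' assumptions, used to synthesise test data that the (idealised-model-trained)
#' estimator is then applied to. Exactly one `kind` is active:
#'
#' * `"none"` -- the idealised model itself.
#' * `"csf"` -- a fourth free-water compartment (diffusivity 3 um^2/ms) of
#'   fraction `v_csf` with its own T2 (`t2_csf`, default 2 s) against a common
#'   tissue T2 (`t2_tissue`, default 0.1 s).
#' * `"compartmental_t2"` -- intra-cellular (stick + sphere) T2 fixed at
#'   `t2_intra` (default 0.1 s), extra-cellular T2 = `t2_ext`.
#' * `"perp_stick"` -- non-zero perpendicular stick diffusivity
#'   `lambda_perp_cyl` (um^2/ms).
#' * `"myelin"` -- an MR-invisible myelin fraction `v_myelin` occupying space,
#'   with the tortuosity exponents adjusted to count myelin among the
#'   hindering structures.
#' * `"tortuosity_perp"` -- perpendicular extra-cellular diffusivity scaled by
#'   `alpha` (clipped at the free diffusivity; the parallel one raised to keep
#'   the ordering).
#' * `"tortuosity_both"` -- both extra-cellular diffusivities scaled by `beta`
#'   and clipped at the free diffusivity.
#' * `"gamma_sph"` -- sphere diffusivities drawn from a gamma distribution
#'   with mean `lambda_sph` and variance `var_sph` ((um^2/ms)^2); the sphere
#'   term is the mean signal over `n_draws` draws.
#' * `"kurtosis"` -- sphere log-signal gains a quadratic term:
#'   `exp(-b lambda_sph + (1/6) k_t b^2 lambda_sph^2)`; requires
#'   `lambda_sph <= 3 / (b_max k_t)` for `k_t > 0` so the signal is monotone
#'   up to `b_max`.
#'
#' @param kind violation kind, see above
#' @param v_csf,t2_csf,t2_tissue,t2_intra,t2_ext,lambda_perp_cyl,v_myelin
#'   kind-specific magnitudes (times in s, diffusivities in um^2/ms)
#' @param alpha,beta tortuosity perturbation factors, typically in `[0.5, 1.5]`
#' @param var_sph,n_draws gamma-distribution variance and number of draws
#' @param k_t,b_max total kurtosis and the maximum protocol b-value (s/mm^2)
#'   used in the monotonicity constraint
#' @return object of class `soma_violation`
#' @export
violation <- function(kind = c("none", "csf", "compartmental_t2", "perp_stick",
                               "myelin", "tortuosity_perp", "tortuosity_both",
                               "gamma_sph", "kurtosis"),
                      v_csf = 0.1, t2_csf = 2, t2_tissue = 0.1,
                      t2_intra = 0.1, t2_ext = 0.03,
                      lambda_perp_cyl = 0.01, v_myelin = 0.1,
                      alpha = 1, beta = 1,
                      var_sph = 0.05, n_draws = 10000,
                      k_t = 0, b_max = 5000) {
  kind <- match.arg(kind)
  v <- list(kind = kind, v_csf = v_csf, t2_csf = t2_csf, t2_tissue = t2_tissue,
            t2_intra = t2_intra, t2_ext = t2_ext,
            lambda_perp_cyl = lambda_perp_cyl, v_myelin = v_myelin,
            alpha = alpha, beta = beta, var_sph = var_sph,
            n_draws = as.integer(n_draws), k_t = k_t, b_max = b_max)
  stopifnot(v$v_csf >= 0, v$v_csf <= 1, v$v_myelin >= 0, v$v_myelin < 1,
            v$lambda_perp_cyl >= 0, v$alpha > 0, v$beta > 0, v$var_sph >= 0,
            v$t2_csf > 0, v$t2_tissue > 0, v$t2_intra > 0, v$t2_ext > 0)
  class(v) <- "soma_violation"
  v
}

#' Powder signal under a model violation
#'
#' Generates T2-normalised powder-averaged signals from one of the violated
#' generative models described in [violation()]. Where compartments carry
#' different T2 weights, the b = 0 reference carries the same weights, so the
#' effective signal fractions are
#' `f_i = v_i exp(-TE/T2_i) / sum_j v_j exp(-TE/T2_j)` at the protocol's echo
#' time. With `kind = "none"` this reduces exactly to [powder_signal()].
#'
#' @param p tissue parameter table; fractions are the tissue-internal
#'   (3-simplex) fractions, which CSF and myelin variants scale down by their
#'   extra fraction
#' @param shells a `soma_protocol` (needed for its echo time by the T2
#'   variants) or a shells data.frame
#' @param v a `soma_violation`
#' @param te_ms echo time override, ms; defaults to the protocol's
#' @param seed RNG seed for the gamma draws of `kind = "gamma_sph"`
#' @return n x n_shell signal matrix
#' @export
violated_powder_signal <- function(p, shells, v, te_ms = NULL, seed = 1L) {
  stopifnot(inherits(v, "soma_violation"))
  sh <- shells_of(shells)
  if (is.null(te_ms)) te_ms <- if (inherits(shells, "soma_protocol")) shells$te_ms else 94
  te <- te_ms / 1000
  b <- b_to_internal(sh$b)
  bd <- sh$b_delta
  n <- nrow(p); m <- nrow(sh)
  B <- matrix(b, n, m, byrow = TRUE)

  switch(v$kind,
    none = powder_signal(p, sh),

    csf = {
      fac <- compartment_factors(p, b, bd)
      w_t <- exp(-te / v$t2_tissue)
      w_c <- exp(-te / v$t2_csf)
      s_csf <- exp(-B * LAMBDA_FREE)
      num <- (1 - v$v_csf) * w_t * (p$v_cyl * fac$cyl + p$v_sph * fac$sph + p$v_ext * fac$ext) +
        v$v_csf * w_c * s_csf
      den <- (1 - v$v_csf) * w_t + v$v_csf * w_c
      num / den
    },

    compartmental_t2 = {
      fac <- compartment_factors(p, b, bd)
      w_in <- exp(-te / v$t2_intra)
      w_ex <- exp(-te / v$t2_ext)
      num <- w_in * (p$v_cyl * fac$cyl + p$v_sph * fac$sph) + w_ex * p$v_ext * fac$ext
      den <- w_in * (p$v_cyl + p$v_sph) + w_ex * p$v_ext
      num / den
    },

    perp_stick = {
      fac <- compartment_factors(p, b, bd, lambda_perp_cyl = v$lambda_perp_cyl)
      p$v_cyl * fac$cyl + p$v_sph * fac$sph + p$v_ext * fac$ext
    },

    myelin = {
      vm <- v$v_myelin
      vc <- p$v_cyl * (1 - vm); vs <- p$v_sph * (1 - vm); ve <- p$v_ext * (1 - vm)
      e <- vs + vc + vm
      epar <- ifelse(e > 0, 0.5 * vs / e, 0)
      eperp <- ifelse(e > 0, (0.5 * vs + vc + vm) / e, 0)
      ext <- data.frame(lambda_par = p$lambda_cyl * ve^epar,
                        lambda_perp = p$lambda_cyl * ve^eperp)
      fac <- compartment_factors(p, b, bd, ext_tensor = ext)
      ## myelin is signal-free at all b including b = 0, so the visible
      ## fractions renormalise back to the 3-simplex values
      p$v_cyl * fac$cyl + p$v_sph * fac$sph + p$v_ext * fac$ext
    },

    tortuosity_perp = {
      ext0 <- tortuosity(p$v_cyl, p$v_sph, p$v_ext, p$lambda_cyl)
      lp <- pmin(v$alpha * ext0$lambda_perp, LAMBDA_FREE)
      ext <- data.frame(lambda_par = pmax(lp, ext0$lambda_par), lambda_perp = lp)
      fac <- compartment_factors(p, b, bd, ext_tensor = ext)
      p$v_cyl * fac$cyl + p$v_sph * fac$sph + p$v_ext * fac$ext
    },

    tortuosity_both = {
      ext0 <- tortuosity(p$v_cyl, p$v_sph, p$v_ext, p$lambda_cyl)
      ext <- data.frame(lambda_par = pmin(v$beta * ext0$lambda_par, LAMBDA_FREE),
                        lambda_perp = pmin(v$beta * ext0$lambda_perp, LAMBDA_FREE))
      fac <- compartment_factors(p, b, bd, ext_tensor = ext)
      p$v_cyl * fac$cyl + p$v_sph * fac$sph + p$v_ext * fac$ext
    },

    gamma_sph = {
      fac <- compartment_factors(p, b, bd)
      sph <- matrix(0, n, m)
      if (v$var_sph <= 0) {
        sph <- fac$sph
      } else {
        set.seed(seed)
        for (i in seq_len(n)) {
          mu <- p$lambda_sph[i]
          if (mu <= 0) { sph[i, ] <- 1; next }
          shape <- mu^2 / v$var_sph
          lam <- stats::rgamma(v$n_draws, shape = shape, scale = v$var_sph / mu)
          sph[i, ] <- colMeans(exp(-outer(lam, b)))
        }
      }
      p$v_cyl * fac$cyl + p$v_sph * sph + p$v_ext * fac$ext
    },

    kurtosis = {
      if (v$k_t > 0) {
        lmax <- 3 / (b_to_internal(v$b_max) * v$k_t)
        if (any(p$lambda_sph > lmax + 1e-9)) {
          stop("kurtosis constraint violated: lambda_sph must be <= 3/(b_max * k_t) = ",
               format(lmax), " um^2/ms for k_t = ", v$k_t)
        }
      }
      fac <- compartment_factors(p, b, bd)
      sph <- exp(-B * p$lambda_sph + (1 / 6) * v$k_t * B^2 * p$lambda_sph^2)
      p$v_cyl * fac$cyl + p$v_sph * sph + p$v_ext * fac$ext
    }
  )
}

#' Gold-standard parameter values under a violation
#'
#' Reference values against which estimates from violated data are compared.
#' For CSF, the free-water fraction is expected to be absorbed by the
#' extra-cellular compartment, so the extra-cellular gold standard is
#' `v_ext (1 - v_csf) + v_csf` while stick and sphere standards are the
#' MR-visible `v_i (1 - v_csf)`. For myelin, fractions are referenced to the
#' MR-visible volume, i.e. the actual fractions divided by `(1 - v_myelin)`,
#' which equals the tissue-internal 3-simplex values. Other kinds leave the
#' reference untouched.
#'
#' @param p tissue parameter table as passed to [violated_powder_signal()]
#' @param v a `soma_violation`
#' @return data.frame with the same columns as `p`
#' @export
gold_standard <- function(p, v) {
  stopifnot(inherits(v, "soma_violation"))
  g <- p
  if (v$kind == "csf") {
    g$v_cyl <- p$v_cyl * (1 - v$v_csf)
    g$v_sph <- p$v_sph * (1 - v$v_csf)
    g$v_ext <- p$v_ext * (1 - v$v_csf) + v$v_csf
  }
  ## myelin: actual fractions are v_i (1 - v_myelin); dividing by
  ## (1 - v_myelin) restores the tissue-internal values already in p
  g
}
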