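#' Tissue parameter table
#'
#' The biophysical state of a voxel (or many voxels, row-wise): volume
#' fractions of cylindrical (neural projections), spherical (neural soma) and
#' extra-cellular compartments, with the two free diffusivities. The
#' extra-cellular fraction is `1 - v_cyl - v_sph`. Constraints enforced:
#' fractions in `[0, 1]` summing to one, and
#' `0 <= lambda_sph <= lambda_cyl <= 3` um^2/ms.
#'
#' @param v_cyl cylindrical (stick) volume fraction
#' @param v_sph spherical volume fraction
#' @param lambda_cyl parallel stick diffusivity, um^2/ms (the intrinsic
#'   neural diffusivity; also the `lambda` entering the tortuosity model)
#' @param lambda_sph apparent spherical diffusivity, um^2/ms
#' @return data.frame with columns `v_cyl`, `v_sph`, `v_ext`, `lambda_cyl`,
#'   `lambda_sph`
#' @export
tissue_params <- function(v_cyl, v_sph, lambda_cyl, lambda_sph) {
  p <- data.frame(v_cyl = v_cyl, v_sph = v_sph, v_ext = 1 - v_cyl - v_sph,
                  lambda_cyl = lambda_cyl, lambda_sph = lambda_sph)
  tol <- 1e-9
  if (any(p$v_cyl < -tol | p$v_sph < -tol | p$v_ext < -tol |
          p$v_cyl > 1 + tol | p$v_sph > 1 + tol)) {
    stop("volume fractions must lie in [0, 1] and sum to at most 1")
  }
  if (any(p$lambda_sph < -tol | p$lambda_sph > p$lambda_cyl + tol |
          p$lambda_cyl > LAMBDA_FREE + tol)) {
    stop("diffusivities must satisfy 0 <= lambda_sph <= lambda_cyl <= ",
         LAMBDA_FREE, " um^2/ms")
  }
  p$v_ext <- pmin(pmax(p$v_ext, 0), 1)
  p
}

#' Tortuosity approximation for extra-cellular diffusivity
#'
#' Hindered extra-cellular diffusion parallel and perpendicular to the stick
#' axis, from the power-law tortuosity model: with `e = v_sph + v_cyl`,
#' `lambda_par_ext  = lambda * v_ext ^ (0.5 v_sph / e)` and
#' `lambda_perp_ext = lambda * v_ext ^ ((0.5 v_sph + v_cyl) / e)`.
#' When no cellular structures are present (`e = 0`) the extra-cellular space
#' behaves as free water and both diffusivities equal `lambda`.
#'
#' @param v_cyl,v_sph,v_ext volume fractions
#' @param lambda_cyl intrinsic diffusivity `lambda`, um^2/ms
#' @return data.frame with columns `lambda_par`, `lambda_perp` (um^2/ms),
#'   satisfying `lambda_perp <= lambda_par <= lambda_cyl`
#' @export
tortuosity <- function(v_cyl, v_sph, v_ext, lambda_cyl) {
  e <- v_sph + v_cyl
  epar <- ifelse(e > 0, 0.5 * v_sph / e, 0)
  eperp <- ifelse(e > 0, (0.5 * v_sph + v_cyl) / e, 0)
  ## v_ext^0 := 1 covers both the free-water limit and v_sph = 0
  data.frame(lambda_par = lambda_cyl * v_ext^epar,
             lambda_perp = lambda_cyl * v_ext^eperp)
}

## sqrt(pi)/2 * erf(sqrt(x))/sqrt(x), continued to x <= 0.
## x > 0: anisotropy attenuation factor of the powder average;
## x = 0: limit 1 (erf(t)/t -> 2/sqrt(pi));
## x < 0 (planar-like b_delta < 0): imaginary-error-function branch.
## Series for |x| < 1e-6 avoids 0/0.
powder_aniso_factor <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-6
  out[small] <- 1 - x[small] / 3 + x[small]^2 / 10
  pos <- !small & x > 0
  if (any(pos)) {
    sx <- sqrt(x[pos])
    out[pos] <- sqrt(pi) / 2 * pracma::erf(sx) / sx
  }
  neg <- !small & x < 0
  if (any(neg)) {
    sx <- sqrt(-x[neg])
    out[neg] <- sqrt(pi) / 2 * pracma::erfi(sx) / sx
  }
  out
}

#' Powder-averaged signal of one axially symmetric Gaussian compartment
#'
#' Orientation average of `exp(-B : D)` over uniformly distributed microdomain
#' orientations, for an axially symmetric b-tensor of shape `b_delta` and an
#' axially symmetric diffusion tensor `(lambda_par, lambda_perp)`:
#' `f(x) * exp(-b * ((1 - b_delta)/3 * lambda_par + (2 + b_delta)/3 * lambda_perp))`
#' with `x = b * b_delta * (lambda_par - lambda_perp)` and
#' `f(x) = sqrt(pi)/2 * erf(sqrt(x)) / sqrt(x)` (continuous at 0).
#'
#' @param b b-value in ms/um^2 (internal units; divide s/mm^2 by 1000)
#' @param b_delta b-tensor shape
#' @param lambda_par,lambda_perp compartment diffusivities, um^2/ms
#' @return signal fraction in (0, 1]; arguments recycle
#' @export
compartment_powder_term <- function(b, b_delta, lambda_par, lambda_perp) {
  x <- b * b_delta * (lambda_par - lambda_perp)
  powder_aniso_factor(x) *
    exp(-b * ((1 - b_delta) / 3 * lambda_par + (2 + b_delta) / 3 * lambda_perp))
}

## internal: per-compartment powder factors for a parameter table.
## Returns list of n x n_shell matrices: cyl, sph, ext.
## b_int: vector of b in ms/um^2; bd: vector of b_delta.
compartment_factors <- function(p, b_int, bd,
                                lambda_perp_cyl = 0,
                                ext_tensor = NULL) {
  n <- nrow(p)
  m <- length(b_int)
  B <- matrix(b_int, n, m, byrow = TRUE)
  BD <- matrix(bd, n, m, byrow = TRUE)
  if (is.null(ext_tensor)) {
    ext_tensor <- tortuosity(p$v_cyl, p$v_sph, p$v_ext, p$lambda_cyl)
  }
  list(
    cyl = compartment_powder_term(B, BD, p$lambda_cyl, pmin(lambda_perp_cyl, p$lambda_cyl)),
    sph = compartment_powder_term(B, BD, p$lambda_sph, p$lambda_sph),
    ext = compartment_powder_term(B, BD, ext_tensor$lambda_par, ext_tensor$lambda_perp)
  )
}

shells_of <- function(shells) {
  if (inherits(shells, "soma_protocol")) shells$shells else shells
}

#' Powder-averaged three-compartment signal
#'
#' T2-normalised powder mean of the three-compartment model, one value per
#' shell: the volume-fraction-weighted sum of [compartment_powder_term()] over
#' the stick `(lambda_cyl, 0)`, the sphere `(lambda_sph, lambda_sph)` and the
#' extra-cellular tensor from [tortuosity()].
#'
#' @param p tissue parameter table ([tissue_params()]), n rows
#' @param shells a `soma_protocol` or its `shells` data.frame (b in s/mm^2)
#' @return n x n_shell matrix of signals in (0, 1]
#' @export
powder_signal <- function(p, shells) {
  sh <- shells_of(shells)
  fac <- compartment_factors(p, b_to_internal(sh$b), sh$b_delta)
  p$v_cyl * fac$cyl + p$v_sph * fac$sph + p$v_ext * fac$ext
}

#' Directional microdomain signal
#'
#' Signal of a single coherently oriented microdomain for an arbitrary
#' b-tensor: `sum_i v_i exp(-B : D_i(phi))` where `phi` is the common symmetry
#' axis of the stick and extra-cellular tensors. Serves as the directional
#' generator; its orientation average over uniform axes equals
#' [powder_signal()].
#'
#' @param bt 3x3 b-tensor, s/mm^2 (e.g. [make_btensor()])
#' @param p single-row tissue parameter table
#' @param phi unit 3-vector, symmetry axis of the microdomain
#' @return scalar signal
#' @export
microdomain_signal <- function(bt, p, phi) {
  stopifnot(nrow(p) == 1L, length(phi) == 3L)
  phi <- phi / sqrt(sum(phi^2))
  bt_i <- bt / B_UNIT  # ms/um^2 per element
  tr_b <- sum(diag(bt_i))
  bnn <- as.numeric(t(phi) %*% bt_i %*% phi)
  ext <- tortuosity(p$v_cyl, p$v_sph, p$v_ext, p$lambda_cyl)
  ## for axially symmetric D: B : D = lambda_perp * Tr(B) + (lambda_par - lambda_perp) * phi' B phi
  bd_cyl <- p$lambda_cyl * bnn
  bd_sph <- p$lambda_sph * tr_b
  bd_ext <- ext$lambda_perp * tr_b + (ext$lambda_par - ext$lambda_perp) * bnn
  p$v_cyl * exp(-bd_cyl) + p$v_sph * exp(-bd_sph) + p$v_ext * exp(-bd_ext)
}
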