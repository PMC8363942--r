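logit <- function(p) log(p) - log(1 - p)
inv_logit <- function(z) 1 / (1 + exp(-z))

#' Map tissue parameters to the unbounded logit targets
#'
#' The estimator regresses four unbounded quantities whose inverse transform
#' is guaranteed to satisfy all model constraints:
#' `z1 = logit(v_cyl + v_sph)`, `z2 = logit(v_cyl / (v_cyl + v_sph))`,
#' `z3 = logit(lambda_cyl / 3)`, `z4 = logit(lambda_sph / lambda_cyl)`.
#' Ratios are clipped into `[eps, 1 - eps]` before the logit; boundary inputs
#' (e.g. `v_cyl + v_sph = 0`) therefore map to large finite values.
#'
#' @param p tissue parameter table
#' @param eps boundary clipping, default 1e-6
#' @return n x 4 matrix with columns `z1..z4`
#' @export
params_to_logits <- function(p, eps = 1e-6) {
  clip <- function(x) pmin(pmax(x, eps), 1 - eps)
  vtot <- p$v_cyl + p$v_sph
  z <- cbind(z1 = logit(clip(vtot)),
             z2 = logit(clip(ifelse(vtot > 0, p$v_cyl / vtot, 0.5))),
             z3 = logit(clip(p$lambda_cyl / LAMBDA_FREE)),
             z4 = logit(clip(ifelse(p$lambda_cyl > 0,
                                    p$lambda_sph / p$lambda_cyl, 0.5))))
  z
}

#' Invert the logit transform
#'
#' Any real `(z1, z2, z3, z4)` maps to a valid tissue parameter table:
#' fractions in `[0, 1]` summing to 1 and
#' `0 <= lambda_sph <= lambda_cyl <= 3` um^2/ms, by construction.
#'
#' @param z n x 4 numeric matrix of logits
#' @return tissue parameter table with `n` rows
#' @export
logits_to_params <- function(z) {
  z <- rbind(z)  # tolerate a bare length-4 vector
  if (is.null(dim(z)) || ncol(z) != 4L) stop("z must have four columns")
  vtot <- inv_logit(z[, 1])
  r <- inv_logit(z[, 2])
  lambda_cyl <- LAMBDA_FREE * inv_logit(z[, 3])
  lambda_sph <- lambda_cyl * inv_logit(z[, 4])
  p <- tissue_params(v_cyl = unname(vtot * r), v_sph = unname(vtot * (1 - r)),
                     lambda_cyl = unname(lambda_cyl),
                     lambda_sph = unname(lambda_sph))
  rownames(p) <- NULL
  p
}
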