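#' Powder-average a directional diffusion-weighted volume
#'
#' Collapses a 4-D diffusion-weighted data set (x, y, z, volume) with a
#' per-volume scheme table into per-shell T2-normalised powder means: per
#' voxel, `S0` is the mean over the b = 0 volumes, each shell's signal is the
#' mean of `S / S0` over that shell's directions, and the per-measurement
#' noise level sigma is estimated as the sample standard deviation over the
#' b = 0 repeats divided by `S0`.
#'
#' @param dwi 4-D numeric array, or a path to a NIfTI file (read with
#'   RNifti; any affine/orientation metadata is carried through)
#' @param scheme data.frame from [read_scheme()] with one row per volume
#' @param protocol optional `soma_protocol` defining the expected shell
#'   order; defaults to the protocol inferred from the scheme
#' @param mask optional logical 3-D array; voxels outside it (or with
#'   non-positive `S0`) yield `NA`
#' @return object of class `powder_volume`: list with `signals` (4-D array,
#'   x,y,z,shell), `sigma` (3-D), `mask` (3-D logical), `protocol`, and any
#'   source image metadata in `reference`
#' @export
powder_average <- function(dwi, scheme, protocol = NULL, mask = NULL) {
  reference <- NULL
  if (is.character(dwi)) {
    img <- RNifti::readNifti(dwi)
    reference <- img
    dwi <- as.array(img)
  }
  stopifnot(length(dim(dwi)) == 4L)
  if (dim(dwi)[4] != nrow(scheme)) {
    stop("scheme has ", nrow(scheme), " rows but volume has ", dim(dwi)[4], " frames")
  }
  if (is.null(protocol)) protocol <- protocol_from_scheme(scheme)
  sh <- protocol$shells
  b0 <- which(scheme$b == 0)
  if (length(b0) == 0L) stop("no b = 0 volumes in scheme")

  dims <- dim(dwi)[1:3]
  nvox <- prod(dims)
  Y <- matrix(dwi, nvox, dim(dwi)[4])
  s0 <- rowMeans(Y[, b0, drop = FALSE])
  sig <- if (length(b0) > 1L) apply(Y[, b0, drop = FALSE], 1L, stats::sd) else rep(0, nvox)

  ok <- s0 > 0
  if (!is.null(mask)) ok <- ok & as.logical(mask)
  sig_n <- ifelse(ok, sig / s0, NA_real_)

  S <- matrix(NA_real_, nvox, nrow(sh))
  for (k in seq_len(nrow(sh))) {
    rows <- which(scheme$b == sh$b[k] & scheme$b_delta == sh$b_delta[k])
    if (length(rows) == 0L) {
      stop("scheme contains no volumes for shell b = ", sh$b[k],
           ", b_delta = ", sh$b_delta[k])
    }
    S[ok, k] <- rowMeans(Y[ok, rows, drop = FALSE]) / s0[ok]
  }

  structure(list(signals = array(S, c(dims, nrow(sh))),
                 sigma = array(sig_n, dims),
                 mask = array(ok, dims),
                 protocol = protocol,
                 reference = reference),
            class = "powder_volume")
}

#' Specify a synthetic phantom
#'
#' Labelled-region phantom standing in for an in-vivo acquisition: a 3-D
#' label image where each region carries its own tissue parameters and,
#' optionally, a generative model violation. The default geometry is a
#' 64 x 64 x 8 volume with four bands: white-matter-like, grey-matter-like,
#' CSF-like, and a CSF-contaminated white-matter interface strip (the
#' headline failure mode of CSF partial volume next to coherent fibres).
#'
#' @param dims image dimensions, length 3
#' @param snr per-measurement SNR of the synthesised data
#' @return object of class `phantom_spec`; its `regions` list maps label
#'   names to `list(params = <tissue_params row>, violation = <violation>)`
#' @export
default_phantom_spec <- function(dims = c(64, 64, 8), snr = 25) {
  labels <- array(0L, dims)
  nx <- dims[1]
  q <- round(nx * c(0.3, 0.55, 0.7))
  labels[1:q[1], , ] <- 1L                  # WM-like
  labels[(q[1] + 1):q[2], , ] <- 2L         # GM-like
  labels[(q[2] + 1):q[3], , ] <- 3L         # CSF-like
  labels[(q[3] + 1):nx, , ] <- 4L           # CSF/WM interface
  regions <- list(
    wm = list(params = tissue_params(0.70, 0.10, 2.3, 0.6),
              violation = violation("none")),
    gm = list(params = tissue_params(0.25, 0.40, 2.0, 0.6),
              violation = violation("none")),
    csf = list(params = tissue_params(0, 0, 3.0, 1.0),
               violation = violation("none")),
    interface = list(params = tissue_params(0.70, 0.10, 2.3, 0.6),
                     violation = violation("csf", v_csf = 0.3))
  )
  structure(list(labels = labels, regions = regions, snr = snr),
            class = "phantom_spec")
}

#' Synthesise a phantom data set
#'
#' Generates per-voxel powder-averaged signals for a [default_phantom_spec()]
#' style specification under the given protocol, with Gaussian noise at the
#' spec's SNR scaled per shell for the powder mean, and returns the matched
#' ground-truth parameter maps.
#'
#' @param spec a `phantom_spec`
#' @param protocol a `soma_protocol`
#' @param seed RNG seed
#' @return list: `volume` (a `powder_volume`), `truth` (data.frame of
#'   per-voxel generating parameters, `NA` outside regions), `labels`
#' @export
generate_phantom <- function(spec, protocol = default_protocol(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- dim(spec$labels)
  nvox <- prod(dims)
  m <- nrow(protocol$shells)
  lab <- as.integer(spec$labels)
  S <- matrix(NA_real_, nvox, m)
  truth <- data.frame(v_cyl = rep(NA_real_, nvox), v_sph = NA_real_,
                      v_ext = NA_real_, lambda_cyl = NA_real_,
                      lambda_sph = NA_real_)
  sigma <- 1 / spec$snr
  set.seed(seed)
  for (r in seq_along(spec$regions)) {
    idx <- which(lab == r)
    if (length(idx) == 0L) next
    reg <- spec$regions[[r]]
    p <- reg$params[rep(1, length(idx)), ]
    s <- violated_powder_signal(p, protocol, reg$violation,
                                seed = seed + r)
    sig_shell <- shell_sigma(protocol, rep(sigma, length(idx)))
    S[idx, ] <- add_noise(s, sig_shell)
    g <- gold_standard(p, reg$violation)
    truth[idx, names(g)] <- g
  }
  mask <- array(lab > 0L, dims)
  vol <- structure(list(signals = array(S, c(dims, m)),
                        sigma = array(ifelse(lab > 0L, sigma, NA_real_), dims),
                        mask = mask, protocol = protocol, reference = NULL),
                   class = "powder_volume")
  list(volume = vol, truth = truth, labels = spec$labels)
}

#' Fit a powder volume voxel-wise
#'
#' Runs the estimator over all masked voxels of a `powder_volume` and returns
#' parameter maps plus the root-mean-square residual between the idealised
#' model prediction at the estimates and the measured shell means.
#'
#' @param model trained `soma_estimator`
#' @param pv a `powder_volume` whose protocol fingerprint matches the model
#' @return list of 3-D maps: `v_cyl`, `v_sph`, `v_ext`, `lambda_cyl`,
#'   `lambda_sph`, `lambda_par_ext`, `lambda_perp_ext`, `rms_residual`, plus
#'   `mask` and a per-voxel `estimates` data.frame
#' @export
fit_volume <- function(model, pv) {
  stopifnot(inherits(model, "soma_estimator"), inherits(pv, "powder_volume"))
  dims <- dim(pv$mask)
  m <- dim(pv$signals)[4]
  S <- matrix(pv$signals, prod(dims), m)
  sig <- as.numeric(pv$sigma)
  idx <- which(as.logical(pv$mask) & rowSums(!is.finite(S)) == 0L)
  est <- estimate_params(model, S[idx, , drop = FALSE], sig[idx],
                         protocol = pv$protocol)
  pred <- powder_signal(est, pv$protocol)
  rms <- sqrt(rowMeans((pred - S[idx, , drop = FALSE])^2))

  blank <- array(NA_real_, dims)
  maps <- list()
  for (nm in c("v_cyl", "v_sph", "v_ext", "lambda_cyl", "lambda_sph",
               "lambda_par_ext", "lambda_perp_ext")) {
    mp <- blank
    mp[idx] <- est[[nm]]
    maps[[nm]] <- mp
  }
  rr <- blank
  rr[idx] <- rms
  maps$rms_residual <- rr
  maps$mask <- pv$mask
  maps$estimates <- est
  maps
}

#' Write parameter maps as NIfTI files
#'
#' One file per map, named `<prefix>_<parameter>.nii.gz`, inheriting the
#' geometry of a reference image when available.
#'
#' @param maps list of 3-D arrays as returned by [fit_volume()]
#' @param prefix output path prefix
#' @param reference optional RNifti image whose header is reused
#' @return invisible character vector of paths written
#' @export
write_parameter_maps <- function(maps, prefix, reference = NULL) {
  nm <- intersect(names(maps),
                  c("v_cyl", "v_sph", "v_ext", "lambda_cyl", "lambda_sph",
                    "lambda_par_ext", "lambda_perp_ext", "rms_residual"))
  paths <- character(0)
  for (k in nm) {
    path <- paste0(prefix, "_", k, ".nii.gz")
    img <- maps[[k]]
    if (!is.null(reference)) {
      img <- RNifti::asNifti(img, reference = reference)
    }
    RNifti::writeNifti(img, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
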