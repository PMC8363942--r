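test_that("powder averaging normalises and groups shells correctly", {
  proto <- default_protocol(n_dirs_total = 8)
  sc <- scheme_from_protocol(proto)
  dims <- c(4, 4, 2)
  ## constant signal: every shell mean is exactly 1, sigma is 0
  dwi <- array(3.7, c(dims, nrow(sc)))
  pv <- powder_average(dwi, sc)
  expect_s3_class(pv, "powder_volume")
  expect_equal(dim(pv$signals), c(dims, 8))
  expect_equal(as.numeric(pv$signals), rep(1, prod(dims) * 8), tolerance = 1e-12)
  expect_equal(as.numeric(pv$sigma), rep(0, prod(dims)), tolerance = 1e-12)
  expect_true(all(pv$mask))

  ## row-count mismatch is refused
  expect_error(powder_average(dwi[, , , 1:10], sc), "scheme has")
})

test_that("powder average of directional data matches the analytic powder mean", {
  ## one voxel populated by identical coherent microdomains: averaging the
  ## directional signals over a uniform direction set approximates the
  ## orientation integral
  proto <- default_protocol(n_dirs_total = 192)
  sc <- scheme_from_protocol(proto)
  p <- tissue_params(0.5, 0.2, 2.2, 0.6)
  axis <- c(0.36, 0.48, 0.8)
  sig <- vapply(seq_len(nrow(sc)), function(i) {
    if (sc$b[i] == 0) return(1)
    bt <- make_btensor(sc$b[i], sc$b_delta[i], c(sc$nx[i], sc$ny[i], sc$nz[i]))
    microdomain_signal(bt, p, axis)
  }, numeric(1))
  dwi <- array(rep(sig, each = 4), c(2, 2, 1, nrow(sc)))
  pv <- powder_average(dwi, sc)
  ref <- powder_signal(p, proto)
  expect_equal(pv$signals[1, 1, 1, ], as.numeric(ref), tolerance = 0.02)

  ## rotating the substrate leaves the shell means essentially unchanged
  axis2 <- c(1, 0, 0)
  sig2 <- vapply(seq_len(nrow(sc)), function(i) {
    if (sc$b[i] == 0) return(1)
    bt <- make_btensor(sc$b[i], sc$b_delta[i], c(sc$nx[i], sc$ny[i], sc$nz[i]))
    microdomain_signal(bt, p, axis2)
  }, numeric(1))
  dwi2 <- array(rep(sig2, each = 4), c(2, 2, 1, nrow(sc)))
  pv2 <- powder_average(dwi2, sc)
  expect_equal(pv2$signals[1, 1, 1, ], pv$signals[1, 1, 1, ], tolerance = 0.03)
})

test_that("sigma is estimated from b0 repeats", {
  proto <- default_protocol(n_dirs_total = 8)
  sc <- scheme_from_protocol(proto)
  dims <- c(6, 6, 2)
  set.seed(24)
  s0 <- 100
  dwi <- array(s0 * 0.5, c(dims, nrow(sc)))
  b0_idx <- which(sc$b == 0)
  dwi[, , , b0_idx] <- s0 + rnorm(prod(dims) * length(b0_idx), sd = 4)
  pv <- powder_average(dwi, sc)
  ## normalised sigma near 4 / 100; the 12-repeat sd estimator is biased
  ## low by the usual c4(12) = 0.978 factor
  expect_lt(abs(mean(pv$sigma) - 0.04), 0.003)
})

test_that("NIfTI round trip preserves the volume", {
  skip_if_not_installed("RNifti")
  proto <- default_protocol(n_dirs_total = 8)
  sc <- scheme_from_protocol(proto)
  dims <- c(4, 4, 2)
  set.seed(25)
  dwi <- array(runif(prod(dims) * nrow(sc), 50, 100), c(dims, nrow(sc)))
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(dwi), f)
  pv <- powder_average(f, sc)
  pv2 <- powder_average(dwi, sc)
  expect_equal(pv$signals, pv2$signals, tolerance = 1e-6)
  expect_false(is.null(pv$reference))
})

test_that("phantom generation and volume fitting round-trip", {
  m <- quick_model()
  spec <- default_phantom_spec(dims = c(12, 12, 2), snr = 25)
  ph <- generate_phantom(spec, seed = 26)
  expect_s3_class(ph$volume, "powder_volume")
  expect_equal(dim(ph$volume$signals)[1:3], c(12, 12, 2))
  ## truth maps match the region definitions
  wm_idx <- which(as.integer(ph$labels) == 1L)
  expect_equal(unique(ph$truth$v_cyl[wm_idx]), 0.70)

  maps <- fit_volume(m, ph$volume)
  expect_equal(dim(maps$v_cyl), c(12, 12, 2))
  ## mask and geometry preserved; all masked voxels estimated
  expect_equal(maps$mask, ph$volume$mask)
  expect_true(all(is.finite(maps$v_cyl[as.logical(maps$mask)])))
  expect_true(all(is.finite(maps$rms_residual[as.logical(maps$mask)])))

  ## writing maps produces one file per parameter
  pre <- tempfile()
  paths <- write_parameter_maps(maps, pre)
  expect_length(paths, 8L)
  expect_true(all(file.exists(paths)))
})

test_that("noise-free phantom voxels are recovered by the classical fit", {
  spec <- default_phantom_spec(dims = c(4, 2, 1), snr = Inf)
  ph <- generate_phantom(spec, seed = 27)
  ## pick one WM-like voxel (idealised generative model, no noise)
  idx <- which(as.integer(ph$labels) == 1L)[1]
  S <- matrix(ph$volume$signals, prod(dim(ph$labels)), 8)
  fit <- fit_nlls(S[idx, , drop = FALSE], 0, ph$volume$protocol, n_restarts = 25)
  expect_equal(fit$v_cyl, 0.70, tolerance = 1e-3)
  expect_equal(fit$lambda_cyl, 2.3, tolerance = 1e-2)
})
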