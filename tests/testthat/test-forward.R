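test_that("tortuosity reproduces hand-derived limits and ordering", {
  ## sticks only: parallel diffusion free, perpendicular fully hindered once
  expect_equal(tortuosity(0.5, 0, 0.5, 2.0),
               data.frame(lambda_par = 2.0, lambda_perp = 1.0))
  ## free water limit
  expect_equal(tortuosity(0, 0, 1, 2.7),
               data.frame(lambda_par = 2.7, lambda_perp = 2.7))
  ## spheres only: isotropic hindrance with exponent 1/2
  tt <- tortuosity(0, 0.5, 0.5, 2.0)
  expect_equal(tt$lambda_par, 2.0 * sqrt(0.5), tolerance = 1e-12)
  expect_equal(tt$lambda_perp, tt$lambda_par, tolerance = 1e-12)

  ## ordering holds across the simplex
  set.seed(2)
  p <- sample_tissue_params(500)
  tt <- tortuosity(p$v_cyl, p$v_sph, p$v_ext, p$lambda_cyl)
  expect_true(all(tt$lambda_perp <= tt$lambda_par + 1e-12))
  expect_true(all(tt$lambda_par <= p$lambda_cyl + 1e-12))
  expect_true(all(tt$lambda_perp >= 0))
})

test_that("compartment powder term has the right limits", {
  ## b = 0 normalisation
  expect_equal(compartment_powder_term(0, 1, 2.0, 0), 1)
  ## STE collapses to the mean-diffusivity exponential
  lpar <- 2.2; lperp <- 0.4; b <- 2.0
  expect_equal(compartment_powder_term(b, 0, lpar, lperp),
               exp(-b * (lpar + 2 * lperp) / 3), tolerance = 1e-14)
  ## stick LTE value, checked against the orientation integral
  expect_equal(compartment_powder_term(5, 1, 2.0, 0), 0.2802474,
               tolerance = 1e-6)
  ## continuity of the anisotropy factor across the x -> 0 series switch
  ## (b = xs, b_delta = 1, lambda_par = 1, lambda_perp = 0 makes the
  ## exponential term exactly 1, isolating the factor)
  xs <- c(1e-8, 1e-7, 9.9e-7, 1.01e-6, 1e-5)
  vals <- compartment_powder_term(xs, 1, 1, 0)
  expect_true(all(diff(vals) < 0))
  expect_equal(vals, 1 - xs / 3 + xs^2 / 10, tolerance = 1e-12)
})

test_that("planar-shape branch agrees with a direct orientation average", {
  b <- 2.0; bd <- -0.5; lpar <- 2.0; lperp <- 0.2
  ## direct quadrature over the polar angle of the axially symmetric average
  f <- function(ct) {
    exp(-b * (bd * (lpar - lperp) * ct^2 +
                (1 - bd) / 3 * lpar + (2 + bd) / 3 * lperp))
  }
  ref <- stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
  expect_equal(compartment_powder_term(b, bd, lpar, lperp), ref,
               tolerance = 1e-9)
})

test_that("powder_signal limits and normalisation", {
  proto <- default_protocol()
  ## pure extra-cellular space is free water
  p <- tissue_params(0, 0, 2.5, 1.0)
  s <- powder_signal(p, proto)
  expect_equal(as.numeric(s), exp(-b_to_internal(proto$shells$b) * 2.5),
               tolerance = 1e-12)
  ## pure sticks under STE
  p2 <- tissue_params(1, 0, 2.0, 0.5)
  s2 <- powder_signal(p2, data.frame(b = 2000, b_delta = 0, n_dirs = 32))
  expect_equal(as.numeric(s2), exp(-2 * 2 / 3), tolerance = 1e-12)
  ## b = 0 gives 1 for any tissue
  set.seed(3)
  p3 <- sample_tissue_params(20)
  expect_equal(as.numeric(powder_signal(p3, data.frame(b = 0, b_delta = 1, n_dirs = 1))),
               rep(1, 20), tolerance = 1e-12)
  ## monotone decreasing in b for both encodings
  bs <- seq(0, 5000, by = 250)
  for (bd in c(0, 1)) {
    sig <- powder_signal(p3, data.frame(b = bs, b_delta = bd, n_dirs = 1))
    expect_true(all(apply(sig, 1, function(r) all(diff(r) < 1e-12))))
  }
})

test_that("microdomain signal is the directional generator of the powder mean", {
  set.seed(4)
  p <- sample_tissue_params(1)
  ## STE is orientation-invariant
  bt <- make_btensor(2000, 0, c(0, 0, 1))
  vals <- sapply(1:20, function(i) {
    u <- rnorm(3); microdomain_signal(bt, p, u / sqrt(sum(u^2)))
  })
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)
  ## LTE along the stick axis with only sticks
  ps <- tissue_params(1, 0, 2.3, 0.1)
  bt2 <- make_btensor(3000, 1, c(1, 0, 0))
  expect_equal(microdomain_signal(bt2, ps, c(1, 0, 0)), exp(-3 * 2.3),
               tolerance = 1e-12)
  ## Monte-Carlo orientation average reproduces the powder mean
  for (case in list(c(2000, 1), c(5000, 1), c(1500, 0))) {
    mc <- mc_powder_oracle(p, case[1], case[2], n_orient = 2e4, seed = 9)
    pw <- powder_signal(p, data.frame(b = case[1], b_delta = case[2], n_dirs = 1))
    expect_lt(abs(mc["mean"] - as.numeric(pw)), 3 * mc["se"] + 1e-12)
  }
})

test_that("LTE/STE contrast inverts between WM-like and GM-like tissue", {
  wm <- tissue_params(0.7, 0.05, 2.3, 0.6)
  gm <- tissue_params(0.25, 0.4, 2.3, 0.6)
  sh <- data.frame(b = c(2000, 2000), b_delta = c(1, 0), n_dirs = 32)
  s_wm <- powder_signal(wm, sh)
  s_gm <- powder_signal(gm, sh)
  expect_gt(s_wm[1], s_gm[1])  # LTE: WM brighter
  expect_lt(s_wm[2], s_gm[2])  # STE: WM darker
})
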