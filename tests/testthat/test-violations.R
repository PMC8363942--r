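proto_v <- default_protocol()

test_that("every violation reduces to the idealised model at zero magnitude", {
  set.seed(5)
  p <- sample_tissue_params(20)
  s0 <- powder_signal(p, proto_v)
  cases <- list(
    violation("none"),
    violation("csf", v_csf = 0),
    violation("compartmental_t2", t2_intra = 0.1, t2_ext = 0.1),
    violation("perp_stick", lambda_perp_cyl = 0),
    violation("myelin", v_myelin = 0),
    violation("tortuosity_perp", alpha = 1),
    violation("tortuosity_both", beta = 1),
    violation("gamma_sph", var_sph = 0),
    violation("kurtosis", k_t = 0)
  )
  for (v in cases) {
    expect_equal(violated_powder_signal(p, proto_v, v), s0, tolerance = 1e-12,
                 info = v$kind)
  }
})

test_that("CSF variant interpolates to pure free water", {
  p <- tissue_params(0.5, 0.3, 2.0, 0.5)
  v <- violation("csf", v_csf = 1)
  s <- violated_powder_signal(p, proto_v, v)
  expect_equal(as.numeric(s), exp(-b_to_internal(proto_v$shells$b) * 3),
               tolerance = 1e-12)
  ## T2 weighting raises the CSF share: more signal decay than volume implies
  v2 <- violation("csf", v_csf = 0.2)
  s2 <- violated_powder_signal(p, proto_v, v2)
  w_c <- exp(-0.094 / 2); w_t <- exp(-0.094 / 0.1)
  f_csf <- 0.2 * w_c / (0.8 * w_t + 0.2 * w_c)
  expect_gt(f_csf, 0.2)
  manual <- (1 - f_csf) * powder_signal(p, proto_v) +
    f_csf * exp(-outer(rep(1, 1), b_to_internal(proto_v$shells$b)) * 3)
  expect_equal(s2, manual, tolerance = 1e-12)
})

test_that("compartmental T2 reweights intra- vs extra-cellular signal", {
  p <- tissue_params(0.4, 0.2, 2.0, 0.5)
  v <- violation("compartmental_t2", t2_ext = 0.03)
  s <- violated_powder_signal(p, proto_v, v)
  ## manual effective fractions at TE = 94 ms
  w_in <- exp(-0.094 / 0.1); w_ex <- exp(-0.094 / 0.03)
  den <- 0.6 * w_in + 0.4 * w_ex
  ext <- tortuosity(0.4, 0.2, 0.4, 2.0)
  b <- b_to_internal(proto_v$shells$b); bd <- proto_v$shells$b_delta
  manual <- (0.4 * w_in * compartment_powder_term(b, bd, 2.0, 0) +
               0.2 * w_in * compartment_powder_term(b, bd, 0.5, 0.5) +
               0.4 * w_ex * compartment_powder_term(b, bd, ext$lambda_par, ext$lambda_perp)) / den
  expect_equal(as.numeric(s), manual, tolerance = 1e-12)
  ## at b = 0 the normalisation still gives exactly 1
  s0 <- violated_powder_signal(p, data.frame(b = 0, b_delta = 0, n_dirs = 1), v)
  expect_equal(as.numeric(s0), 1, tolerance = 1e-12)
})

test_that("gamma-distributed sphere diffusivities match the analytic Laplace transform", {
  ## E[exp(-b L)] for L ~ Gamma(k, theta) is (1 + b theta)^(-k)
  p <- tissue_params(0, 1, 2.0, 0.8)
  v <- violation("gamma_sph", var_sph = 0.08, n_draws = 200000)
  s <- violated_powder_signal(p, proto_v, v, seed = 42)
  b <- b_to_internal(proto_v$shells$b)
  theta <- 0.08 / 0.8; k <- 0.8^2 / 0.08
  ref <- (1 + b * theta)^(-k)
  expect_equal(as.numeric(s), ref, tolerance = 5e-3)
  ## reproducible under the seed
  s2 <- violated_powder_signal(p, proto_v, v, seed = 42)
  expect_identical(s, s2)
})

test_that("kurtosis term matches its closed form and enforces monotonicity", {
  p <- tissue_params(0, 1, 2.0, 0.5)
  v <- violation("kurtosis", k_t = 0.7)
  s <- violated_powder_signal(p, data.frame(b = 5000, b_delta = 0, n_dirs = 1), v)
  expect_equal(as.numeric(s), exp(-2.5 + (1 / 6) * 0.7 * 25 * 0.25),
               tolerance = 1e-12)
  ## lambda_sph above 3/(b_max k_t) would make the signal non-monotone
  p_bad <- tissue_params(0, 1, 2.0, 1.5)
  expect_error(violated_powder_signal(p_bad, proto_v, v), "constraint")
  ## negative kurtosis is unconstrained
  vneg <- violation("kurtosis", k_t = -0.7)
  expect_silent(violated_powder_signal(p_bad, proto_v, vneg))
})

test_that("myelin variant uses the adjusted tortuosity and renormalises", {
  p <- tissue_params(0.4, 0.2, 2.0, 0.5)
  vm <- 0.25
  v <- violation("myelin", v_myelin = vm)
  s <- violated_powder_signal(p, proto_v, v)
  ## manual: actual fractions scaled by (1 - vm), myelin counted as hindrance
  vc <- 0.4 * (1 - vm); vs <- 0.2 * (1 - vm); ve <- 0.4 * (1 - vm)
  e <- vs + vc + vm
  lp <- 2.0 * ve^(0.5 * vs / e)
  lq <- 2.0 * ve^((0.5 * vs + vc + vm) / e)
  b <- b_to_internal(proto_v$shells$b); bd <- proto_v$shells$b_delta
  manual <- 0.4 * compartment_powder_term(b, bd, 2.0, 0) +
    0.2 * compartment_powder_term(b, bd, 0.5, 0.5) +
    0.4 * compartment_powder_term(b, bd, lp, lq)
  expect_equal(as.numeric(s), manual, tolerance = 1e-12)
})

test_that("gold standards implement the renormalisation identities", {
  set.seed(6)
  p <- sample_tissue_params(50)
  ## CSF: extra-cellular reference absorbs the free-water fraction
  g <- gold_standard(p, violation("csf", v_csf = 0.3))
  expect_equal(g$v_ext, p$v_ext * 0.7 + 0.3, tolerance = 1e-12)
  expect_equal(g$v_cyl + g$v_sph + g$v_ext, rep(1, 50), tolerance = 1e-12)
  ## myelin: reference is actual fraction / (1 - v_myelin) = tissue-internal value
  g2 <- gold_standard(p, violation("myelin", v_myelin = 0.3))
  expect_equal(g2$v_cyl, p$v_cyl, tolerance = 1e-12)
  ## others leave the reference untouched
  g3 <- gold_standard(p, violation("kurtosis", k_t = 0.5))
  expect_identical(g3, p)
})

test_that("violated signals stay in (0, 1] for non-positive kurtosis", {
  set.seed(7)
  p <- sample_tissue_params(30)
  for (v in list(violation("csf", v_csf = 0.4),
                 violation("compartmental_t2", t2_ext = 0.05),
                 violation("perp_stick", lambda_perp_cyl = 0.05),
                 violation("myelin", v_myelin = 0.3),
                 violation("tortuosity_perp", alpha = 1.5),
                 violation("tortuosity_both", beta = 0.5),
                 violation("gamma_sph", var_sph = 0.1, n_draws = 500),
                 violation("kurtosis", k_t = -0.7))) {
    s <- violated_powder_signal(p, proto_v, v)
    expect_true(all(s > 0 & s <= 1 + 1e-12), info = v$kind)
  }
})
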