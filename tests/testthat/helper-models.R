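## Shared trained estimators, built once per test run.
##
## desk_model(): the desk-scale estimator used by the bias/trend studies
## (default training configuration; roughly ten minutes of CPU).
## quick_model(): a small network for interface and smoke tests (seconds).

.model_cache <- new.env(parent = emptyenv())

desk_model <- function() {
  if (is.null(.model_cache$desk)) {
    .model_cache$desk <- train_estimator(default_protocol(), seed = 7L)
  }
  .model_cache$desk
}

quick_model <- function() {
  if (is.null(.model_cache$quick)) {
    .model_cache$quick <- train_estimator(default_protocol(), n_samples = 2^12,
                                          epochs = 80, batch_size = 512,
                                          hidden = c(32, 32), seed = 5L)
  }
  .model_cache$quick
}

## Independent orientation-average oracle: Monte-Carlo mean of the directional
## microdomain signal sum_i v_i exp(-B : D_i) over uniform orientations,
## computed directly from the b-tensor without the error-function form.
mc_powder_oracle <- function(p1, b_s_mm2, b_delta, n_orient = 1e5, seed = 1L) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n_orient), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  bt <- make_btensor(b_s_mm2, b_delta, c(0, 0, 1)) / 1000  # ms/um^2
  tr_b <- sum(diag(bt))
  ubu <- rowSums((u %*% bt) * u)
  ext <- tortuosity(p1$v_cyl, p1$v_sph, p1$v_ext, p1$lambda_cyl)
  s <- p1$v_cyl * exp(-p1$lambda_cyl * ubu) +
    p1$v_sph * exp(-p1$lambda_sph * tr_b) +
    p1$v_ext * exp(-(ext$lambda_perp * tr_b +
                       (ext$lambda_par - ext$lambda_perp) * ubu))
  c(mean = mean(s), se = stats::sd(s) / sqrt(n_orient))
}
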