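test_that("FFT correlation path matches the direct-sum oracle", {
  set.seed(11)
  a <- rpois(1024, 5)
  b <- rpois(1024, 3)
  lags <- multitau_lags(1024)
  oracle_ab <- direct_correlation_oracle(a, b, lags)
  oracle_aa <- direct_correlation_oracle(a, a, lags)
  fft_ab <- carpetFCS:::pcf_pairs_fft(cbind(a), cbind(b), lags)$values[1, ]
  fft_aa <- carpetFCS:::pcf_pairs_fft(cbind(a), cbind(a), lags)$values[1, ]
  expect_lt(max(abs(fft_ab - oracle_ab)), 1e-10)
  expect_lt(max(abs(fft_aa - oracle_aa)), 1e-10)
})

test_that("pair correlation of hand-built series has the expected values", {
  # constant trace: no fluctuations, pCF identically zero
  const <- matrix_carpet(matrix(7, 512, 2))
  curve <- pcf_column(const, column = 0, d = 0)
  expect_true(all(abs(curve$values) < 1e-12))

  # strictly alternating trace at lag 1: products all zero -> pCF = -1
  alt <- rep(c(1, 0), 256)
  expect_equal(direct_correlation_oracle(alt, alt, 1), -1)

  # Poisson zero-lag amplitude is the shot-noise variance/mean^2 = 1/lambda
  set.seed(5)
  lam <- 4
  x <- rpois(2e5, lam)
  g0 <- direct_correlation_oracle(x, x, 0)
  expect_equal(g0, 1 / lam, tolerance = 0.05)
})

test_that("a delayed copy produces a pCF peak at the construction delay", {
  set.seed(7)
  n <- 4096; k <- 12
  src <- as.numeric(arima.sim(list(ar = 0.9), n + k)) + 10
  m <- cbind(src[(k + 1):(n + k)], src[1:n])   # col 2 lags col 1 by k lines
  carp <- matrix_carpet(m)
  curve <- pcf_column(carp, column = 0, d = 1, lags = 1:64)
  expect_equal(curve$lags[which.max(curve$values)], k)
})

test_that("pCF at d = 0 is the ACF, exactly and element-wise", {
  carp <- small_carpet(n_lines = 2000, n_pixels = 16)
  cc <- pcf_carpet(carp, d = 0)
  expect_identical(cc$mode, "auto")
  for (col in c(0, 7, 15)) {
    curve <- pcf_column(carp, col, d = 0)
    expect_identical(cc$values[col + 1, ], curve$values)
  }
  # and the oracle agrees on a sample column
  a <- carp$data[, 5, 1]
  expect_lt(max(abs(cc$values[5, ] -
                      direct_correlation_oracle(a, a, cc$lags))), 1e-10)
})

test_that("random-permutation surrogate decorrelates to the null", {
  carp <- small_carpet(n_lines = 6000, n_pixels = 8, seed = 3)
  x <- carp$data[, 4, 1]
  lags <- multitau_lags(length(x))
  set.seed(99)
  null_amps <- replicate(30, {
    xs <- sample(x)
    mean(direct_correlation_oracle(xs, xs, lags))
  })
  xs <- sample(x)
  surr <- mean(direct_correlation_oracle(xs, xs, lags))
  expect_lt(abs(surr - mean(null_amps)), 3 * sd(null_amps) + 1e-12)
  # while the unshuffled trace is far outside the null
  real <- mean(direct_correlation_oracle(x, x, lags))
  expect_gt(real - mean(null_amps), 10 * sd(null_amps))
})

test_that("physical pair separation is d times the pixel size", {
  carp <- small_carpet(n_lines = 512, n_pixels = 32, pixel_size_nm = 40)
  cc <- pcf_carpet(carp, d = 20)
  expect_equal(cc$separation_nm, 800)
  expect_equal(cc$mode, "pair")
  # out-of-range targets are flagged, not NaN-propagated
  expect_false(any(cc$valid[(32 - 19):32]))
  expect_true(all(is.na(cc$values[(32 - 19):32, ])))
})

test_that("multitau lag grid is increasing, bounded and log-dense", {
  lg <- multitau_lags(32000)
  expect_true(all(diff(lg) > 0))
  expect_gte(lg[1], 1)
  expect_lte(max(lg), 4000)
  lg2 <- multitau_lags(32000, points_per_octave = 16)
  expect_gt(length(lg2), length(lg))
})

test_that("detrending removes slow trends and preserves the mean", {
  x <- rep(5, 1000)
  expect_equal(detrend_column(x, "additive", 100), x)
  ramp <- seq(0, 1, length.out = 2000) + 3
  r <- detrend_column(ramp, "additive", 201)
  expect_lt(abs(unname(coef(lm(r ~ seq_along(r)))[2])),
            1e-6 * abs(unname(coef(lm(ramp ~ seq_along(ramp)))[2])) + 1e-10)
  expect_equal(mean(r), mean(ramp), tolerance = 1e-3)
  expect_error(detrend_column(x, "additive", 1), "window")
  expect_error(detrend_column(x, "additive", 2000), "window")

  # exponential bleach: multiplicative detrend pulls the ACF tail toward 0
  carp <- small_carpet(n_lines = 8000, n_pixels = 8, seed = 9)
  bleach <- exp(-(seq_len(8000) - 1) / 4000)
  x <- carp$data[, 4, 1] * bleach
  lags <- multitau_lags(8000)
  tail_sel <- lags > 500
  raw_tail <- mean(direct_correlation_oracle(x, x, lags)[tail_sel])
  xd <- detrend_column(x, "multiplicative", 1000)
  det_tail <- mean(direct_correlation_oracle(xd, xd, lags)[tail_sel])
  expect_lt(abs(det_tail), abs(raw_tail))
})

test_that("drift gives an earlier downstream pCF peak than upstream", {
  cfg <- simulation_config(
    species = species_spec(0.5, 6, 300, velocity_um_per_s = 1.5),
    n_pixels = 64, n_lines = 16000, seed = 31)
  carp <- simulate_carpet(cfg)
  down <- pcf_carpet(carp, d = 10)
  up <- pcf_carpet(carp, d = -10)
  cols <- 20:40 + 1
  amp_down <- mean(colMeans(down$values[cols, , drop = FALSE]))
  amp_up <- mean(colMeans(up$values[cols, , drop = FALSE]))
  expect_gt(amp_down, amp_up)   # transport is directional
})
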