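test_that("an exact model curve is recovered to numerical precision", {
  model <- fcs_model_config(psf_waist_um = 0.25)
  tau <- multitau_lags(32000) * 0.0015
  for (kappa in c(Inf, 5)) {
    m <- fcs_model_config(structure_parameter = kappa)
    y <- fcs_model_curve(tau, G0 = 0.05, tau_D = 1e-3, kappa = kappa)
    fit <- fit_single_component(tau, y, m)
    expect_true(fit$valid)
    expect_equal(fit$G0, 0.05, tolerance = 1e-6)
    expect_equal(fit$tau_D_s, 1e-3, tolerance = 1e-6)
    expect_equal(fit$N_apparent, 20, tolerance = 1e-5)
  }
  # D follows w0^2 / (4 tau_D)
  y <- fcs_model_curve(tau, 0.1, 2e-3)
  fit <- fit_single_component(tau, y, model)
  expect_equal(fit$D_um2_s, 0.25^2 / (4 * 2e-3), tolerance = 1e-6)
})

test_that("fits outside the admissible diffusion range are invalidated", {
  model <- fcs_model_config()
  tau <- multitau_lags(32000) * 0.0015
  # tau_D chosen so D = w0^2/(4 tau_D) = 150 um^2/s > 100
  y <- fcs_model_curve(tau, 0.05, 0.25^2 / (4 * 150))
  fit <- fit_single_component(tau, y, model)
  expect_equal(fit$D_um2_s, 150, tolerance = 0.05)
  expect_false(fit$valid)
  expect_identical(fit$speed_class, "invalid")
  # degenerate inputs give invalid results, not exceptions
  expect_false(fit_single_component(tau, rep(0, length(tau)), model)$valid)
  expect_false(fit_single_component(tau[1:5], rep(0.1, 5), model)$valid)
})

test_that("speed classification uses a strict threshold at 2 um^2/s", {
  expect_identical(classify_speed(3.53), "fast")
  expect_identical(classify_speed(0.35), "slow")
  expect_identical(classify_speed(2.0), "slow")
  expect_identical(classify_speed(2.0 + 1e-9), "fast")
  expect_identical(classify_speed(5, valid = FALSE), "invalid")
  expect_identical(classify_speed(c(1, 3), threshold = 2),
                   c("slow", "fast"))
})

test_that("chi-square on exact-model data with known noise is near dof", {
  set.seed(21)
  model <- fcs_model_config()
  tau <- multitau_lags(32000) * 0.0015
  sigma <- 0.002
  reps <- replicate(20, {
    y <- fcs_model_curve(tau, 0.08, 3e-3) + rnorm(length(tau), 0, sigma)
    fit <- fit_single_component(tau, y, model,
                                weights = rep(1 / sigma^2, length(tau)))
    c(fit$chi2, fit$dof)
  })
  dof <- reps[2, 1]
  expect_lt(abs(mean(reps[1, ]) - dof), 3 * sqrt(2 * dof) / sqrt(20) + 3)
})

test_that("intensity scaling leaves the correlation and the fit unchanged", {
  carp <- small_carpet(n_lines = 4000, n_pixels = 16, seed = 22)
  scaled <- carp
  scaled$data <- carp$data * 7
  cc1 <- pcf_carpet(carp, d = 0)
  cc2 <- pcf_carpet(scaled, d = 0)
  expect_equal(cc1$values, cc2$values, tolerance = 1e-6)
  f1 <- fit_carpet_acf(carp, n_blocks = 0)
  f2 <- fit_carpet_acf(scaled, n_blocks = 0)
  expect_equal(f1$D_um2_s, f2$D_um2_s, tolerance = 1e-6)
})

test_that("zone statistics summarize valid fits per zone", {
  res <- data.frame(column = 0:9, G0 = 0.1, tau_D_s = 1e-3,
                    D_um2_s = c(rep(4, 5), rep(1, 4), 50),
                    chi2 = NA, dof = 50,
                    valid = c(rep(TRUE, 9), FALSE),
                    speed_class = c(rep("fast", 5), rep("slow", 4),
                                    "invalid"),
                    N_apparent = 10)
  zm <- assign_zones(4, ne_half_width_px = 1, orientation = "cyto_left",
                     n_pixels = 10)
  zs <- zone_statistics(res, zm)
  expect_identical(zs$zone, c("cytoplasm", "NE", "nucleoplasm"))
  cy <- zs[zs$zone == "cytoplasm", ]
  expect_equal(cy$n, 3)                     # columns 0..2
  expect_equal(cy$mean_D, 4)
  expect_equal(cy$sem_D, 0)
  # invalid column excluded
  nu <- zs[zs$zone == "nucleoplasm", ]
  expect_equal(nu$n, 3)                     # columns 6..8; 9 is invalid
  zc <- zone_statistics(res, zm, by_class = TRUE)
  expect_true(all(c("fast", "slow") %in% zc$speed_class))
  expect_equal(zc$n[zc$zone == "nucleoplasm" & zc$speed_class == "slow"], 3)
})

test_that("file averaging combines repeated acquisitions", {
  carps <- lapply(1:3, function(s)
    small_carpet(n_lines = 4000, n_pixels = 8, seed = 30 + s))
  fa <- file_averaged_diffusion(carps)
  expect_equal(nrow(fa), 8)
  expect_true(any(fa$valid))
  fb <- file_averaged_diffusion(carps, method = "average_fits")
  expect_equal(nrow(fb), 8)
  expect_true(all(is.finite(fb$D_um2_s[fb$valid])))
})
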