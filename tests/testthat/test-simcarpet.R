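test_that("identical config and seed reproduce the carpet bit for bit", {
  cfg <- simulation_config(species = species_spec(2, 3, 50),
                           n_pixels = 32, n_lines = 1000, seed = 42)
  c1 <- simulate_carpet(cfg)
  c2 <- simulate_carpet(cfg)
  expect_identical(c1$data, c2$data)
})

test_that("no emitters and no background give an all-zero carpet", {
  cfg <- simulation_config(species = list(), background_rate = 0,
                           n_pixels = 16, n_lines = 100, seed = 1)
  carp <- simulate_carpet(cfg)
  expect_true(all(carp$data == 0))
})

test_that("an immobile particle renders a static Gaussian PSF profile", {
  cfg <- simulation_config(
    species = species_spec(0, 5, 1, mobile_fraction = 0),
    n_pixels = 64, n_lines = 50, seed = 8)
  carp <- simulate_carpet(cfg, noise = "expectation",
                          keep_trajectories = TRUE)
  m <- carp$data[, , 1]
  # every line identical
  expect_lt(max(abs(sweep(m, 2, m[1, ]))), 1e-12)
  # profile is the Gaussian PSF around the particle position
  tr <- attr(carp, "trajectories")[[1]]
  x0 <- tr$pos_x[1, 1]; y0 <- tr$y[1, 1]
  xc <- (seq_len(64) - 0.5) * 0.041
  w <- 0.25
  expected <- 5 * exp(-2 * ((xc - x0)^2 + y0^2) / w^2)
  near <- abs(xc - x0) < 2 * w     # inside the rendering cutoff
  expect_equal(m[1, near], expected[near], tolerance = 1e-6)
})

test_that("mean intensity obeys photon conservation in expectation", {
  n <- 400; b <- 3
  cfg <- simulation_config(species = species_spec(3, b, n),
                           n_pixels = 64, n_lines = 10000, seed = 12)
  carp <- simulate_carpet(cfg, noise = "expectation")
  area <- cfg$field_length_um * cfg$strip_height_um
  waist <- cfg$psf_waist_nm / 1000
  expected_mean <- n * b * (pi * waist^2 / 2) / area
  line_means <- rowMeans(carp$data[, , 1])
  mc_sigma <- sd(line_means) / sqrt(10000 / 10)  # ~10-line correlation time
  expect_lt(abs(mean(line_means) - expected_mean),
            3 * mc_sigma + 0.01 * expected_mean)
})

test_that("an impermeable barrier is never crossed", {
  cfg <- simulation_config(species = species_spec(5, 1, 80),
                           n_pixels = 64, n_lines = 4000,
                           barrier = barrier_spec(32, 0), seed = 13)
  carp <- simulate_carpet(cfg, keep_trajectories = TRUE)
  pos <- attr(carp, "trajectories")[[1]]$pos_x
  barrier_x <- (32 + 0.5) * 0.041
  side <- pos > barrier_x
  expect_true(all(apply(side, 2, function(s) all(s == s[1]))))
})

test_that("a fully permeable barrier is crossed freely", {
  cfg <- simulation_config(species = species_spec(5, 1, 80),
                           n_pixels = 64, n_lines = 4000,
                           barrier = barrier_spec(32, 1), seed = 13)
  carp <- simulate_carpet(cfg, keep_trajectories = TRUE)
  pos <- attr(carp, "trajectories")[[1]]$pos_x
  side <- pos > (32 + 0.5) * 0.041
  expect_gt(sum(apply(side, 2, function(s) any(s != s[1]))), 40)
})

test_that("free Brownian displacements have variance 2 D T per axis", {
  D <- 2; n_lines <- 2000; n <- 300
  cfg <- simulation_config(species = species_spec(D, 1, n),
                           n_pixels = 32, n_lines = n_lines, seed = 14)
  carp <- simulate_carpet(cfg, keep_trajectories = TRUE)
  tr <- attr(carp, "trajectories")[[1]]
  T_s <- (n_lines - 1) * cfg$line_period_ms / 1000
  for (ax in c("x", "y")) {
    dx <- tr[[ax]][n_lines, ] - tr[[ax]][1, ]
    expect_equal(mean(dx), 0, tolerance = 4 * sqrt(2 * D * T_s / n))
    expect_equal(var(dx), 2 * D * T_s,
                 tolerance = 2 * D * T_s * 3 * sqrt(2 / (n - 1)))
  }
})

test_that("mobile_fraction freezes the immobile complement", {
  cfg <- simulation_config(
    species = species_spec(5, 1, 40, mobile_fraction = 0.5),
    n_pixels = 32, n_lines = 500, seed = 15)
  carp <- simulate_carpet(cfg, keep_trajectories = TRUE)
  tr <- attr(carp, "trajectories")[[1]]
  moved <- apply(tr$pos_x, 2, function(p) any(p != p[1]))
  expect_identical(moved, tr$mobile)
  expect_equal(sum(tr$mobile), 20)
})

test_that("the lamina stripe is static, Gaussian and channel-assigned", {
  cfg <- simulation_config(species = list(),
                           lamina = lamina_spec(40, 3, 12, channel = 2),
                           n_pixels = 128, n_lines = 64, seed = 16)
  carp <- simulate_carpet(cfg, noise = "expectation")
  expect_true(all(carp$data[, , 1] == 0))
  prof <- carp$data[1, , 2]
  expect_equal(which.max(prof) - 1, 40)
  expect_equal(max(prof), 12, tolerance = 1e-9)
})

test_that("co-transport stack construction matches its contract", {
  cfg <- simulation_config(species = species_spec(2, 4, 30),
                           n_pixels = 24, pixel_size_nm = 200,
                           line_period_ms = 10, psf_waist_nm = 300,
                           seed = 17)
  # fraction 1, no noise: channels proportional frame by frame
  stk <- simulate_cotransport_stack(cfg, n_frames = 64,
                                    cotransport_fraction = 1,
                                    noise = "expectation")
  expect_equal(dim(stk$data), c(64, 24, 24, 2))
  expect_lt(max(abs(stk$data[, , , 1] - stk$data[, , , 2])), 1e-9)
  # fraction 0: channels are independent renders, not copies
  stk0 <- simulate_cotransport_stack(cfg, n_frames = 64,
                                     cotransport_fraction = 0,
                                     noise = "expectation")
  expect_gt(mean(abs(stk0$data[, , , 1] - stk0$data[, , , 2])), 1e-3)
})

test_that("sphere fields respect placement and report voxelized truth", {
  expect_equal(nrow(simulate_sphere_field(0, 4, 10, seed = 1)$truth), 0)
  f <- simulate_sphere_field(2, 4, 20, dims_vox = c(48, 48, 24), seed = 2)
  expect_equal(nrow(f$truth), 2)
  # voxelized volume within 10% of (4/3) pi r^3
  expect_true(all(abs(f$truth$volume_vox - 4 / 3 * pi * 4^3) <
                    0.1 * 4 / 3 * pi * 4^3))
  # impossible packing errors out
  expect_error(simulate_sphere_field(100, 6, 10, dims_vox = c(20, 20, 20),
                                     seed = 3, max_tries = 50),
               "could not place")
})
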