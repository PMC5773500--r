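test_that("N and B follow the moment definitions exactly", {
  set.seed(41)
  # trace engineered to have sample mean 10 and variance 5 exactly
  z <- as.numeric(scale(rnorm(300)))
  x <- 10 + sqrt(5) * z
  m <- matrix(rep(x, 2), ncol = 2)
  carp <- matrix_carpet(m)
  nb <- nb_compute(carp, nb_scheme("fast", block_lines = 300,
                                   n_segments = 1))
  expect_equal(nb$mean_k, c(10, 10), tolerance = 1e-12)
  expect_equal(nb$var_k, c(5, 5), tolerance = 1e-12)
  expect_equal(nb$N_apparent, c(20, 20), tolerance = 1e-12)
  expect_equal(nb$B_apparent, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("pure shot noise calibrates to B = 1 and N = <k>", {
  carp <- poisson_carpet(lambda = 4, n_lines = 20000, n_pixels = 8,
                         seed = 42)
  agg <- nb_aggregate(nb_compute(carp, nb_scheme("fast")))
  expect_equal(mean(agg$mean_B), 1, tolerance = 0.02)
  expect_equal(mean(agg$mean_N), 4, tolerance = 0.02 * 4)
})

test_that("degenerate columns are flagged rather than poisoned", {
  m <- cbind(rep(5, 300), rpois(300, 5))
  carp <- matrix_carpet(m)
  nb <- nb_compute(carp, nb_scheme("fast", block_lines = 300,
                                   n_segments = 1))
  expect_false(nb$defined[1])
  expect_true(is.na(nb$N_apparent[1]))
  expect_equal(nb$B_apparent[1], 0)
  expect_true(nb$defined[2])
})

test_that("counts scaled by c scale B by c and leave N invariant", {
  carp <- small_carpet(n_lines = 1200, n_pixels = 8, seed = 43)
  scaled <- carp; scaled$data <- carp$data * 3
  a <- nb_compute(carp, nb_scheme("fast", block_lines = 300))
  b <- nb_compute(scaled, nb_scheme("fast", block_lines = 300))
  ok <- a$defined
  expect_equal(b$N_apparent[ok], a$N_apparent[ok], tolerance = 1e-12)
  expect_equal(b$B_apparent[ok], 3 * a$B_apparent[ok], tolerance = 1e-12)
})

test_that("line averaging suppresses fast but not immobile brightness", {
  # fast diffuser: averaging 100 lines washes out its fluctuations
  fast <- small_carpet(n_lines = 30000, n_pixels = 16, D = 10,
                       brightness = 6, n = 60, seed = 44)
  bf <- mean(nb_aggregate(nb_compute(fast, nb_scheme("fast")))$mean_B)
  bs <- mean(nb_aggregate(nb_compute(fast, nb_scheme("slow")))$mean_B,
             na.rm = TRUE)
  expect_gt(bf, bs)
  # immobile bright aggregates: slow-scheme B relatively enhanced because
  # averaging removes shot noise but keeps the static number contrast
  cfg <- simulation_config(
    species = species_spec(0, 30, 12, mobile_fraction = 0),
    n_pixels = 16, n_lines = 30000, background_rate = 2, seed = 45)
  frozen <- simulate_carpet(cfg)
  shot_f <- mean(nb_aggregate(nb_compute(frozen, nb_scheme("fast")))$mean_B)
  shot_s <- mean(nb_aggregate(nb_compute(frozen,
                                         nb_scheme("slow")))$mean_B,
                 na.rm = TRUE)
  # an immobile field has only shot noise in time: B_fast ~ 1, while the
  # slow scheme's line averaging divides it by the window
  expect_lt(shot_s, shot_f)
})

test_that("across-segment SEM shrinks like 1 over sqrt(n_segments)", {
  carp <- poisson_carpet(lambda = 6, n_lines = 30000, n_pixels = 4,
                         seed = 46)
  s100 <- nb_aggregate(nb_compute(carp, nb_scheme("fast",
                                                  block_lines = 300,
                                                  n_segments = 100)))
  s25 <- nb_aggregate(nb_compute(carp, nb_scheme("fast",
                                                 block_lines = 300,
                                                 n_segments = 25)))
  ratio <- mean(s100$sem_N) / mean(s25$sem_N)
  expect_equal(ratio, 0.5, tolerance = 0.35)
})

test_that("scheme overrun and short carpets are refused", {
  carp <- small_carpet(n_lines = 500, n_pixels = 8)
  expect_error(nb_compute(carp, nb_scheme("fast", block_lines = 300,
                                          n_segments = 10)),
               "overruns")
  expect_error(nb_compute(carp, nb_scheme("slow", average_window = 400)),
               "fewer than 2")
})

test_that("joint partition pairs each column with its matching scheme", {
  carp <- small_carpet(n_lines = 30000, n_pixels = 12, seed = 47)
  nb_f <- nb_compute(carp, nb_scheme("fast"))
  nb_s <- nb_compute(carp, nb_scheme("slow"))
  fits <- data.frame(column = 0:11, G0 = 0.1, tau_D_s = 1e-3,
                     D_um2_s = c(rep(5, 6), rep(1, 5), 2000),
                     chi2 = NA, dof = 40,
                     valid = c(rep(TRUE, 11), FALSE),
                     speed_class = c(rep("fast", 6), rep("slow", 5),
                                     "invalid"),
                     N_apparent = 10)
  jp <- joint_speed_partition(nb_f, nb_s, fits)
  expect_equal(nrow(jp), 11)          # invalid column dropped
  expect_true(all(jp$scheme[jp$speed_class == "fast"] == "fast"))
  expect_true(all(jp$scheme[jp$speed_class == "slow"] == "slow"))
  # all-fast input leaves no slow rows
  fits$speed_class <- "fast"
  jp2 <- joint_speed_partition(nb_f, nb_s, fits[fits$valid, ])
  expect_false(any(jp2$scheme == "slow"))
  expect_error(joint_speed_partition(nb_f, nb_s,
                                     transform(fits, column = column + 50)),
               "mismatch")
})

test_that("brightness-distance histogram localizes planted aggregates", {
  # bright immobile aggregates 1 um cytoplasmic of the lamina at column 80
  cfg <- simulation_config(
    species = list(species_spec(3, 2, 150),
                   species_spec(0, 40, 3, mobile_fraction = 0)),
    n_pixels = 128, n_lines = 10000, background_rate = 1, seed = 48)
  carp <- simulate_carpet(cfg)
  # place the aggregates deterministically instead: craft a carpet column
  m <- matrix(rpois(10000 * 128, 2), 10000, 128)
  agg_col <- 80 - round(1 / 0.041)       # 1 um cytoplasmic (left) of lamina
  m[, agg_col + 1] <- rpois(10000, 2) + 40 * rbinom(10000, 1, 0.3)
  carp2 <- matrix_carpet(m)
  nb <- nb_compute(carp2, nb_scheme("fast", block_lines = 500))
  zm <- assign_zones(80, 11, "cyto_left", 128)
  h <- brightness_vs_distance(nb, zm, pixel_size_nm = 41,
                              bin_width_um = 0.25)
  peak_bin <- h[which.max(h$mean_B), ]
  expect_lte(peak_bin$bin_lo_um, -1)
  expect_gte(peak_bin$bin_hi_um, -1.1)
  # uniform brightness gives a flat histogram
  hu <- brightness_vs_distance(nb_compute(matrix_carpet(
    matrix(rpois(5000 * 32, 4), 5000, 32)),
    nb_scheme("fast", block_lines = 500)),
    assign_zones(16, 3, "cyto_left", 32), 41, 0.25)
  expect_lt(max(hu$mean_B) - min(hu$mean_B), 0.15)
  # halving the bin width moves the peak by less than one original bin
  h2 <- brightness_vs_distance(nb, zm, 41, bin_width_um = 0.125)
  expect_lt(abs(h2$bin_mid_um[which.max(h2$mean_B)] -
                  peak_bin$bin_mid_um), 0.25)
})

test_that("prominence peak detection finds planted transits only", {
  expect_equal(nrow(detect_rare_peaks(1:100, 1)), 0)
  x <- rep(0, 200); x[77] <- 5
  pk <- detect_rare_peaks(x, min_prominence = 1)
  expect_equal(pk$position, 77)
  expect_equal(pk$height, 5)
  # three bright transits on a noisy floor, no false positives
  set.seed(50)
  y <- rnorm(600, 10, 0.3)
  for (p in c(100, 300, 500)) y[p + (-2:2)] <- y[p + (-2:2)] + c(2, 6, 9, 6, 2)
  pk <- detect_rare_peaks(y, min_prominence = 4, min_separation = 20)
  expect_equal(nrow(pk), 3)
  expect_true(all(abs(pk$position - c(100, 300, 500)) <= 2))
  # minimum separation enforced greedily by prominence
  z <- rep(0, 100); z[40] <- 5; z[44] <- 7
  pk2 <- detect_rare_peaks(z, 1, min_separation = 10)
  expect_equal(pk2$position, 44)
})
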