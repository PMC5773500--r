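# Shared small fixtures: kept deliberately tiny; heavier simulations live
# in the individual tests that need them.

small_carpet <- function(n_lines = 4000, n_pixels = 32, D = 3,
                         brightness = 4, n = 100, seed = 1, ...) {
  cfg <- simulation_config(species = species_spec(D, brightness, n),
                           n_pixels = n_pixels, n_lines = n_lines,
                           seed = seed, ...)
  simulate_carpet(cfg)
}

poisson_carpet <- function(lambda = 4, n_lines = 20000, n_pixels = 8,
                           seed = 1) {
  cfg <- simulation_config(species = list(), background_rate = lambda,
                           n_pixels = n_pixels, n_lines = n_lines,
                           seed = seed)
  simulate_carpet(cfg)
}

# carpet built directly from a matrix (one channel)
matrix_carpet <- function(m, pixel_size_nm = 41, line_period_ms = 1.5) {
  line_scan_carpet(array(m, dim = c(nrow(m), ncol(m), 1)),
                   pixel_size_nm = pixel_size_nm,
                   line_period_ms = line_period_ms, dwell_time_us = 2)
}
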