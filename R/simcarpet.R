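#' Specify a diffusing fluorescent species
#'
#' Describes one molecular species for the line-scan / image simulator:
#' its mobility, brightness, abundance and how its emission is split
#' across the two detection channels.
#'
#' @param D_um2_per_s Diffusion coefficient in um^2/s (>= 0).
#' @param brightness Mean counts per sampling per molecule at the centre of
#'   the Gaussian detection volume (photon-counting convention).
#' @param n_particles Number of particles of this species in the field.
#' @param velocity_um_per_s Optional drift along the scan axis (directed
#'   transport), um/s.
#' @param channel_weights Length-2 non-negative weights summing to 1: the
#'   fraction of this species' emission detected in each channel. A
#'   dual-colour co-transported species has both weights positive; a
#'   single-colour species has one weight equal to 1.
#' @param mobile_fraction Fraction of the particles that diffuse; the rest
#'   are immobile for the whole run (arrested, endosome-like objects).
#' @param x_range_um Optional length-2 range for the initial positions
#'   along the scan axis, um; with an impermeable barrier this confines a
#'   species to one compartment (e.g. slow particles on the cytoplasmic
#'   side only). Default: the whole field.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(D_um2_per_s, brightness, n_particles,
                         velocity_um_per_s = 0,
                         channel_weights = c(1, 0),
                         mobile_fraction = 1, x_range_um = NULL) {
  stopifnot(length(D_um2_per_s) == 1, D_um2_per_s >= 0,
            length(brightness) == 1, brightness >= 0,
            length(n_particles) == 1, n_particles >= 0,
            n_particles == round(n_particles),
            length(channel_weights) == 2, all(channel_weights >= 0),
            mobile_fraction >= 0, mobile_fraction <= 1)
  if (abs(sum(channel_weights) - 1) > 1e-9)
    stop("channel_weights must sum to 1", call. = FALSE)
  if (!is.null(x_range_um))
    stopifnot(length(x_range_um) == 2, x_range_um[1] < x_range_um[2])
  structure(list(D_um2_per_s = D_um2_per_s, brightness = brightness,
                 n_particles = as.integer(n_particles),
                 velocity_um_per_s = velocity_um_per_s,
                 channel_weights = channel_weights,
                 mobile_fraction = mobile_fraction,
                 x_range_um = x_range_um),
            class = "species_spec")
}

#' Specify a semi-permeable barrier across the scanned line
#'
#' Models the nuclear envelope as a vertical plane at a pixel column.
#' A particle whose Brownian step would cross the plane is transmitted with
#' probability `crossing_probability` and specularly reflected otherwise;
#' 0 is an impermeable envelope, 1 removes the barrier.
#'
#' @param position_px 0-based column index of the barrier.
#' @param crossing_probability Per-encounter transmission probability in
#'   \[0, 1\].
#' @return An object of class `barrier_spec`.
#' @export
barrier_spec <- function(position_px, crossing_probability) {
  stopifnot(position_px >= 0, position_px == round(position_px),
            crossing_probability >= 0, crossing_probability <= 1)
  structure(list(position_px = as.integer(position_px),
                 crossing_probability = crossing_probability),
            class = "barrier_spec")
}

#' Specify a static lamina marker stripe
#'
#' A time-invariant Gaussian intensity stripe emulating a lamin C-EGFP
#' labelled nuclear lamina, rendered into one detection channel.
#'
#' @param position_px 0-based column of the stripe centre.
#' @param width_px Gaussian standard deviation of the stripe, in pixels.
#' @param amplitude Peak expected counts per sampling added at the centre.
#' @param channel Detection channel (1 or 2) receiving the stripe.
#' @return An object of class `lamina_spec`.
#' @export
lamina_spec <- function(position_px, width_px, amplitude, channel = 1) {
  stopifnot(position_px >= 0, width_px > 0, amplitude >= 0, channel %in% 1:2)
  structure(list(position_px = position_px, width_px = width_px,
                 amplitude = amplitude, channel = as.integer(channel)),
            class = "lamina_spec")
}

#' Configure a line-scan simulation
#'
#' Collects the acquisition geometry and the ground-truth physics for
#' [simulate_carpet()]. Defaults follow a typical confocal line-scan
#' acquisition across the nuclear envelope: 41 nm pixels, 2 us pixel dwell,
#' 32,000 lines in about 48 s (1.5 ms line period), and a 0.25 um 1/e^2
#' Gaussian detection waist.
#'
#' Particles live on a 2D strip: the scan axis x (length `field_length_um`,
#' defaulting to the scanned extent) and a transverse axis y of height
#' `strip_height_um`, so that lateral escape from the detection volume is
#' modelled and the standard 2D FCS correlation shape applies. The default
#' strip is deliberately much taller than the detection waist so the
#' reservoir approximates an open system: in a closed box the conserved
#' particle number leaves a -1/N_total anticorrelation in the long-lag
#' correlation tail.
#'
#' @param species List of [species_spec()] objects.
#' @param n_pixels Pixels per scanned line.
#' @param pixel_size_nm Sampling pitch along the line, nm.
#' @param n_lines Number of scanned lines (time points).
#' @param line_period_ms Time between successive lines, ms. This is the
#'   correlation time base: trajectories advance once per line.
#' @param dwell_time_us Per-pixel integration time, us (metadata; the
#'   idealized scanner samples all pixels of a line simultaneously, and the
#'   flag `idealized_scanner` records whether the line period is shorter
#'   than `n_pixels * dwell_time_us`).
#' @param psf_waist_nm 1/e^2 radius of the Gaussian detection PSF, nm.
#' @param barrier Optional [barrier_spec()].
#' @param background_rate Mean background counts per pixel per line.
#' @param lamina Optional [lamina_spec()].
#' @param field_length_um Physical extent available to particles along x;
#'   must cover the scanned extent `n_pixels * pixel_size_nm`.
#' @param strip_height_um Transverse extent of the particle strip, um.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(species = list(),
                              n_pixels = 128L,
                              pixel_size_nm = 41,
                              n_lines = 32000L,
                              line_period_ms = 1.5,
                              dwell_time_us = 2,
                              psf_waist_nm = 250,
                              barrier = NULL,
                              background_rate = 0,
                              lamina = NULL,
                              field_length_um = NULL,
                              strip_height_um = 10,
                              seed = NULL) {
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(n_pixels > 0, n_lines > 0, pixel_size_nm > 0,
            line_period_ms > 0, dwell_time_us > 0, psf_waist_nm > 0,
            background_rate >= 0, strip_height_um > 0)
  if (!all(vapply(species, inherits, logical(1), "species_spec")))
    stop("species must be a list of species_spec objects", call. = FALSE)
  scan_um <- n_pixels * pixel_size_nm / 1000
  if (is.null(field_length_um)) field_length_um <- scan_um
  if (scan_um > field_length_um + 1e-9)
    stop("n_pixels * pixel_size_nm exceeds field_length_um", call. = FALSE)
  if (!is.null(barrier)) {
    stopifnot(inherits(barrier, "barrier_spec"))
    if (barrier$position_px >= n_pixels)
      stop("barrier position_px outside the field", call. = FALSE)
  }
  if (!is.null(lamina)) stopifnot(inherits(lamina, "lamina_spec"))
  structure(list(
    species = species, n_pixels = as.integer(n_pixels),
    pixel_size_nm = pixel_size_nm, n_lines = as.integer(n_lines),
    line_period_ms = line_period_ms, dwell_time_us = dwell_time_us,
    psf_waist_nm = psf_waist_nm, barrier = barrier,
    background_rate = background_rate, lamina = lamina,
    field_length_um = field_length_um, strip_height_um = strip_height_um,
    idealized_scanner = line_period_ms * 1000 < n_pixels * dwell_time_us,
    seed = seed), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: %d species, %d px x %d lines (%.0f nm px, %.2f ms/line)\n",
              length(x$species), x$n_pixels, x$n_lines,
              x$pixel_size_nm, x$line_period_ms))
  for (s in x$species)
    cat(sprintf("  D = %g um2/s, brightness %g, n = %d, mobile %.0f%%, weights (%.2f, %.2f)\n",
                s$D_um2_per_s, s$brightness, s$n_particles,
                100 * s$mobile_fraction, s$channel_weights[1],
                s$channel_weights[2]))
  if (!is.null(x$barrier))
    cat(sprintf("  barrier at column %d, p(cross) = %g\n",
                x$barrier$position_px, x$barrier$crossing_probability))
  invisible(x)
}

# static lamina stripe profile over the n_pixels columns (expected counts)
lamina_profile <- function(lamina, n_pixels) {
  j <- seq_len(n_pixels) - 1
  lamina$amplitude * exp(-(j - lamina$position_px)^2 / (2 * lamina$width_px^2))
}

#' Simulate a two-channel line-scan carpet
#'
#' Evolves Brownian particles on a strip crossed by the scanned line and
#' renders the expected photon count per (line, pixel, channel) through a
#' 2D Gaussian detection PSF, then applies Poisson shot noise. Trajectories
#' advance once per line (the line period is the correlation time base;
#' pixel dwell is negligible by comparison). Boundary conditions are
#' periodic along the line, except that the field ends become reflecting
#' walls when a barrier is present so that an impermeable barrier genuinely
#' partitions the field.
#'
#' @param config A [simulation_config()].
#' @param noise `"poisson"` for photon-counting shot noise, or
#'   `"expectation"` to return the noise-free expected intensities (a
#'   deterministic test hook).
#' @param keep_trajectories If `TRUE`, attach per-species unwrapped particle
#'   trajectories (`attr(carpet, "trajectories")`) for diagnostics; also
#'   attach wrapped x positions (`"positions_x"`) used for barrier-side
#'   checks.
#' @return A [line_scan_carpet()] with the generating `config` attached as
#'   an attribute.
#' @export
simulate_carpet <- function(config, noise = c("poisson", "expectation"),
                            keep_trajectories = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  noise <- match.arg(noise)
  if (!is.null(config$seed)) set.seed(config$seed)
  nl <- config$n_lines; np <- config$n_pixels
  px_um <- config$pixel_size_nm / 1000
  waist_um <- config$psf_waist_nm / 1000
  dt <- config$line_period_ms / 1000
  expected <- array(config$background_rate, dim = c(nl, np, 2))
  has_barrier <- !is.null(config$barrier)
  barrier_x <- if (has_barrier)
    (config$barrier$position_px + 0.5) * px_um else 0
  cross_p <- if (has_barrier) config$barrier$crossing_probability else 1
  traj <- list()
  for (si in seq_along(config$species)) {
    s <- config$species[[si]]
    n <- s$n_particles
    if (n == 0) next
    xr <- if (is.null(s$x_range_um)) c(0, config$field_length_um)
          else pmin(pmax(s$x_range_um, 0), config$field_length_um)
    x0 <- stats::runif(n, xr[1], xr[2])
    y0 <- stats::runif(n, -config$strip_height_um / 2,
                       config$strip_height_um / 2)
    n_mob <- round(s$mobile_fraction * n)
    mobile <- c(rep(TRUE, n_mob), rep(FALSE, n - n_mob))
    res <- sim_species_carpet(nl, np, px_um, config$field_length_um,
                              config$strip_height_um, s$D_um2_per_s,
                              s$velocity_um_per_s, s$brightness, waist_um,
                              dt, has_barrier, barrier_x, cross_p,
                              x0, y0, mobile, keep_trajectories)
    expected[, , 1] <- expected[, , 1] + s$channel_weights[1] * res$expected
    expected[, , 2] <- expected[, , 2] + s$channel_weights[2] * res$expected
    if (keep_trajectories)
      traj[[si]] <- list(x = res$traj_x, y = res$traj_y,
                         pos_x = res$pos_x, mobile = mobile)
  }
  if (!is.null(config$lamina)) {
    prof <- lamina_profile(config$lamina, np)
    ch <- config$lamina$channel
    expected[, , ch] <- expected[, , ch] + rep(prof, each = nl)
  }
  data <- if (noise == "poisson") {
    array(stats::rpois(length(expected), expected), dim = dim(expected))
  } else expected
  carpet <- line_scan_carpet(data, pixel_size_nm = config$pixel_size_nm,
                             line_period_ms = config$line_period_ms,
                             dwell_time_us = config$dwell_time_us,
                             channel_names = c("ch1", "ch2"))
  attr(carpet, "config") <- config
  attr(carpet, "noise") <- noise
  if (keep_trajectories) attr(carpet, "trajectories") <- traj
  carpet
}

#' Simulate a two-channel image time series with co-transported particles
#'
#' Ground truth for cross-correlation pCF imaging: a stated fraction of the
#' particles emit in both channels and move identically (co-transport);
#' the remainder are independent single-channel particles, with equal total
#' particle numbers per channel regardless of the fraction. Particles
#' diffuse in the 2D image plane with periodic boundaries; the first
#' species of `config` supplies D, brightness and n_particles, and the
#' line period is reused as the frame period.
#'
#' @param config A [simulation_config()] with at least one species.
#' @param n_frames Number of frames.
#' @param cotransport_fraction Fraction in \[0, 1\] of particles emitting in
#'   both channels with a shared trajectory.
#' @param rows,cols Image size in pixels (defaults: `config$n_pixels`).
#' @param noise `"poisson"` or `"expectation"` as in [simulate_carpet()].
#' @return An [image_stack()] (frames x rows x cols x 2).
#' @export
simulate_cotransport_stack <- function(config, n_frames, cotransport_fraction,
                                       rows = config$n_pixels,
                                       cols = config$n_pixels,
                                       noise = c("poisson", "expectation")) {
  stopifnot(inherits(config, "simulation_config"),
            length(config$species) >= 1, n_frames > 0,
            cotransport_fraction >= 0, cotransport_fraction <= 1)
  noise <- match.arg(noise)
  if (!is.null(config$seed)) set.seed(config$seed)
  s <- config$species[[1]]
  px_um <- config$pixel_size_nm / 1000
  waist_um <- config$psf_waist_nm / 1000
  dt <- config$line_period_ms / 1000
  n <- s$n_particles
  n_co <- round(cotransport_fraction * n)
  n_ind <- n - n_co
  render <- function(n_part) {
    if (n_part == 0) return(array(0, dim = c(rows, cols, n_frames)))
    x0 <- stats::runif(n_part, 0, cols * px_um)
    y0 <- stats::runif(n_part, 0, rows * px_um)
    v <- sim_species_frames(n_frames, rows, cols, px_um, s$D_um2_per_s,
                            s$brightness, waist_um, dt, x0, y0)
    array(v, dim = c(rows, cols, n_frames))
  }
  co <- render(n_co)
  ind1 <- render(n_ind)
  ind2 <- render(n_ind)
  expected <- array(config$background_rate,
                    dim = c(n_frames, rows, cols, 2))
  # co-transported particles share one trajectory set, split across channels
  expected[, , , 1] <- expected[, , , 1] + aperm(co + ind1, c(3, 1, 2))
  expected[, , , 2] <- expected[, , , 2] + aperm(co + ind2, c(3, 1, 2))
  data <- if (noise == "poisson") {
    array(stats::rpois(length(expected), expected), dim = dim(expected))
  } else expected
  stk <- image_stack(data, pixel_size_nm = config$pixel_size_nm,
                     frame_period_ms = config$line_period_ms)
  attr(stk, "cotransport_fraction") <- cotransport_fraction
  stk
}

#' Simulate a 3D field of spherical particles around a nucleus
#'
#' Ground truth for 3D particle segmentation: solid spheres (in voxel
#' units) placed by rejection sampling without overlap, outside a solid
#' ellipsoidal nucleus mask. The truth table reports each sphere's centre,
#' voxelized volume, and geometric distance from its centre to the nucleus
#' surface (negative inside), computed independently of any segmentation.
#'
#' @param n_spheres Number of spheres to place.
#' @param radius_vox Sphere radius in voxels (recycled per sphere).
#' @param intensity Voxel intensity inside each sphere (recycled).
#' @param dims_vox Stack dimensions `c(nx, ny, nz)` in voxels.
#' @param voxel_size_nm Voxel pitch `c(x, y, z)` in nm (default 55, 55, 150).
#' @param nucleus Optional list with `center_vox` (length 3) and
#'   `semiaxes_vox` (length 3) defining the solid ellipsoid nucleus mask.
#' @param min_gap_vox Minimum gap between sphere surfaces, voxels.
#' @param background Mean background intensity added everywhere.
#' @param noise `"none"` or `"poisson"`.
#' @param seed RNG seed (`NULL` = current state).
#' @param max_tries Rejection-sampling attempts per sphere before failing.
#' @return A list with `stack` (3D array), `truth` (data.frame),
#'   `nucleus_mask` (logical 3D array or NULL) and `voxel_size_nm`.
#' @export
simulate_sphere_field <- function(n_spheres, radius_vox, intensity,
                                  dims_vox = c(64, 64, 32),
                                  voxel_size_nm = c(55, 55, 150),
                                  nucleus = NULL, min_gap_vox = 2,
                                  background = 0,
                                  noise = c("none", "poisson"),
                                  seed = NULL, max_tries = 2000) {
  noise <- match.arg(noise)
  stopifnot(n_spheres >= 0, all(radius_vox > 0), all(intensity > 0),
            length(dims_vox) == 3, length(voxel_size_nm) == 3)
  if (!is.null(seed)) set.seed(seed)
  radius_vox <- rep_len(radius_vox, max(n_spheres, 1))
  intensity <- rep_len(intensity, max(n_spheres, 1))
  nx <- dims_vox[1]; ny <- dims_vox[2]; nz <- dims_vox[3]
  nucleus_mask <- NULL
  if (!is.null(nucleus)) {
    stopifnot(length(nucleus$center_vox) == 3, length(nucleus$semiaxes_vox) == 3)
    gx <- (seq_len(nx) - 0.5 - nucleus$center_vox[1]) / nucleus$semiaxes_vox[1]
    gy <- (seq_len(ny) - 0.5 - nucleus$center_vox[2]) / nucleus$semiaxes_vox[2]
    gz <- (seq_len(nz) - 0.5 - nucleus$center_vox[3]) / nucleus$semiaxes_vox[3]
    nucleus_mask <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`) <= 1
  }
  centers <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n_spheres)) {
    r <- radius_vox[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      c_i <- c(stats::runif(1, r + 1, nx - r - 1),
               stats::runif(1, r + 1, ny - r - 1),
               stats::runif(1, r + 1, nz - r - 1))
      ok <- TRUE
      if (nrow(centers) > 0) {
        dd <- sqrt(rowSums((centers - matrix(c_i, nrow(centers), 3,
                                             byrow = TRUE))^2))
        ok <- all(dd > radius_vox[seq_len(nrow(centers))] + r + min_gap_vox)
      }
      if (ok && !is.null(nucleus)) {
        u <- (c_i - nucleus$center_vox) / (nucleus$semiaxes_vox + r)
        ok <- sum(u^2) > 1   # keep sphere clear of the nucleus
      }
      if (ok) { centers <- rbind(centers, c_i); placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf("could not place sphere %d without overlap after %d tries",
                   i, max_tries), call. = FALSE)
  }
  stack <- array(background, dim = dims_vox)
  vol_vox <- integer(n_spheres)
  for (i in seq_len(n_spheres)) {
    r <- radius_vox[i]; c_i <- centers[i, ]
    ir <- ceiling(r)
    xs <- max(1, floor(c_i[1] - ir)):min(nx, ceiling(c_i[1] + ir))
    ys <- max(1, floor(c_i[2] - ir)):min(ny, ceiling(c_i[2] + ir))
    zs <- max(1, floor(c_i[3] - ir)):min(nz, ceiling(c_i[3] + ir))
    dx <- (xs - 0.5 - c_i[1])^2
    dy <- (ys - 0.5 - c_i[2])^2
    dz <- (zs - 0.5 - c_i[3])^2
    inside <- outer(outer(dx, dy, `+`), dz, `+`) <= r^2
    vol_vox[i] <- sum(inside)
    sub <- stack[xs, ys, zs, drop = FALSE]
    sub[inside] <- sub[inside] + intensity[i]
    stack[xs, ys, zs] <- sub
  }
  if (noise == "poisson")
    stack <- array(stats::rpois(length(stack), stack), dim = dims_vox)
  truth <- data.frame(
    id = seq_len(n_spheres),
    cx_vox = centers[, 1][seq_len(n_spheres)],
    cy_vox = if (n_spheres) centers[, 2] else numeric(0),
    cz_vox = if (n_spheres) centers[, 3] else numeric(0),
    radius_vox = radius_vox[seq_len(n_spheres)],
    intensity = intensity[seq_len(n_spheres)],
    volume_vox = vol_vox)
  if (n_spheres > 0 && !is.null(nucleus)) {
    truth$distance_to_ne_um <- vapply(seq_len(n_spheres), function(i)
      ellipsoid_surface_distance(centers[i, ], nucleus$center_vox,
                                 nucleus$semiaxes_vox, voxel_size_nm),
      numeric(1))
  }
  list(stack = stack, truth = truth, nucleus_mask = nucleus_mask,
       voxel_size_nm = voxel_size_nm)
}

# Signed physical distance from a point to an axis-aligned ellipsoid
# surface (negative inside), by dense surface sampling in physical
# coordinates; accuracy well below one voxel for the sampling used.
ellipsoid_surface_distance <- function(p_vox, center_vox, semiaxes_vox,
                                       voxel_size_nm, n_theta = 240,
                                       n_phi = 120) {
  sp_um <- voxel_size_nm / 1000
  p <- (p_vox - center_vox) * sp_um
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-1]
  phi <- seq(0, pi, length.out = n_phi)
  st <- sin(theta); ct <- cos(theta)
  sf <- sin(phi); cf <- cos(phi)
  ax <- semiaxes_vox * sp_um
  # surface grid (n_theta x n_phi)
  sx <- ax[1] * outer(ct, sf)
  sy <- ax[2] * outer(st, sf)
  sz <- ax[3] * outer(rep(1, n_theta), cf)
  d <- sqrt((sx - p[1])^2 + (sy - p[2])^2 + (sz - p[3])^2)
  inside <- sum((p / ax)^2) <= 1
  (if (inside) -1 else 1) * min(d)
}
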