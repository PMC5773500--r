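sphere_stack <- function(centers, r = 4, dims = c(48, 48, 24),
                         intensity = 50) {
  st <- array(0, dims)
  for (i in seq_len(nrow(centers))) {
    c0 <- centers[i, ]
    xs <- seq_len(dims[1]); ys <- seq_len(dims[2]); zs <- seq_len(dims[3])
    inside <- outer(outer((xs - 0.5 - c0[1])^2, (ys - 0.5 - c0[2])^2, `+`),
                    (zs - 0.5 - c0[3])^2, `+`) <= r^2
    st[inside] <- st[inside] + intensity
  }
  st
}

test_that("empty stacks and empty masks are handled explicitly", {
  seg <- segment_particles(array(0, c(16, 16, 8)), threshold = 1)
  expect_equal(nrow(seg$objects), 0)
  expect_true(all(seg$labels == 0))
  expect_error(distance_to_nucleus(seg$objects,
                                   array(FALSE, c(16, 16, 8))),
               "empty nucleus mask")
})

test_that("well-separated spheres are found with accurate volumes", {
  f <- simulate_sphere_field(4, 4, 50, dims_vox = c(64, 64, 32), seed = 71)
  seg <- segment_particles(f$stack, threshold = 10)
  expect_equal(nrow(seg$objects), 4)
  got <- sort(seg$objects$n_voxels)
  truth <- sort(f$truth$volume_vox)
  expect_true(all(abs(got - truth) <= 0.1 * truth))
  # volumes in physical units
  expect_equal(seg$objects$volume_um3,
               seg$objects$n_voxels * 0.055 * 0.055 * 0.150)
})

test_that("touching spheres are split by the watershed", {
  st <- sphere_stack(rbind(c(14, 24, 12), c(20, 24, 12)))  # overlap < 1 r
  seg <- segment_particles(st, threshold = 10)
  expect_equal(nrow(seg$objects), 2)
  # naive connected components would merge them
  cc <- carpetFCS:::label3d(as.logical(st > 10), as.integer(dim(st)))
  expect_equal(max(cc), 1)
})

test_that("labels conserve the size-filtered foreground", {
  f <- simulate_sphere_field(3, 4, 30, dims_vox = c(48, 48, 24), seed = 72)
  seg <- segment_particles(f$stack, threshold = 5, min_voxels = 5)
  expect_equal(sum(seg$labels > 0), sum(seg$objects$n_voxels))
  # determinism
  seg2 <- segment_particles(f$stack, threshold = 5, min_voxels = 5)
  expect_identical(seg$labels, seg2$labels)
})

test_that("distances to the nucleus edge follow the stated conventions", {
  mask <- array(FALSE, c(40, 40, 20))
  mask[1:20, , ] <- TRUE                    # flat face at x = 20 voxels
  # centroids aligned with surface voxel centres (x = 19.5, y = 19.5,
  # z = 9.5 voxel units) so the expected distances are pure x offsets
  objs <- data.frame(label = 1:3,
                     n_voxels = 10, volume_um3 = 1, total_intensity = 1,
                     cx_um = c(29.5, 19.5, 10.5) * 0.055,
                     cy_um = 19.5 * 0.055, cz_um = 9.5 * 0.150)
  out <- distance_to_nucleus(objs, mask, c(55, 55, 150))
  # 10 voxels outside the surface voxel centre at 55 nm -> 0.55 um
  expect_equal(out$distance_to_ne_um[1], 10 * 0.055, tolerance = 1e-9)
  # exactly on a surface voxel centre
  expect_equal(out$distance_to_ne_um[2], 0, tolerance = 1e-9)
  # inside: negative
  expect_lt(out$distance_to_ne_um[3], 0)
})

test_that("segmentation distances agree with geometric ground truth", {
  f <- simulate_sphere_field(5, 4, 50, dims_vox = c(64, 64, 32),
                             nucleus = list(center_vox = c(32, 32, 16),
                                            semiaxes_vox = c(14, 12, 8)),
                             seed = 73)
  seg <- segment_particles(f$stack, threshold = 10)
  objs <- distance_to_nucleus(seg$objects, f$nucleus_mask, f$voxel_size_nm)
  expect_equal(sort(objs$distance_to_ne_um),
               sort(f$truth$distance_to_ne_um), tolerance = 0.12)
})

test_that("doubling voxel sizes doubles distances and scales volumes x8", {
  f <- simulate_sphere_field(3, 4, 40, dims_vox = c(48, 48, 24),
                             nucleus = list(center_vox = c(24, 24, 12),
                                            semiaxes_vox = c(10, 9, 6)),
                             seed = 74)
  s1 <- segment_particles(f$stack, voxel_size_nm = c(55, 55, 150),
                          threshold = 10)
  s2 <- segment_particles(f$stack, voxel_size_nm = 2 * c(55, 55, 150),
                          threshold = 10)
  expect_identical(s1$labels, s2$labels)
  expect_equal(s2$objects$volume_um3, 8 * s1$objects$volume_um3)
  d1 <- distance_to_nucleus(s1$objects, f$nucleus_mask, c(55, 55, 150))
  d2 <- distance_to_nucleus(s2$objects, f$nucleus_mask, 2 * c(55, 55, 150))
  expect_equal(d2$distance_to_ne_um, 2 * d1$distance_to_ne_um,
               tolerance = 1e-9)
})

test_that("distance binning reports contiguous bins with SEM rules", {
  objs <- data.frame(label = 1:5, n_voxels = 10, volume_um3 = c(1, 2, 3, 4, 5),
                     total_intensity = c(10, 20, 30, 40, 50),
                     cx_um = 0, cy_um = 0, cz_um = 0,
                     distance_to_ne_um = c(0.1, 0.2, 0.3, 1.4, 2.2))
  b <- bin_by_distance(objs, 0.5)
  expect_equal(b$n_objects, c(3, 0, 1, 0, 1))
  expect_equal(b$mean_volume_um3[1], 2)
  expect_true(is.na(b$sem_volume_um3[5]))        # single object, SEM null
  expect_true(all(diff(b$bin_lo_um) == 0.5))     # contiguous incl. empties
  expect_error(bin_by_distance(objs, 0), "positive")
  # all in one bin: bin mean equals the sample mean
  one <- bin_by_distance(transform(objs, distance_to_ne_um = 0.2), 1)
  expect_equal(one$mean_volume_um3, mean(objs$volume_um3))
})

test_that("SEM shrinks with object count at fixed variance", {
  set.seed(75)
  mk <- function(n) data.frame(label = seq_len(n), n_voxels = 10,
                               volume_um3 = rnorm(n, 5, 1),
                               total_intensity = 1, cx_um = 0, cy_um = 0,
                               cz_um = 0, distance_to_ne_um = 0.25)
  s1 <- bin_by_distance(mk(40), 1)$sem_volume_um3
  s2 <- bin_by_distance(mk(160), 1)$sem_volume_um3
  expect_equal(s2 / s1, 0.5, tolerance = 0.3)
})

test_that("Otsu threshold separates a bimodal volume", {
  set.seed(76)
  x <- c(rnorm(5000, 2, 0.5), rnorm(500, 30, 2))
  th <- otsu_threshold(x)
  expect_gt(th, 5); expect_lt(th, 28)
})
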