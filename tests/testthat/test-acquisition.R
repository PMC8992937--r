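# Projector physics and the gated-bin time-resampling scheme.

slab_phantom <- function(n = 32) {
  act <- array(0, c(n, n, n))
  act[8:24, 16, 8:24] <- 3  # one-voxel-thick slab facing +y
  structure(list(activity = act, mu_map = array(0, c(n, n, n)),
                 voxel_size = 4.8), class = "voxel_phantom")
}

point_phantom <- function(n = 64, j = 20, value = 100) {
  act <- array(0, c(n, n, n))
  act[n / 2 + 1, j, n / 2 + 1] <- value
  structure(list(activity = act, mu_map = array(0, c(n, n, n)),
                 voxel_size = 4.8), class = "voxel_phantom")
}

test_that("projection of a thin slab is thickness x concentration x sensitivity", {
  vox <- slab_phantom()
  geom <- acq_geometry(n_views_per_head = 2, n_heads = 2,
                       matrix_dim = c(32, 32), orbit_radius = 150,
                       time_per_view = 15)
  nf <- forward_project(vox, geom, attenuation = FALSE, blur = FALSE,
                        sensitivity = 2.5)
  # view 1 is at angle 0: rays along +y cross one voxel of concentration 3
  expect_equal(nf$rate[16, 16, 1], 3 * 2.5)
  expect_equal(max(abs(nf$rate[8:24, 8:24, 1] - 7.5)), 0)
})

test_that("attenuation follows Beer-Lambert through a known water path", {
  vox <- point_phantom()
  vox_att <- vox
  vox_att$mu_map[33, 36:45, 33] <- 0.154  # 10 voxels = 4.8 cm of water
  geom <- fix_geom64()
  p0 <- forward_project(vox, geom, attenuation = FALSE, blur = FALSE)$rate[33, 33, 1]
  p1 <- forward_project(vox_att, geom, attenuation = TRUE, blur = FALSE)$rate[33, 33, 1]
  expect_equal(p1 / p0, exp(-0.154 * 10 * 0.48), tolerance = 1e-10)
})

test_that("collimator blur FWHM grows as intercept + slope x distance", {
  geom <- fix_geom64()
  for (j in c(20, 45)) {
    vox <- point_phantom(j = j)
    prof <- forward_project(vox, geom, attenuation = FALSE,
                            blur = TRUE)$rate[, 33, 1]
    xs <- (seq_len(64) - 33) * 4.8
    m1 <- sum(prof * xs) / sum(prof)
    fwhm_meas <- 2 * sqrt(2 * log(2)) *
      sqrt(sum(prof * (xs - m1)^2) / sum(prof))
    dist <- 250 - (j - 1 - 32) * 4.8
    fwhm_exp <- 4 + 0.05 * dist
    expect_lt(abs(fwhm_meas - fwhm_exp), 2.4)  # within half a pixel
  }
})

test_that("forward projection is linear in activity", {
  tiny <- fix_tiny()
  p1 <- forward_project(tiny$vox, tiny$geom)$rate
  vox3 <- tiny$vox; vox3$activity <- 3 * vox3$activity
  p3 <- forward_project(vox3, tiny$geom)$rate
  expect_equal(p3, 3 * p1, tolerance = 1e-12)
})

test_that("enabling attenuation reduces total expected counts", {
  tiny <- fix_tiny()
  t_on <- sum(forward_project(tiny$vox, tiny$geom, attenuation = TRUE)$rate)
  t_off <- sum(forward_project(tiny$vox, tiny$geom, attenuation = FALSE)$rate)
  expect_lt(t_on, t_off)
})

test_that("incommensurate grids are rejected", {
  tiny <- fix_tiny()
  geom_bad <- acq_geometry(matrix_dim = c(64, 64))
  expect_error(forward_project(tiny$vox, geom_bad), "resampling")
  geom_bad2 <- acq_geometry(n_views_per_head = 12, n_heads = 2,
                            matrix_dim = c(32, 32), pixel_size = 2.4)
  expect_error(forward_project(tiny$vox, geom_bad2), "resampling")
})

test_that("gated bins have the per-bin expectation and Poisson variance", {
  # small noise-free set so 1000 bins are cheap; fixed seeds
  rate <- array(c(2, 20, 100, 7), c(2, 2, 1))
  nf <- structure(list(rate = rate,
                       geometry = acq_geometry(n_views_per_head = 1,
                                               n_heads = 1,
                                               matrix_dim = c(2, 2)),
                       voxel_size = 4.8, sensitivity = 1,
                       model_flags = list(attenuation = FALSE, blur = FALSE)),
                  class = "projection_set")
  st <- simulate_gated_acquisition(nf, n_gate_bins = 1000, time_per_view = 1000,
                                   seed = 11)
  expect_true(all(st$counts >= 0))
  expect_true(all(st$counts == round(st$counts)))
  for (i in 1:2) for (j in 1:2) {
    draws <- st$counts[i, j, 1, ]
    se <- sqrt(rate[i, j, 1] / 1000)
    expect_lt(abs(mean(draws) - rate[i, j, 1]), 3 * se)
  }
})

test_that("zero expectation gives zero counts", {
  nf <- structure(list(rate = array(0, c(2, 2, 1)),
                       geometry = acq_geometry(n_views_per_head = 1,
                                               n_heads = 1,
                                               matrix_dim = c(2, 2)),
                       voxel_size = 4.8, sensitivity = 1,
                       model_flags = list(attenuation = FALSE, blur = FALSE)),
                  class = "projection_set")
  st <- simulate_gated_acquisition(nf, 15, 15, seed = 3)
  expect_true(all(st$counts == 0))
})

test_that("gated simulation is seed-deterministic with stable substreams", {
  nf <- fix_noise_free()
  s1 <- simulate_gated_acquisition(nf, 15, seed = 42)
  s2 <- simulate_gated_acquisition(nf, 15, seed = 42)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_gated_acquisition(nf, 15, seed = 43)
  expect_false(identical(s1$counts, s3$counts))
  # per-bin substreams: the first 8 bins do not depend on the bin count
  s8 <- simulate_gated_acquisition(nf, 8, time_per_view = 8, seed = 42)
  expect_identical(s8$counts[, , , 1:8], s1$counts[, , , 1:8])
})

test_that("bin sums reproduce the 3/8/15 s resampling table", {
  nf <- fix_noise_free()
  st <- simulate_gated_acquisition(nf, 15, seed = 5)
  s3 <- sum_bins(st, c(1, 3)); s8 <- sum_bins(st, c(1, 8))
  s15 <- sum_bins(st, c(1, 15))
  expect_equal(s3$bin_duration, 3)
  expect_equal(s8$bin_duration, 8)
  expect_equal(s15$bin_duration, 15)
  expect_equal(s15$counts[, , , 1], apply(st$counts, 1:3, sum))
  # associativity: (1-3) + (4-8) = (1-8)
  s48 <- sum_bins(st, c(4, 8))
  expect_equal(s3$counts[, , , 1] + s48$counts[, , , 1], s8$counts[, , , 1])
  expect_error(sum_bins(st, c(0, 3)), "index")
  expect_error(sum_bins(st, c(9, 16)), "index")
})

test_that("summed bins match a single full-duration acquisition in law", {
  # 500 seeds: per-pixel mean and variance of the 15-bin sum both match
  # the full-duration expectation within 3 standard errors
  rate <- array(c(1.5, 12, 40, 4), c(2, 2, 1))
  nf <- structure(list(rate = rate,
                       geometry = acq_geometry(n_views_per_head = 1,
                                               n_heads = 1,
                                               matrix_dim = c(2, 2)),
                       voxel_size = 4.8, sensitivity = 1,
                       model_flags = list(attenuation = FALSE, blur = FALSE)),
                  class = "projection_set")
  n_rep <- 500
  sums <- vapply(seq_len(n_rep), function(sd) {
    st <- simulate_gated_acquisition(nf, 15, 15, seed = 1000 + sd)
    as.numeric(sum_bins(st, c(1, 15))$counts[, , 1, 1])
  }, numeric(4))
  lambda <- 15 * as.numeric(rate)
  for (p in 1:4) {
    se_mean <- sqrt(lambda[p] / n_rep)
    expect_lt(abs(mean(sums[p, ]) - lambda[p]), 3 * se_mean)
    # var(sample variance) ~ 2 lambda^2 / (n-1) + lambda/n for Poisson
    se_var <- sqrt(2 * lambda[p]^2 / (n_rep - 1) + lambda[p] / n_rep)
    expect_lt(abs(var(sums[p, ]) - lambda[p]), 3 * se_var)
  }
})

test_that("total scan time follows the per-view time", {
  geom <- acq_geometry()
  expect_equal(total_scan_time(geom, 8) / 60, 8)   # 8 s/view -> 8 min
  expect_equal(total_scan_time(geom) / 60, 15)     # 15 s/view -> 15 min
  expect_equal(geom$n_projections, 120)
})
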