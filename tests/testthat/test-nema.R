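# ROI layout rules and the image-quality metric definitions.

test_that("layout yields 12 background positions and 60 ROIs per diameter", {
  lay <- fix_layout64()
  expect_equal(nrow(lay$background_positions), 12)
  expect_equal(lay$n_background_rois, 60)
  expect_equal(length(lay$analysis_slices), 5)
  expect_equal(lay$analysis_slices, lay$central_slice + (-2:2))
  expect_equal(lay$roi_diameters, fix_spec()$sphere_diameters)
})

test_that("background ROIs respect the 15 mm margin rules", {
  lay <- fix_layout64()
  spec <- fix_spec()
  tt <- seq(0, 2 * pi, length.out = 3601)[-3601]
  bx <- spec$body_semiaxes[1] * cos(tt); by <- spec$body_semiaxes[2] * sin(tt)
  for (i in seq_len(12)) {
    p <- lay$background_positions[i, ]
    # edge-to-margin >= 15 means centre-to-boundary >= 15 + 18.5
    expect_gte(min(sqrt((bx - p[1])^2 + (by - p[2])^2)), 15 + 18.5 - 1e-6)
    ds <- sqrt((spec$sphere_centers[, "x"] - p[1])^2 +
                 (spec$sphere_centers[, "y"] - p[2])^2)
    expect_true(all(ds >= 15 + 18.5 + spec$sphere_diameters / 2 - 1e-6))
  }
  # no two 37 mm ROIs overlap
  dmat <- as.matrix(dist(lay$background_positions))
  expect_true(all(dmat[upper.tri(dmat)] >= 37 - 1e-6))
})

test_that("infeasible layouts fail with a diagnostic", {
  small <- phantom_spec(body_semiaxes = c(100, 80),
                        sphere_ring_radius = 40,
                        sphere_diameters = c(20, 17, 15, 13, 11, 10),
                        fill_plan = compute_fill_plan(214.2, 1200,
                                                      c(20, 17, 15, 13, 11, 10),
                                                      9787))
  expect_error(build_roi_layout(small, c(64, 64, 64), 4.8),
               "layout-infeasible")
})

test_that("contrast recovery closed forms", {
  expect_equal(contrast_recovery(8.5, 1, 8.5), 100)   # perfect recovery
  expect_equal(contrast_recovery(1, 1, 8.5), 0)       # no contrast
  expect_equal(contrast_recovery(5.675, 1, 8.5), 100 * 4.675 / 7.5)
  expect_equal(contrast_recovery(5.675, 1, 8.5), 62.33, tolerance = 1e-4)
  expect_error(contrast_recovery(1, 0, 8.5), "undefined")
  expect_error(contrast_recovery(1, 1, 1), "invalid")
})

test_that("background variability closed forms and Eq. 3 denominator", {
  expect_equal(background_variability(rep(4, 60)), 0)
  expect_equal(background_variability(c(9, 11)), 100 * sqrt(2) / 10)
  expect_equal(background_variability(c(9, 11)), 14.14, tolerance = 1e-3)
  expect_equal(background_variability(2 * c(9, 11)),
               background_variability(c(9, 11)))
  # sample SD (K - 1) against a brute-force two-pass oracle
  set.seed(4)
  for (i in 1:20) {
    v <- rlnorm(60)
    mbar <- sum(v) / 60
    oracle <- sqrt(sum((v - mbar)^2) / 59)
    expect_equal(background_variability(v), 100 * oracle / mbar,
                 tolerance = 1e-12)
  }
  expect_error(background_variability(c(5)), "invalid")
  expect_error(background_variability(c(0, 0)), "undefined")
})

test_that("CNR boundary is strict at the Rose criterion", {
  expect_equal(cnr(10, 10, 2)$cnr, 0)
  expect_false(cnr(10, 10, 2)$rose_visible)
  at5 <- cnr(20, 10, 2)           # contrast 10, SD 2 -> exactly 5
  expect_equal(at5$cnr, 5)
  expect_false(at5$rose_visible)  # strict >
  expect_true(cnr(20.001, 10, 2)$rose_visible)
  expect_error(cnr(1, 0, 0), "undefined")
})

test_that("circular ROI membership approximates the analytic area", {
  # fractional-area weighting against the analytic circle area; the
  # centre-in rule within the quantisation bound of its perimeter
  slice <- matrix(1, 64, 64)
  for (d in c(37, 28, 22, 17, 13, 10)) {
    for (off in list(c(0, 0), c(1.7, -2.2), c(2.4, 2.4))) {
      w <- roi_stats_slice(slice, off, d, 4.8, fractional = TRUE)$weight
      expect_equal(w * 4.8^2, pi * (d / 2)^2, tolerance = 0.02)
      npx <- roi_stats_slice(slice, off, d, 4.8)$weight
      expect_lt(abs(npx * 4.8^2 - pi * (d / 2)^2),
                (pi * d + 4.8) * 4.8)  # perimeter-band quantisation
    }
  }
})

test_that("metrics are invariant to positive rescaling of the volume", {
  vox <- fix_vox64()
  lay <- fix_layout64()
  R <- fix_spec()$fill_plan$ratio_R
  set.seed(9)
  noisy <- vox$activity * (1 + 0.2 * array(runif(length(vox$activity)),
                                           dim(vox$activity)))
  m1 <- evaluate_volume(noisy, lay, R)
  m2 <- evaluate_volume(noisy * 17.3, lay, R)
  expect_equal(m1$RC, m2$RC, tolerance = 1e-12)
  expect_equal(m1$BV, m2$BV, tolerance = 1e-12)
  expect_equal(m1$CNR, m2$CNR, tolerance = 1e-12)
})

test_that("the binary-digitised ground truth scores perfect recovery", {
  vox <- fix_vox64_binary()
  m <- evaluate_volume(vox$activity, fix_layout64(),
                       fix_spec()$fill_plan$ratio_R)
  expect_equal(m$RC, rep(100, 6), tolerance = 1e-9)
  expect_equal(m$BV, rep(0, 6), tolerance = 1e-9)
})

test_that("a uniform volume has zero contrast and zero variability", {
  lay <- fix_layout64()
  m <- evaluate_volume(array(5, c(64, 64, 64)), lay, 8.5)
  expect_equal(m$RC, rep(0, 6))
  expect_equal(m$BV, rep(0, 6))
  expect_true(all(is.na(m$CNR)))  # SD 0: CNR undefined
})

test_that("supersampled ground truth scores within partial-volume bounds", {
  # sub-voxel-averaged digitisation lowers the centre-rule sphere mean:
  # recovery stays high but below 100, more so for small spheres
  m <- evaluate_volume(fix_vox64()$activity, fix_layout64(),
                       fix_spec()$fill_plan$ratio_R)
  expect_true(all(m$RC <= 100))
  expect_gte(m$RC[m$sphere_mm == 37], 90)
  expect_true(all(m$BV < 1))
})
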