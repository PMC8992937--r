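# OSEM update correctness against hand and brute-force oracles, EM
# properties on the matched projector, and the Gaussian post-filter.

# independent MLEM oracle: textbook update written directly
mlem_oracle <- function(y, A, n_iter, x0 = rep(1, ncol(A))) {
  x <- x0
  sens <- colSums(A)
  for (i in seq_len(n_iter)) {
    fp <- A %*% x
    r <- ifelse(fp > 0, y / fp, 0)
    x <- x * as.numeric(t(A) %*% r) / sens
  }
  x
}

test_that("identity system: one MLEM update returns the data exactly", {
  y <- c(2, 5, 0.5, 7)
  x1 <- osem_matrix(y, diag(4), n_iterations = 1)
  expect_equal(x1, y)
})

test_that("two-voxel hand system matches the hand-computed update", {
  # A = [[1,0],[1,1]], y = (2,5), x0 = (1,1):
  # fp = (1,2); ratio = (2, 2.5); A^T ratio = (4.5, 2.5); sens = (2,1)
  # x1 = (1,1) * (4.5/2, 2.5/1) = (2.25, 2.5)
  A <- matrix(c(1, 1, 0, 1), 2, 2)
  x1 <- osem_matrix(c(2, 5), A, n_iterations = 1)
  expect_equal(x1, c(2.25, 2.5))
})

test_that("OSEM with one subset equals the MLEM oracle on a random toy system", {
  set.seed(17)
  A <- matrix(runif(16 * 16), 16, 16)
  xt <- runif(16, 0.5, 2)
  y <- as.numeric(A %*% xt)
  for (it in c(1, 5, 20)) {
    expect_equal(osem_matrix(y, A, n_iterations = it),
                 mlem_oracle(y, A, it), tolerance = 1e-12)
  }
})

test_that("subset count must divide the measurements", {
  expect_error(osem_matrix(rep(1, 10), matrix(1, 10, 4), n_subsets = 3),
               "configuration error")
})

test_that("matched-model OSEM preserves non-negativity and increases the likelihood", {
  tiny <- fix_tiny()
  nf <- forward_project(tiny$vox, tiny$geom)
  st <- exact_stack(nf)
  prm <- recon_params(n_iterations = 6, n_subsets = 1, postfilter_fwhm = 0)
  run <- osem(st, tiny$vox$mu_map, prm, snapshots = 1:6)
  ll <- vapply(run$snapshots, function(v) {
    expect_true(all(v$values >= 0))
    osem_loglik(v, st, tiny$vox$mu_map, prm)
  }, numeric(1))
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-6])))
})

test_that("count conservation: projected totals match the data within 1%", {
  tiny <- fix_tiny()
  nf <- forward_project(tiny$vox, tiny$geom, attenuation = FALSE, blur = TRUE)
  st <- exact_stack(nf)
  prm <- recon_params(n_subsets = 8, postfilter_fwhm = 0, attenuation = FALSE)
  for (it in c(1, 3)) {
    p <- prm; p$n_iterations <- as.integer(it)
    vol <- osem(st, NULL, p)
    expect_equal(osem_projected_total(vol, st, NULL, p), sum(st$counts),
                 tolerance = 0.01)
  }
})

test_that("noise-free matched reconstruction recovers the largest sphere", {
  # blur-free, attenuation-free projections of the binary-digitised
  # phantom: 12 iterations x 8 subsets must restore >= 95% contrast
  # recovery for the 37 mm sphere
  vox <- fix_vox64_binary()
  nf <- forward_project(vox, fix_geom64(), attenuation = FALSE, blur = FALSE)
  st <- exact_stack(nf)
  vol <- osem(st, NULL, recon_params(12, 8, 0, attenuation = FALSE,
                                     resolution_recovery = FALSE))
  m <- evaluate_volume(vol, fix_layout64(), fix_spec()$fill_plan$ratio_R)
  expect_gte(m$RC[m$sphere_mm == 37], 95)
})

test_that("all-zero projections return a zero volume with a warning", {
  tiny <- fix_tiny()
  nf <- forward_project(tiny$vox, tiny$geom)
  st <- exact_stack(nf)
  st$counts[] <- 0
  expect_warning(vol <- osem(st, tiny$vox$mu_map,
                             recon_params(1, 8, 0)), "all-zero")
  expect_true(all(vol$values == 0))
})

test_that("post-filter: identity at fwhm 0, impulse response width, flat fields", {
  n <- 33
  arr <- array(0, c(n, n, n)); arr[17, 17, 17] <- 1
  vol <- structure(list(values = arr, voxel_size = 4.8,
                        params = recon_params(1, 1, 0), duration = 15,
                        noise_seed = 1), class = "recon_volume")
  expect_identical(gaussian_postfilter_3d(vol, 0)$values, arr)
  expect_error(gaussian_postfilter_3d(vol, -1), "invalid")

  sm <- gaussian_postfilter_3d(vol, 8)$values
  prof <- sm[, 17, 17]
  xs <- (seq_len(n) - 17) * 4.8
  fwhm <- 2 * sqrt(2 * log(2)) * sqrt(sum(prof * xs^2) / sum(prof))
  expect_equal(fwhm, 8, tolerance = 0.05)
  expect_equal(sum(sm), 1, tolerance = 1e-9)  # interior sums preserved

  flat <- array(3, c(n, n, n))
  smf <- gaussian_postfilter_3d(flat, 8)
  expect_equal(smf[5:29, 5:29, 5:29], flat[5:29, 5:29, 5:29],
               tolerance = 1e-12)
})

test_that("background variance is non-increasing in post-filter width", {
  tab <- fix_trend_table()
  # BV at the study operating point: 8 mm must not exceed unfiltered
  g <- tab[tab$iterations == 12 & tab$duration_s == 15, ]
  bv0 <- mean(g$BV[g$fwhm_mm == 0])
  bv8 <- mean(g$BV[g$fwhm_mm == 8])
  expect_lte(bv8, bv0)
})
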