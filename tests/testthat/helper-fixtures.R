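# Shared fixtures, built once per test run and memoised. The study-scale
# objects (64^3 grid, 120 views, 1e6 total counts at 15 s) mirror the
# package defaults at test-tractable grid size.

.fix_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fix_env)) {
    assign(name, force(expr), envir = .fix_env)
  }
  get(name, envir = .fix_env)
}

fix_spec <- function() memo("spec", phantom_spec())

fix_geom64 <- function() memo("geom64", acq_geometry(matrix_dim = c(64, 64)))

fix_vox64 <- function() {
  memo("vox64", voxelize_phantom(fix_spec(), 4.8, c(64, 64, 64), 4))
}

fix_vox64_binary <- function() {
  memo("vox64b", voxelize_phantom(fix_spec(), 4.8, c(64, 64, 64), 1))
}

fix_layout64 <- function() {
  memo("layout64", build_roi_layout(fix_spec(), c(64, 64, 64), 4.8))
}

# calibrated noise-free study projections (blur + attenuation)
fix_noise_free <- function() {
  memo("nf64", calibrate_sensitivity(
    forward_project(fix_vox64(), fix_geom64()), 1e6))
}

# a tiny off-centre blob phantom for fast reconstruction properties
fix_tiny <- function() {
  memo("tiny", {
    n <- 32
    act <- array(0, c(n, n, n))
    act[12:18, 14:20, 15:18] <- 5
    act[20:22, 10:12, 16:17] <- 9
    mu <- array(0, c(n, n, n))
    mu[8:24, 8:24, 10:22] <- 0.154
    vox <- structure(list(activity = act, mu_map = mu, voxel_size = 4.8),
                     class = "voxel_phantom")
    geom <- acq_geometry(n_views_per_head = 12, n_heads = 2,
                         matrix_dim = c(n, n), orbit_radius = 150)
    list(vox = vox, geom = geom)
  })
}

# noise-free single-bin stack holding exact expected counts (no Poisson
# draw), for convergence/likelihood properties
exact_stack <- function(nf, time_per_view = 15) {
  st <- simulate_gated_acquisition(nf, 1, time_per_view, seed = 1)
  st$counts <- array(nf$rate * time_per_view, c(dim(nf$rate), 1))
  st
}

# The scaled-down replication of the study: 10 gated realisations,
# durations 3/8/15 s, reconstructions at 4 and 12 iterations (8 subsets),
# post-filters 0 and 8 mm. Built once; used by the trend and acceptance
# tests.
fix_trend_table <- function() {
  memo("trend", {
    cfg <- sweep_config(durations = c(3, 8, 15), iteration_grid = c(4, 12),
                        subsets = 8, fwhm_grid = c(0, 8), seeds = 1:10)
    run_parameter_sweep(fix_vox64(), fix_noise_free(), cfg,
                        layout = fix_layout64())
  })
}

trend_means <- function(tab = fix_trend_table()) {
  summarize_sweep(tab)
}
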