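#' Dual-head step-and-shoot acquisition geometry
#'
#' Defaults follow a clinical bone protocol: 60 views per detector head
#' (120 projections in total) over 360 degrees, 128 x 128 matrix, 4.8 mm
#' pixels, 15 s per view, circular orbit. The collimator-detector response
#' is a distance-dependent Gaussian with FWHM = intercept + slope * distance.
#'
#' @param n_views_per_head Views acquired per head.
#' @param n_heads Number of detector heads (acquire in parallel, so total
#'   projections = `n_views_per_head * n_heads` and total scan time is
#'   `n_views_per_head * time_per_view`).
#' @param arc Total angular coverage in degrees.
#' @param matrix_dim Projection matrix dimensions (transaxial, axial).
#' @param pixel_size Projection pixel size in mm.
#' @param orbit_radius Detector orbit radius in mm (circular orbit).
#' @param time_per_view Acquisition time per view in seconds.
#' @param collimator Named vector `c(fwhm_intercept = , fwhm_slope = )`:
#'   blur FWHM in mm at zero distance and its growth per mm of distance.
#' @return An object of class `acq_geometry`.
#' @export
acq_geometry <- function(n_views_per_head = 60, n_heads = 2, arc = 360,
                         matrix_dim = c(128, 128), pixel_size = 4.8,
                         orbit_radius = 250, time_per_view = 15,
                         collimator = c(fwhm_intercept = 4, fwhm_slope = 0.05)) {
  .check_positive(n_views_per_head, "n_views_per_head")
  .check_positive(n_heads, "n_heads")
  .check_positive(pixel_size, "pixel_size")
  .check_positive(orbit_radius, "orbit_radius")
  .check_positive(time_per_view, "time_per_view")
  stopifnot(length(matrix_dim) == 2)

  n_proj <- n_views_per_head * n_heads
  structure(list(
    n_views_per_head = n_views_per_head,
    n_heads = n_heads,
    n_projections = n_proj,
    arc = arc,
    matrix_dim = as.integer(matrix_dim),
    pixel_size = pixel_size,
    orbit_radius = orbit_radius,
    time_per_view = time_per_view,
    collimator = collimator,
    view_angles_deg = seq(0, arc, length.out = n_proj + 1)[seq_len(n_proj)]
  ), class = "acq_geometry")
}

#' Total scan time of a step-and-shoot acquisition
#'
#' Heads acquire simultaneously, so the scan lasts
#' `n_views_per_head * time_per_view` seconds regardless of head count.
#'
#' @param geometry An [acq_geometry()].
#' @param time_per_view Optional override of the per-view time (s).
#' @return Scan time in seconds.
#' @export
total_scan_time <- function(geometry, time_per_view = geometry$time_per_view) {
  geometry$n_views_per_head * time_per_view
}

# Per-y-plane blur sigma (in pixels) for a rotated volume: plane j sits at
# distance orbit_radius - y_j from the detector at +y.
.plane_sigmas_px <- function(geometry, ny, voxel_size) {
  y_mm <- .axis_coords(ny, voxel_size)
  d <- pmax(geometry$orbit_radius - y_mm, 0)
  fwhm <- geometry$collimator[["fwhm_intercept"]] +
    geometry$collimator[["fwhm_slope"]] * d
  .fwhm_to_sigma(fwhm) / voxel_size
}

# Incremental blur variances (px^2) for the plane-marching Gaussian
# cascade: delta_j = sigma_j^2 - sigma_{j+1}^2 (sigma decreases towards
# the detector), last plane gets its full variance.
.plane_blur_deltas <- function(geometry, ny, voxel_size) {
  v <- .plane_sigmas_px(geometry, ny, voxel_size)^2
  pmax(v - c(v[-1], 0), 0)
}

.check_commensurate <- function(vox, geometry) {
  d <- dim(vox$activity)
  if (abs(vox$voxel_size - geometry$pixel_size) > 1e-9)
    stop("resampling error: projection pixel size must equal the phantom ",
         "voxel size", call. = FALSE)
  if (geometry$matrix_dim[1] != d[1] || geometry$matrix_dim[2] != d[3])
    stop("resampling error: projection matrix must match the phantom grid ",
         "(transaxial, axial)", call. = FALSE)
  invisible(TRUE)
}

# Precompute per-view transmission cubes in the rotated frame (list of
# cubes), or NULL when attenuation is off.
.view_transmissions <- function(mu_map, geometry, voxel_size) {
  step_cm <- voxel_size / 10
  lapply(geometry$view_angles_deg * pi / 180, function(th) {
    cpp_transmission(cpp_rotate_z(mu_map, th), step_cm)
  })
}

.null_cube <- array(0, c(1, 1, 1))

#' Noise-free forward projection of a voxelized phantom
#'
#' Rotation-based projector: for each view the activity (and attenuation)
#' volume is rotated into the detector frame, each constant-distance plane
#' is blurred with the distance-dependent collimator kernel, attenuated by
#' the Beer-Lambert transmission to the detector, and summed along the
#' rays. The result is an expected count *rate* (counts/s per pixel) at
#' the given sensitivity.
#'
#' @param vox A [voxelize_phantom()] result.
#' @param geometry An [acq_geometry()]; its matrix and pixel size must
#'   match the phantom grid.
#' @param attenuation,blur Model component switches.
#' @param sensitivity Counts per second per (kBq/ml summed along one voxel
#'   of ray depth); see [calibrate_sensitivity()].
#' @return An object of class `projection_set`: `rate` is an array
#'   (transaxial, axial, view) of expected counts/s.
#' @export
forward_project <- function(vox, geometry, attenuation = TRUE, blur = TRUE,
                            sensitivity = 1) {
  stopifnot(inherits(vox, "voxel_phantom") || is.list(vox))
  .check_commensurate(vox, geometry)
  if (!is.numeric(sensitivity) || sensitivity < 0)
    stop("invalid parameter: sensitivity must be non-negative", call. = FALSE)

  d <- dim(vox$activity)
  sig <- .plane_blur_deltas(geometry, d[2], vox$voxel_size)
  Tv <- if (attenuation) .view_transmissions(vox$mu_map, geometry, vox$voxel_size)
  rate <- array(0, c(d[1], d[3], geometry$n_projections))
  th <- geometry$view_angles_deg * pi / 180
  for (v in seq_len(geometry$n_projections)) {
    rate[, , v] <- cpp_fp_view(vox$activity, th[v],
                               if (attenuation) Tv[[v]] else .null_cube,
                               attenuation, sig, blur, sensitivity)
  }
  structure(list(rate = rate, geometry = geometry,
                 voxel_size = vox$voxel_size,
                 model_flags = list(attenuation = attenuation, blur = blur),
                 sensitivity = sensitivity),
            class = "projection_set")
}

#' Scale a noise-free projection set to a target total count level
#'
#' The sensitivity is chosen so that an acquisition of `time_per_view`
#' seconds per view totals `target_total` expected counts over all
#' projections (default 1e6 for the 15 s protocol).
#'
#' @param proj A [forward_project()] result.
#' @param target_total Desired expected total counts.
#' @param time_per_view Per-view time in seconds used for the target.
#' @return The projection set rescaled, with `sensitivity` updated.
#' @export
calibrate_sensitivity <- function(proj, target_total = 1e6,
                                  time_per_view = proj$geometry$time_per_view) {
  stopifnot(inherits(proj, "projection_set"))
  .check_positive(target_total, "target_total")
  tot <- sum(proj$rate) * time_per_view
  if (tot <= 0) stop("cannot calibrate: projections are all zero", call. = FALSE)
  f <- target_total / tot
  proj$rate <- proj$rate * f
  proj$sensitivity <- proj$sensitivity * f
  proj
}

# Per-bin RNG substream: a fixed multiplier scheme keeps every bin's draw
# independent of how many bins are simulated.
.bin_seed <- function(seed, bin) {
  as.integer((as.numeric(seed) * 1009 + bin * 9973) %% 2147483647)
}

#' Simulate a gated Poisson acquisition
#'
#' Each of `n_gate_bins` bins is an independent Poisson realisation with
#' mean `rate * time_per_view / n_gate_bins`, emulating an ECG-triggered
#' gated scan whose bins can later be summed into shorter effective
#' acquisition durations.
#'
#' @param proj A [forward_project()] result (expected counts/s).
#' @param n_gate_bins Number of gate bins (default 15).
#' @param time_per_view Total per-view acquisition time in seconds.
#' @param seed Integer seed; identical seeds give identical stacks.
#' @return An object of class `projection_stack` with integer `counts`
#'   indexed (transaxial, axial, view, bin) and `bin_duration` seconds.
#' @export
simulate_gated_acquisition <- function(proj, n_gate_bins = 15,
                                       time_per_view = proj$geometry$time_per_view,
                                       seed = 1) {
  stopifnot(inherits(proj, "projection_set"))
  n_gate_bins <- as.integer(n_gate_bins)
  stopifnot(n_gate_bins >= 1)
  .check_positive(time_per_view, "time_per_view")

  d <- dim(proj$rate)
  mean_per_bin <- proj$rate * (time_per_view / n_gate_bins)
  counts <- array(0L, c(d, n_gate_bins))
  for (b in seq_len(n_gate_bins)) {
    set.seed(.bin_seed(seed, b))
    counts[, , , b] <- rpois(length(mean_per_bin), mean_per_bin)
  }
  structure(list(counts = counts, geometry = proj$geometry,
                 n_gate_bins = n_gate_bins,
                 bin_duration = time_per_view / n_gate_bins,
                 time_per_view = time_per_view,
                 voxel_size = proj$voxel_size,
                 sensitivity = proj$sensitivity,
                 model_flags = proj$model_flags,
                 noise_seed = seed),
            class = "projection_stack")
}

#' Sum a range of gate bins into one effective acquisition
#'
#' Summing bins 1-3, 1-8 and 1-15 of a 15-bin, 15 s/view acquisition
#' yields the 3, 8 and 15 s/view datasets of a time-resampling study.
#'
#' @param stack A [simulate_gated_acquisition()] result.
#' @param bin_range Inclusive `c(first, last)` bin indices.
#' @return A `projection_stack` with a single summed bin and
#'   `bin_duration` equal to the summed time.
#' @export
sum_bins <- function(stack, bin_range) {
  stopifnot(inherits(stack, "projection_stack"))
  bin_range <- as.integer(bin_range)
  if (length(bin_range) != 2 || any(is.na(bin_range)) ||
      bin_range[1] > bin_range[2] ||
      bin_range[1] < 1 || bin_range[2] > stack$n_gate_bins)
    stop("index error: bin_range must be within [1, ", stack$n_gate_bins, "]",
         call. = FALSE)

  idx <- seq(bin_range[1], bin_range[2])
  d <- dim(stack$counts)
  summed <- array(0, d[1:3])
  for (b in idx) summed <- summed + array(stack$counts[, , , b], d[1:3])
  out <- stack
  out$counts <- array(as.integer(summed), c(d[1:3], 1L))
  out$n_gate_bins <- 1L
  out$bin_duration <- length(idx) * stack$bin_duration
  out
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("projection_stack: %d x %d pixels, %d views, %d bin(s) of %.2f s\n",
              d[1], d[2], d[3], d[4], x$bin_duration))
  cat(sprintf("  total counts %.0f (seed %s)\n", sum(x$counts),
              format(x$noise_seed)))
  invisible(x)
}
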