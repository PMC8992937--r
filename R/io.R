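#' Write / read a volume as NIfTI-1 with a JSON provenance sidecar
#'
#' Voxel sizes are carried in the NIfTI header (mm); reconstruction
#' provenance (iterations, subsets, post-filter, duration, seed) goes to
#' `<path>.json`.
#'
#' @param vol A [recon_volume][osem()], [voxelize_phantom()] activity/mu
#'   array, or plain 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel size in mm (taken from the object if present).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = NULL) {
  arr <- if (inherits(vol, "recon_volume")) vol$values else vol
  vs <- voxel_size %||%
    (if (inherits(vol, "recon_volume")) vol$voxel_size else 1)
  img <- RNifti::asNifti(arr, list(pixdim = c(-1, vs, vs, vs, 0, 0, 0, 0)),
                         datatype = "float")
  RNifti::writeNifti(img, path)
  side <- list(voxel_size_mm = vs)
  if (inherits(vol, "recon_volume")) {
    side <- c(side, list(iterations = vol$params$n_iterations,
                         subsets = vol$params$n_subsets,
                         postfilter_fwhm_mm = vol$params$postfilter_fwhm,
                         duration_s = vol$duration,
                         noise_seed = vol$noise_seed))
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  list(values = arr, voxel_size = RNifti::pixdim(img)[1], provenance = side)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a gated projection stack
#'
#' Counts go to a 4-D NIfTI-1 file (transaxial, axial, view, bin);
#' geometry and gating metadata go to `<path>.json`.
#'
#' @param stack A [simulate_gated_acquisition()] stack.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_projections <- function(stack, path) {
  stopifnot(inherits(stack, "projection_stack"))
  img <- RNifti::asNifti(stack$counts + 0, datatype = "float")
  RNifti::writeNifti(img, path)
  g <- stack$geometry
  meta <- list(
    n_views_per_head = g$n_views_per_head, n_heads = g$n_heads,
    arc = g$arc, matrix_dim = g$matrix_dim, pixel_size = g$pixel_size,
    orbit_radius = g$orbit_radius, time_per_view = stack$time_per_view,
    collimator = as.list(g$collimator),
    n_gate_bins = stack$n_gate_bins, bin_duration = stack$bin_duration,
    voxel_size = stack$voxel_size, sensitivity = stack$sensitivity,
    model_flags = stack$model_flags, noise_seed = stack$noise_seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- acq_geometry(n_views_per_head = meta$n_views_per_head,
                       n_heads = meta$n_heads, arc = meta$arc,
                       matrix_dim = meta$matrix_dim,
                       pixel_size = meta$pixel_size,
                       orbit_radius = meta$orbit_radius,
                       time_per_view = meta$time_per_view,
                       collimator = unlist(meta$collimator))
  structure(list(counts = array(as.integer(round(img)), dim = dim(img)),
                 geometry = geom,
                 n_gate_bins = meta$n_gate_bins,
                 bin_duration = meta$bin_duration,
                 time_per_view = meta$time_per_view,
                 voxel_size = meta$voxel_size,
                 sensitivity = meta$sensitivity,
                 model_flags = meta$model_flags,
                 noise_seed = meta$noise_seed),
            class = "projection_stack")
}

#' Write / read an ROI layout as JSON
#'
#' @param layout A [build_roi_layout()] result.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "roi_layout"))
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  l$sphere_centers <- matrix(unlist(l$sphere_centers), ncol = 2,
                             dimnames = list(NULL, c("x", "y")))
  l$background_positions <- matrix(unlist(l$background_positions), ncol = 2)
  structure(l, class = "roi_layout")
}

#' Write / read a sweep metrics table as CSV (RFC 4180)
#'
#' @param tab A [run_parameter_sweep()] table (or any data.frame).
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  tab <- read.csv(path)
  class(tab) <- c("sweep_table", class(tab))
  tab
}

#' Pivot a sweep table into the wide CNR-by-iteration layout
#'
#' One row per iteration count, one column per (duration, sphere), the
#' layout used to tabulate CNR against iteration number at each
#' acquisition time.
#'
#' @param tab A sweep table filtered to one post-filter width (and seed,
#'   or pre-averaged across seeds).
#' @param value Metric column to tabulate (default `"CNR"`).
#' @return A wide data.frame.
#' @export
sweep_wide_table <- function(tab, value = "CNR") {
  tab <- as.data.frame(tab)
  if (length(unique(tab$fwhm_mm)) > 1)
    stop("filter the table to a single fwhm before pivoting", call. = FALSE)
  agg <- stats::aggregate(tab[[value]],
                          by = list(iterations = tab$iterations,
                                    duration_s = tab$duration_s,
                                    sphere_mm = tab$sphere_mm), FUN = mean)
  its <- sort(unique(tab$iterations))
  durs <- sort(unique(tab$duration_s))
  sph <- sort(unique(tab$sphere_mm))
  out <- data.frame(iterations = its)
  for (d in durs) for (s in sph) {
    v <- vapply(its, function(it) {
      m <- agg$x[agg$iterations == it & agg$duration_s == d &
                   agg$sphere_mm == s]
      if (length(m)) m else NA_real_
    }, numeric(1))
    out[[sprintf("%s_%gs_%gmm", value, d, s)]] <- v
  }
  out
}
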