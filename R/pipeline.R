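#' Default end-to-end pipeline configuration
#'
#' Nested sections for the phantom, acquisition, reconstruction, analysis
#' and sweep stages, with every default of the study protocol. Unknown
#' keys are rejected at validation time.
#'
#' @return A named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    schema_version = 1L,
    phantom = list(
      sphere_diameters_mm = c(37, 28, 22, 17, 13, 10),
      total_activity_MBq = 214.2,
      stock_volume_ml = 1200,
      background_volume_ml = 9787,
      body_semiaxes_mm = c(150, 115),
      body_length_mm = 180,
      mu_water_per_cm = 0.154,
      lung_insert = FALSE,
      voxel_size_mm = 4.8,
      grid_shape = c(128, 128, 128),
      supersampling = 4L
    ),
    acquisition = list(
      n_views_per_head = 60L,
      n_heads = 2L,
      arc_deg = 360,
      orbit_radius_mm = 250,
      time_per_view_s = 15,
      n_gate_bins = 15L,
      collimator_fwhm_intercept_mm = 4,
      collimator_fwhm_slope = 0.05,
      total_counts = 1e6,
      seed = 1L
    ),
    recon = list(
      subsets = 8L,
      attenuation = TRUE,
      resolution_recovery = TRUE
    ),
    sweep = list(
      durations_s = c(3, 8, 15),
      iteration_grid = seq(4L, 24L, by = 4L),
      fwhm_grid_mm = c(0, 4, 8, 12),
      seeds = 1L,
      convergence_threshold_pct = 3.5
    )
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Merges the user configuration over [default_pipeline_config()],
#' rejecting unknown sections or keys and checking cross-field
#' constraints (e.g. the subset count must divide the number of
#' projections).
#'
#' @param config Partial configuration list (e.g. from
#'   [yaml::read_yaml()]), or `NULL` for the defaults.
#' @return The validated, fully populated `pipeline_config`.
#' @export
validate_pipeline_config <- function(config = NULL) {
  def <- default_pipeline_config()
  if (is.null(config)) return(def)
  config <- unclass(config)

  bad <- setdiff(names(config), names(def))
  if (length(bad))
    stop("configuration error: unknown section(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (sec in names(config)) {
    if (is.list(def[[sec]])) {
      badk <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(badk))
        stop("configuration error: unknown key(s) in ", sec, ": ",
             paste(badk, collapse = ", "), call. = FALSE)
      def[[sec]] <- modifyList(def[[sec]], config[[sec]])
    } else def[[sec]] <- config[[sec]]
  }

  n_proj <- def$acquisition$n_views_per_head * def$acquisition$n_heads
  if (n_proj %% def$recon$subsets != 0)
    stop("configuration error: subset count (", def$recon$subsets,
         ") does not divide the number of projections (", n_proj, ")",
         call. = FALSE)
  bin_dur <- def$acquisition$time_per_view_s / def$acquisition$n_gate_bins
  k <- def$sweep$durations_s / bin_dur
  if (any(abs(k - round(k)) > 1e-9) || any(k > def$acquisition$n_gate_bins))
    stop("configuration error: sweep durations not achievable from ",
         def$acquisition$n_gate_bins, " gate bins of ", bin_dur, " s",
         call. = FALSE)
  class(def) <- "pipeline_config"
  def
}

.log_stage <- function(quiet, stage, ...) {
  if (!quiet)
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(..., collapse = "")))
}

#' Run the full phantom-to-metrics pipeline
#'
#' Executes phantom voxelization, noise-free projection, count-level
#' calibration, gated Poisson acquisition, bin re-summing, the OSEM
#' parameter sweep and NEMA metric evaluation, writing every artifact
#' (NIfTI volumes, projections, layout JSON, tidy and wide CSV tables)
#' plus a manifest with MD5 checksums to `out_dir`.
#'
#' @param config A (partial) configuration list, a path to a YAML file,
#'   or `NULL` for defaults; validated by [validate_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, the manifest data.frame (file, md5); also written
#'   as `manifest.json`.
#' @export
run_pipeline <- function(config = NULL, out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1 && file.exists(config))
    config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  t0 <- Sys.time()
  .log_stage(quiet, "phantom", "voxelizing at ",
             paste(cfg$phantom$grid_shape, collapse = "x"))
  ph <- cfg$phantom
  spec <- phantom_spec(sphere_diameters = ph$sphere_diameters_mm,
                       body_semiaxes = ph$body_semiaxes_mm,
                       body_length = ph$body_length_mm,
                       fill_plan = compute_fill_plan(ph$total_activity_MBq,
                                                     ph$stock_volume_ml,
                                                     ph$sphere_diameters_mm,
                                                     ph$background_volume_ml),
                       mu_water = ph$mu_water_per_cm,
                       lung_insert = ph$lung_insert)
  vox <- voxelize_phantom(spec, ph$voxel_size_mm, ph$grid_shape,
                          ph$supersampling)
  write_volume(vox$activity, file.path(out_dir, "phantom_activity.nii"),
               voxel_size = ph$voxel_size_mm)
  write_volume(vox$mu_map, file.path(out_dir, "phantom_mu.nii"),
               voxel_size = ph$voxel_size_mm)

  aq <- cfg$acquisition
  .log_stage(quiet, "simulate", "projecting ", aq$n_views_per_head * aq$n_heads,
             " views, seed ", aq$seed)
  geom <- acq_geometry(n_views_per_head = aq$n_views_per_head,
                       n_heads = aq$n_heads, arc = aq$arc_deg,
                       matrix_dim = c(ph$grid_shape[1], ph$grid_shape[3]),
                       pixel_size = ph$voxel_size_mm,
                       orbit_radius = aq$orbit_radius_mm,
                       time_per_view = aq$time_per_view_s,
                       collimator = c(fwhm_intercept = aq$collimator_fwhm_intercept_mm,
                                      fwhm_slope = aq$collimator_fwhm_slope))
  nf <- forward_project(vox, geom)
  nf <- calibrate_sensitivity(nf, aq$total_counts)
  stack <- simulate_gated_acquisition(nf, aq$n_gate_bins, seed = aq$seed)
  write_projections(stack, file.path(out_dir, "projections.nii"))

  .log_stage(quiet, "analyze", "building ROI layout")
  layout <- build_roi_layout(spec, ph$grid_shape, ph$voxel_size_mm)
  write_layout_json(layout, file.path(out_dir, "roi_layout.json"))

  sw <- cfg$sweep
  scfg <- sweep_config(durations = sw$durations_s,
                       iteration_grid = sw$iteration_grid,
                       subsets = cfg$recon$subsets,
                       fwhm_grid = sw$fwhm_grid_mm,
                       seeds = sw$seeds,
                       convergence_threshold = sw$convergence_threshold_pct)
  .log_stage(quiet, "sweep", length(scfg$seeds), " seed(s) x ",
             length(scfg$durations), " durations x ",
             length(scfg$iteration_grid), " iteration counts x ",
             length(scfg$fwhm_grid), " filters")
  tab <- run_parameter_sweep(vox, nf, scfg, layout = layout)
  write_sweep_csv(tab, file.path(out_dir, "metrics.csv"))
  ref_fw <- if (8 %in% scfg$fwhm_grid) 8 else scfg$fwhm_grid[1]
  wide <- sweep_wide_table(tab[tab$fwhm_mm == ref_fw, ], "CNR")
  write.csv(wide, file.path(out_dir, "cnr_by_iteration.csv"), row.names = FALSE)

  .log_stage(quiet, "report", "convergence detection")
  conv <- do.call(rbind, lapply(split(tab[tab$fwhm_mm == ref_fw, ],
                                      interaction(tab[tab$fwhm_mm == ref_fw, ]$duration_s,
                                                  tab[tab$fwhm_mm == ref_fw, ]$sphere_mm,
                                                  drop = TRUE)),
                                function(g) {
    g <- stats::aggregate(RC ~ iterations, data = g, FUN = mean)
    data.frame(duration_s = NA, sphere_mm = NA,
               converged_at = tryCatch(
                 detect_convergence(g$RC[order(g$iterations)],
                                    sort(g$iterations),
                                    scfg$convergence_threshold),
                 error = function(e) NA_integer_))
  }))
  keys <- do.call(rbind, strsplit(rownames(conv), ".", fixed = TRUE))
  conv$duration_s <- as.numeric(keys[, 1])
  conv$sphere_mm <- as.numeric(keys[, 2])
  write.csv(conv[order(conv$duration_s, -conv$sphere_mm), ],
            file.path(out_dir, "convergence.csv"), row.names = FALSE)

  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         row.names = NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage(quiet, "done", sprintf("%.1f s elapsed",
                                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(manifest)
}
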