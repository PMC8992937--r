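#' Configuration of the acquisition-time / reconstruction-parameter sweep
#'
#' Defaults reproduce the study grid: effective acquisition times of 3, 8
#' and 15 s/view (nested partial sums of one 15-bin gated scan), 4-24
#' OSEM iterations in steps of 4, eight subsets, and 0-12 mm Gaussian
#' post-filters. Contrast-recovery convergence is declared when the
#' relative change between successive grid iterations stays below 3.5%.
#'
#' @param durations Effective seconds per view to analyse.
#' @param iteration_grid OSEM iteration counts.
#' @param subsets Subset count.
#' @param fwhm_grid Post-filter FWHMs in mm.
#' @param seeds Integer seeds; each seed is an independent gated
#'   acquisition realisation (all durations within a seed share it).
#' @param convergence_threshold Percent relative-change threshold.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(durations = c(3, 8, 15),
                         iteration_grid = seq(4, 24, by = 4),
                         subsets = 8,
                         fwhm_grid = c(0, 4, 8, 12),
                         seeds = 1L,
                         convergence_threshold = 3.5) {
  stopifnot(length(durations) > 0, length(iteration_grid) > 0,
            length(fwhm_grid) > 0, length(seeds) > 0)
  .check_positive(durations, "durations")
  .check_positive(iteration_grid, "iteration_grid")
  .check_positive(subsets, "subsets")
  if (any(fwhm_grid < 0))
    stop("invalid parameter: fwhm_grid must be >= 0", call. = FALSE)
  .check_positive(convergence_threshold, "convergence_threshold")
  structure(list(durations = sort(durations),
                 iteration_grid = sort(as.integer(iteration_grid)),
                 subsets = as.integer(subsets),
                 fwhm_grid = sort(fwhm_grid),
                 seeds = as.integer(seeds),
                 convergence_threshold = convergence_threshold),
            class = "sweep_config")
}

#' Run the full acquisition-time / reconstruction-parameter sweep
#'
#' For each seed, a gated acquisition is realised (or the supplied stack
#' reused), partial bin sums give each duration, a single warm-started
#' OSEM run per duration provides every grid iteration count as a
#' snapshot, each snapshot is post-filtered at every FWHM, and the NEMA
#' metrics are evaluated per sphere. The 3/8/15 s datasets within a seed
#' are nested subsets of one acquisition, exactly as in a gated
#' time-resampling experiment.
#'
#' @param vox The [voxelize_phantom()] ground truth (supplies `mu_map`
#'   and the true concentration ratio).
#' @param x Either a noise-free [forward_project()] result (gated stacks
#'   are then simulated per seed in `config$seeds`) or a single
#'   [simulate_gated_acquisition()] stack (its own seed is used).
#' @param config A [sweep_config()].
#' @param layout Optional pre-built [build_roi_layout()]; computed from
#'   `vox` by default.
#' @param warm_start Reuse one OSEM run per duration for all iteration
#'   counts (valid because OSEM iterations compose); set `FALSE` to
#'   reconstruct each cell independently for audit.
#' @return A `sweep_table`: tidy data.frame with one row per
#'   (seed, duration, iterations, fwhm, sphere). Failed cells are kept
#'   with `failed = TRUE`.
#' @export
run_parameter_sweep <- function(vox, x, config = sweep_config(),
                                layout = NULL, warm_start = TRUE) {
  stopifnot(inherits(vox, "voxel_phantom"))
  if (is.null(layout))
    layout <- build_roi_layout(vox$spec, dim(vox$activity), vox$voxel_size)
  R <- vox$spec$fill_plan$ratio_R

  if (inherits(x, "projection_stack")) {
    stacks <- list(x)
    seeds <- x$noise_seed
  } else if (inherits(x, "projection_set")) {
    seeds <- config$seeds
    stacks <- lapply(seeds, function(sd)
      simulate_gated_acquisition(x, n_gate_bins = 15, seed = sd))
  } else stop("x must be a projection_set or projection_stack", call. = FALSE)

  bin_dur <- stacks[[1]]$bin_duration
  n_bins_needed <- config$durations / bin_dur
  if (any(abs(n_bins_needed - round(n_bins_needed)) > 1e-9) ||
      any(n_bins_needed > stacks[[1]]$n_gate_bins))
    stop("configuration error: durations not achievable from the gated stack",
         call. = FALSE)

  rows <- list()
  any_failed <- FALSE
  for (si in seq_along(stacks)) {
    stack <- stacks[[si]]
    for (dur in config$durations) {
      summed <- sum_bins(stack, c(1, round(dur / bin_dur)))
      res <- tryCatch({
        max_it <- max(config$iteration_grid)
        prm <- recon_params(n_iterations = max_it, n_subsets = config$subsets,
                            postfilter_fwhm = 0)
        if (warm_start) {
          run <- osem(summed, vox$mu_map, prm, snapshots = config$iteration_grid)
          vols <- run$snapshots
        } else {
          vols <- lapply(config$iteration_grid, function(it) {
            p <- prm; p$n_iterations <- as.integer(it)
            osem(summed, vox$mu_map, p)
          })
          names(vols) <- as.character(config$iteration_grid)
        }
        do.call(rbind, lapply(names(vols), function(itn) {
          do.call(rbind, lapply(config$fwhm_grid, function(fw) {
            m <- evaluate_volume(gaussian_postfilter_3d(vols[[itn]], fw),
                                 layout, R)
            m$seed <- seeds[si]
            m
          }))
        }))
      }, error = function(e) {
        warning("sweep cell failed (seed ", seeds[si], ", ", dur, " s): ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) { any_failed <- TRUE; next }
      rows[[length(rows) + 1]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "failed_cells") <- any_failed
  attr(tab, "config") <- config
  class(tab) <- c("sweep_table", class(tab))
  tab
}

#' Summarise a sweep table across seeds
#'
#' @param tab A [run_parameter_sweep()] table.
#' @return Mean and SD of RC, BV and CNR per
#'   (duration, iterations, fwhm, sphere) cell.
#' @export
summarize_sweep <- function(tab) {
  key <- interaction(tab$duration_s, tab$iterations, tab$fwhm_mm,
                     tab$sphere_mm, drop = TRUE)
  agg <- function(f) do.call(rbind, lapply(split(tab, key), function(g) {
    data.frame(duration_s = g$duration_s[1], iterations = g$iterations[1],
               fwhm_mm = g$fwhm_mm[1], sphere_mm = g$sphere_mm[1],
               n_seeds = nrow(g),
               RC = f(g$RC), BV = f(g$BV), CNR = f(g$CNR))
  }))
  m <- agg(mean); s <- agg(sd)
  names(m)[6:8] <- c("RC_mean", "BV_mean", "CNR_mean")
  m$RC_sd <- s$RC; m$BV_sd <- s$BV; m$CNR_sd <- s$CNR
  rownames(m) <- NULL
  m[order(m$duration_s, m$iterations, m$fwhm_mm, -m$sphere_mm), ]
}

#' Detect contrast-recovery convergence on an iteration grid
#'
#' Returns the smallest grid iteration from which every subsequent
#' relative change `|RC(i+1) - RC(i)| / RC(i)` stays below
#' `threshold` percent, or `NA` ("not converged") if none does. A
#' constant series converges at the first grid point.
#'
#' @param rc Contrast-recovery values sampled at increasing iteration
#'   counts.
#' @param iterations The iteration grid (same length as `rc`).
#' @param threshold Percent threshold (default 3.5).
#' @return The converging iteration count, or `NA_integer_`.
#' @export
detect_convergence <- function(rc, iterations, threshold = 3.5) {
  stopifnot(length(rc) == length(iterations), length(rc) >= 2,
            !is.unsorted(iterations, strictly = TRUE))
  .check_positive(threshold, "threshold")
  n <- length(rc)
  denom <- rc[-n]
  if (any(denom == 0))
    stop("undefined-relative-change: RC is zero in the series", call. = FALSE)
  rel <- abs(rc[-1] - denom) / denom
  for (m in seq_len(n - 1)) {
    if (all(rel[m:(n - 1)] < threshold / 100)) return(as.integer(iterations[m]))
  }
  NA_integer_
}
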