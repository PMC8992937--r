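#' OSEM reconstruction parameters
#'
#' @param n_iterations Full passes over all subsets (the study grid is
#'   4-24).
#' @param n_subsets Ordered subsets; must divide the number of
#'   projections (8 in the study).
#' @param postfilter_fwhm Post-reconstruction 3D Gaussian filter FWHM in
#'   mm (0 disables; 0-12 in the study).
#' @param attenuation,resolution_recovery System-model switches: include
#'   Beer-Lambert attenuation and/or the distance-dependent collimator
#'   blur in forward and backprojection.
#' @return An object of class `recon_params`.
#' @export
recon_params <- function(n_iterations = 12, n_subsets = 8,
                         postfilter_fwhm = 8, attenuation = TRUE,
                         resolution_recovery = TRUE) {
  n_iterations <- as.integer(n_iterations)
  n_subsets <- as.integer(n_subsets)
  stopifnot(n_iterations >= 1, n_subsets >= 1)
  if (postfilter_fwhm < 0)
    stop("invalid parameter: postfilter_fwhm must be >= 0", call. = FALSE)
  structure(list(n_iterations = n_iterations, n_subsets = n_subsets,
                 postfilter_fwhm = postfilter_fwhm,
                 attenuation = attenuation,
                 resolution_recovery = resolution_recovery),
            class = "recon_params")
}

# Views assigned to subsets by stride (view i -> subset i mod n), which
# maximises the angular spread within each subset; subsets are visited in
# index order.
.subset_views <- function(n_views, n_subsets) {
  if (n_views %% n_subsets != 0)
    stop("configuration error: subset count (", n_subsets,
         ") must divide the number of projections (", n_views, ")",
         call. = FALSE)
  lapply(seq_len(n_subsets), function(s) seq(s, n_views, by = n_subsets))
}

# Shared system-model pieces for a reconstruction: per-view angles,
# transmissions and blur sigmas. Reused across warm-started runs.
.recon_system <- function(stack, mu_map, params) {
  geom <- stack$geometry
  ny <- if (!is.null(mu_map)) dim(mu_map)[2] else dim(stack$counts)[1]
  sig <- .plane_blur_deltas(geom, ny, stack$voxel_size)
  Tv <- NULL
  if (params$attenuation) {
    if (is.null(mu_map))
      stop("configuration error: attenuation correction requested but no ",
           "mu_map supplied", call. = FALSE)
    Tv <- .view_transmissions(mu_map, geom, stack$voxel_size)
  }
  list(theta = geom$view_angles_deg * pi / 180, Tv = Tv, sigmas = sig, ny = ny)
}

#' 3D OSEM reconstruction with resolution recovery and attenuation
#'
#' Classic multiplicative OSEM: for each subset S the estimate is updated
#' as `x <- x * backproject_S(y_S / forward_S(x)) / backproject_S(1)`.
#' The forward model is identical to the acquisition simulator's projector
#' (matched-model reconstruction): distance-dependent Gaussian collimator
#' blur when `resolution_recovery` is on and Beer-Lambert attenuation from
#' `mu_map` when `attenuation` is on. Ratios where the forward projection
#' is below a small guard are set to 0, and voxels with zero subset
#' sensitivity stay 0, so non-negativity is preserved throughout.
#'
#' @param stack A [projection_stack][simulate_gated_acquisition()] with a
#'   single (summed) bin.
#' @param mu_map Attenuation map (1/cm) on the reconstruction grid, or
#'   `NULL` when `attenuation` is off.
#' @param params A [recon_params()].
#' @param snapshots Optional integer vector of iteration numbers at which
#'   to record intermediate volumes (used by the parameter sweep to
#'   warm-start the iteration grid from one run).
#' @param sensitivity Projector sensitivity used in the system model; the
#'   default (1) reconstructs in arbitrary units proportional to activity
#'   concentration, which the ratio-based NEMA metrics do not depend on.
#' @return An object of class `recon_volume` (unfiltered); if `snapshots`
#'   is given, field `snapshots` holds a named list of intermediate
#'   `recon_volume`s.
#' @export
osem <- function(stack, mu_map = NULL, params = recon_params(),
                 snapshots = NULL, sensitivity = 1) {
  stopifnot(inherits(stack, "projection_stack"))
  if (dim(stack$counts)[4] != 1)
    stop("osem expects a single summed bin; see sum_bins()", call. = FALSE)
  geom <- stack$geometry
  subsets <- .subset_views(geom$n_projections, params$n_subsets)
  sys <- .recon_system(stack, mu_map, params)

  nx <- dim(stack$counts)[1]; nz <- dim(stack$counts)[2]; ny <- sys$ny
  y <- stack$counts[, , , 1]
  if (sum(y) == 0) {
    warning("all-zero projections: returning zero volume")
    vol <- .new_volume(array(0, c(nx, ny, nz)), stack, params)
    return(vol)
  }

  # uniform start inside a cylindrical support mask
  coords_x <- .axis_coords(nx, stack$voxel_size)
  coords_y <- .axis_coords(ny, stack$voxel_size)
  r_support <- (min(nx, ny) / 2 - 1) * stack$voxel_size
  mask <- array(0, c(nx, ny, nz))
  mask[] <- outer(coords_x^2, coords_y^2, "+") <= r_support^2
  x <- mask * 1.0

  use_att <- params$attenuation
  use_blur <- params$resolution_recovery
  null_T <- .null_cube

  # per-subset sensitivity images, independent of the data
  ones <- matrix(1, nx, nz)
  sens_img <- lapply(subsets, function(vs) {
    s <- array(0, c(nx, ny, nz))
    for (v in vs)
      s <- s + cpp_bp_view(ones, sys$theta[v],
                           if (use_att) sys$Tv[[v]] else null_T, use_att,
                           sys$sigmas, use_blur, sensitivity, ny)
    s
  })

  eps_rel <- 1e-12
  snaps <- list()
  for (it in seq_len(params$n_iterations)) {
    for (s in seq_along(subsets)) {
      vs <- subsets[[s]]
      bp <- array(0, c(nx, ny, nz))
      for (v in vs) {
        fp <- cpp_fp_view(x, sys$theta[v],
                          if (use_att) sys$Tv[[v]] else null_T, use_att,
                          sys$sigmas, use_blur, sensitivity)
        guard <- eps_rel * max(mean(fp), .Machine$double.xmin)
        ratio <- y[, , v] / fp
        ratio[fp <= guard] <- 0
        bp <- bp + cpp_bp_view(ratio, sys$theta[v],
                               if (use_att) sys$Tv[[v]] else null_T, use_att,
                               sys$sigmas, use_blur, sensitivity, ny)
      }
      upd <- bp / sens_img[[s]]
      upd[sens_img[[s]] <= 0] <- 0
      x <- x * upd
    }
    if (it %in% snapshots) {
      p <- params; p$n_iterations <- it
      snaps[[as.character(it)]] <- .new_volume(x, stack, p)
    }
  }
  vol <- .new_volume(x, stack, params)
  if (length(snaps)) vol$snapshots <- snaps
  vol
}

.new_volume <- function(values, stack, params) {
  structure(list(values = values, voxel_size = stack$voxel_size,
                 params = params, duration = stack$bin_duration,
                 noise_seed = stack$noise_seed),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "recon_volume: %d x %d x %d @ %.2f mm | %d it x %d ss, %.3g mm filter, %.1f s/view\n",
    d[1], d[2], d[3], x$voxel_size, x$params$n_iterations,
    x$params$n_subsets, x$params$postfilter_fwhm, x$duration))
  invisible(x)
}

#' Isotropic 3D Gaussian post-filter
#'
#' Convolves the volume with an isotropic Gaussian of the given FWHM
#' (sigma = FWHM / (2 sqrt(2 ln 2)) converted to voxels). `fwhm = 0`
#' returns the input unchanged. The truncated kernel is renormalised at
#' the grid edges so interior sums are preserved.
#'
#' @param vol A [recon_volume][osem()] (or plain 3D array).
#' @param fwhm Filter FWHM in mm.
#' @return Filtered volume of the same class as the input.
#' @export
gaussian_postfilter_3d <- function(vol, fwhm) {
  if (!is.numeric(fwhm) || length(fwhm) != 1 || is.na(fwhm) || fwhm < 0)
    stop("invalid parameter: fwhm must be a single number >= 0", call. = FALSE)
  arr <- if (inherits(vol, "recon_volume")) vol$values else vol
  vs <- if (inherits(vol, "recon_volume")) vol$voxel_size else 1
  if (fwhm == 0) {
    out <- arr
  } else {
    out <- cpp_gauss3d(arr, .fwhm_to_sigma(fwhm) / vs)
  }
  if (inherits(vol, "recon_volume")) {
    vol$values <- out
    vol$params$postfilter_fwhm <- fwhm
    vol
  } else out
}

#' Poisson log-likelihood of projections under a reconstructed volume
#'
#' `sum(y * log(yhat) - yhat)` over all views (terms with `y = 0` and
#' `yhat = 0` contribute 0). Used to check the EM monotonicity property.
#'
#' @param x Volume array (or `recon_volume`).
#' @param stack Single-bin projection stack.
#' @param mu_map,params,sensitivity As in [osem()].
#' @return Scalar log-likelihood (additive constants dropped).
#' @export
osem_loglik <- function(x, stack, mu_map = NULL, params = recon_params(),
                        sensitivity = 1) {
  arr <- if (inherits(x, "recon_volume")) x$values else x
  sys <- .recon_system(stack, mu_map, params)
  y <- stack$counts[, , , 1]
  ll <- 0
  for (v in seq_len(stack$geometry$n_projections)) {
    fp <- cpp_fp_view(arr, sys$theta[v],
                      if (params$attenuation) sys$Tv[[v]] else .null_cube,
                      params$attenuation, sys$sigmas,
                      params$resolution_recovery, sensitivity)
    yv <- y[, , v]
    pos <- fp > 0
    ll <- ll + sum(yv[pos] * log(fp[pos]) - fp[pos])
    if (any(yv[!pos] > 0)) ll <- -Inf
  }
  ll
}

#' Total forward-projected counts of a volume under the system model
#'
#' @inheritParams osem_loglik
#' @return Scalar: `sum(forward(x))`.
#' @export
osem_projected_total <- function(x, stack, mu_map = NULL,
                                 params = recon_params(), sensitivity = 1) {
  arr <- if (inherits(x, "recon_volume")) x$values else x
  sys <- .recon_system(stack, mu_map, params)
  tot <- 0
  for (v in seq_len(stack$geometry$n_projections)) {
    tot <- tot + sum(cpp_fp_view(arr, sys$theta[v],
                                 if (params$attenuation) sys$Tv[[v]] else .null_cube,
                                 params$attenuation, sys$sigmas,
                                 params$resolution_recovery, sensitivity))
  }
  tot
}

#' OSEM/MLEM on an explicit system matrix
#'
#' Reference implementation of the same multiplicative update for a dense
#' system matrix `A` (rows = measurements, columns = voxels), used for toy
#' systems where the update can be verified by hand. With
#' `n_subsets = 1` this is plain MLEM.
#'
#' @param y Measurement vector.
#' @param A Dense system matrix.
#' @param n_iterations Full passes over all subsets.
#' @param n_subsets Rows are assigned to subsets by stride.
#' @param x0 Starting estimate (default uniform 1).
#' @return Estimate vector after `n_iterations` passes.
#' @export
osem_matrix <- function(y, A, n_iterations = 1, n_subsets = 1,
                        x0 = rep(1, ncol(A))) {
  stopifnot(length(y) == nrow(A), length(x0) == ncol(A))
  if (nrow(A) %% n_subsets != 0)
    stop("configuration error: subset count must divide the number of rows",
         call. = FALSE)
  rows <- lapply(seq_len(n_subsets), function(s) seq(s, nrow(A), by = n_subsets))
  x <- as.numeric(x0)
  for (it in seq_len(n_iterations)) {
    for (rs in rows) {
      As <- A[rs, , drop = FALSE]
      fp <- as.numeric(As %*% x)
      ratio <- ifelse(fp > 0, y[rs] / fp, 0)
      sens <- as.numeric(crossprod(As, rep(1, length(rs))))
      upd <- as.numeric(crossprod(As, ratio)) / sens
      upd[sens <= 0] <- 0
      x <- x * upd
    }
  }
  x
}
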