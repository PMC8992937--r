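#' NEMA NU 2-2018 style ROI layout for the IEC phantom
#'
#' Places one circular ROI per hot sphere (diameter equal to the sphere's
#' internal diameter) on the central slice through the sphere centres, and
#' finds 12 background positions for 37 mm ROIs by a deterministic greedy
#' search on a polar candidate grid. Background ROIs must keep their edge
#' at least `margin` mm from the phantom outline and from every hot
#' sphere, and must not overlap each other. Concentric smaller ROIs (one
#' per sphere diameter) share each background centre; replicated over the
#' central slice and two slices on each side, this yields 60 background
#' ROIs per diameter.
#'
#' @param spec A [phantom_spec()].
#' @param grid_shape 3-vector of volume grid dimensions.
#' @param voxel_size Voxel size in mm.
#' @param margin Clearance in mm between ROI edge and phantom margin /
#'   sphere surface (15 per the standard).
#' @param slice_offsets Index offsets of the analysis slices around the
#'   central slice.
#' @return An object of class `roi_layout`.
#' @export
build_roi_layout <- function(spec, grid_shape, voxel_size = 4.8,
                             margin = 15, slice_offsets = c(-2, -1, 0, 1, 2)) {
  stopifnot(inherits(spec, "phantom_spec"))
  coords_z <- .axis_coords(grid_shape[3], voxel_size)
  central <- which.min(abs(coords_z - spec$sphere_centers[1, "z"]))
  slices <- central + slice_offsets
  if (any(slices < 1 | slices > grid_shape[3]))
    stop("layout-infeasible: analysis slices fall outside the grid",
         call. = FALSE)

  diam <- spec$sphere_diameters
  roi_big <- max(diam)  # 37 mm background ROI carries the concentric set
  r_big <- roi_big / 2

  # dense elliptical boundary polyline for margin distances
  tt <- seq(0, 2 * pi, length.out = 1441)[-1441]
  bx <- spec$body_semiaxes[1] * cos(tt)
  by <- spec$body_semiaxes[2] * sin(tt)

  ok_position <- function(p) {
    if ((p[1] / spec$body_semiaxes[1])^2 +
        (p[2] / spec$body_semiaxes[2])^2 >= 1) return(FALSE)
    if (min(sqrt((bx - p[1])^2 + (by - p[2])^2)) < margin + r_big) return(FALSE)
    ds <- sqrt((spec$sphere_centers[, "x"] - p[1])^2 +
                 (spec$sphere_centers[, "y"] - p[2])^2)
    all(ds >= margin + r_big + diam / 2)
  }

  # deterministic candidate lattice (2 mm), tried boundary-hugging
  # positions first (largest normalised elliptical radius) as in the
  # standard layout where background ROIs ring the cavity edge; ties
  # broken by angle
  gx <- seq(-spec$body_semiaxes[1], spec$body_semiaxes[1], by = 2)
  gy <- seq(-spec$body_semiaxes[2], spec$body_semiaxes[2], by = 2)
  cand <- as.matrix(expand.grid(gx, gy))
  erad <- (cand[, 1] / spec$body_semiaxes[1])^2 +
    (cand[, 2] / spec$body_semiaxes[2])^2
  keep <- erad < 1
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(-erad[keep], atan2(cand[, 2], cand[, 1])), , drop = FALSE]

  picked <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (!ok_position(p)) next
    if (nrow(picked) &&
        min(sqrt((picked[, 1] - p[1])^2 + (picked[, 2] - p[2])^2)) < roi_big)
      next
    picked <- rbind(picked, p)
    if (nrow(picked) == 12) break
  }
  if (nrow(picked) < 12)
    stop("layout-infeasible: only ", nrow(picked),
         " valid background positions found (need 12)", call. = FALSE)

  structure(list(
    central_slice = central,
    analysis_slices = slices,
    sphere_centers = spec$sphere_centers[, c("x", "y"), drop = FALSE],
    roi_diameters = diam,
    background_positions = unname(picked),
    margin = margin,
    grid_shape = grid_shape,
    voxel_size = voxel_size,
    n_background_rois = nrow(picked) * length(slices)
  ), class = "roi_layout")
}

#' @export
print.roi_layout <- function(x, ...) {
  cat(sprintf(
    "roi_layout: central slice %d (+%d analysis slices), %d background positions\n",
    x$central_slice, length(x$analysis_slices) - 1, nrow(x$background_positions)))
  cat(sprintf("  %d background ROIs per diameter (%s mm)\n",
              x$n_background_rois, paste(x$roi_diameters, collapse = ", ")))
  invisible(x)
}

#' Mean (and pixel SD) of a circular ROI on one slice
#'
#' Default membership rule: a pixel belongs to the ROI when its centre
#' lies inside the circle. `fractional = TRUE` instead weights each pixel
#' by the supersampled (8x8) area fraction of the pixel inside the circle.
#'
#' @param slice 2D matrix of pixel values (transaxial plane).
#' @param center ROI centre `c(x, y)` in mm.
#' @param diameter ROI diameter in mm.
#' @param voxel_size Pixel size in mm.
#' @param fractional Use fractional-area weighting instead of the
#'   centre-in rule.
#' @return List with `mean`, `sd` (pixel SD, `NA` under fractional
#'   weighting) and `weight` (total pixel weight).
#' @export
roi_stats_slice <- function(slice, center, diameter, voxel_size,
                            fractional = FALSE) {
  n1 <- nrow(slice); n2 <- ncol(slice)
  cx <- .axis_coords(n1, voxel_size)
  cy <- .axis_coords(n2, voxel_size)
  r <- diameter / 2
  ix <- which(abs(cx - center[1]) <= r + voxel_size)
  iy <- which(abs(cy - center[2]) <= r + voxel_size)
  if (!length(ix) || !length(iy))
    stop("undefined-metric: ROI does not intersect the slice", call. = FALSE)

  if (!fractional) {
    d2 <- outer((cx[ix] - center[1])^2, (cy[iy] - center[2])^2, "+")
    inside <- d2 <= r^2
    vals <- slice[ix, iy, drop = FALSE][inside]
    if (!length(vals))
      stop("undefined-metric: no pixel centre inside the ROI", call. = FALSE)
    list(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
         weight = length(vals))
  } else {
    ss <- 8
    off <- ((seq_len(ss) - 0.5) / ss - 0.5) * voxel_size
    w <- matrix(0, length(ix), length(iy))
    for (a in seq_len(ss)) for (b in seq_len(ss)) {
      w <- w + (outer((cx[ix] + off[a] - center[1])^2,
                      (cy[iy] + off[b] - center[2])^2, "+") <= r^2)
    }
    w <- w / ss^2
    if (sum(w) == 0)
      stop("undefined-metric: ROI has zero area weight", call. = FALSE)
    m <- sum(w * slice[ix, iy, drop = FALSE]) / sum(w)
    list(mean = m, sd = NA_real_, weight = sum(w))
  }
}

#' Contrast recovery (percent)
#'
#' `100 * (C_H/C_B - 1) / (R - 1)`: the fraction of the true
#' sphere-to-background contrast restored in the image.
#'
#' @param C_H Mean pixel value in the sphere ROI.
#' @param C_B Mean of the background ROI means.
#' @param R True sphere-to-background activity concentration ratio.
#' @return Contrast recovery in percent (100 = perfect).
#' @export
contrast_recovery <- function(C_H, C_B, R) {
  if (!is.numeric(R) || R <= 1)
    stop("invalid parameter: R must be > 1", call. = FALSE)
  if (any(C_B == 0))
    stop("undefined-metric: C_B is zero", call. = FALSE)
  100 * (C_H / C_B - 1) / (R - 1)
}

#' Background variability (percent)
#'
#' `100 * SD / C_B`, where SD is the sample standard deviation (K - 1
#' denominator) over the K background ROI means and C_B their mean.
#'
#' @param bg_means Vector of background ROI means (K >= 2), or
#'   alternatively supply `SD` and `C_B` directly.
#' @param SD,C_B Precomputed statistics (used if `bg_means` missing).
#' @return Background variability in percent.
#' @export
background_variability <- function(bg_means = NULL, SD = NULL, C_B = NULL) {
  if (!is.null(bg_means)) {
    if (length(bg_means) < 2)
      stop("invalid parameter: need K >= 2 background ROIs", call. = FALSE)
    SD <- sd(bg_means)
    C_B <- mean(bg_means)
  }
  if (is.null(SD) || is.null(C_B))
    stop("invalid parameter: supply bg_means or both SD and C_B", call. = FALSE)
  if (C_B == 0) stop("undefined-metric: C_B is zero", call. = FALSE)
  100 * SD / C_B
}

#' Contrast-to-noise ratio and Rose visibility
#'
#' `CNR = (C_H - C_B) / SD_ROI`; an object is deemed visible when
#' `CNR > 5` (strict), the Rose criterion.
#'
#' @param C_H,C_B Sphere and background ROI means.
#' @param SD_ROI Noise term: by default the SD over the background ROI
#'   means (the only SD the standard defines).
#' @return List with `cnr` and logical `rose_visible`.
#' @export
cnr <- function(C_H, C_B, SD_ROI) {
  if (any(SD_ROI <= 0))
    stop("undefined-metric: SD_ROI must be positive", call. = FALSE)
  v <- (C_H - C_B) / SD_ROI
  list(cnr = v, rose_visible = v > 5)
}

#' Evaluate NEMA image-quality metrics on a volume
#'
#' For each sphere s: `C_H` is the mean in the sphere's ROI on the
#' central slice; `C_B` and `SD` are the mean and sample SD of the 60
#' matching-diameter background ROI means (12 positions x 5 slices); the
#' metrics are contrast recovery, background variability and CNR with
#' Rose visibility.
#'
#' @param vol A [recon_volume][osem()] or 3D array.
#' @param layout A [build_roi_layout()] result.
#' @param R True sphere-to-background concentration ratio.
#' @param fractional Membership rule passed to [roi_stats_slice()].
#' @param sd_roi_mode `"between"` (default) uses the SD across the 60
#'   background ROI means as the CNR noise term; `"within"` uses the
#'   within-ROI pixel SD averaged over the background ROIs.
#' @return A data.frame with one row per sphere: `sphere_mm`, `C_H`,
#'   `C_B`, `SD`, `RC`, `BV`, `CNR`, `rose_visible`, plus provenance
#'   columns when the input is a `recon_volume`.
#' @export
evaluate_volume <- function(vol, layout, R, fractional = FALSE,
                            sd_roi_mode = c("between", "within")) {
  sd_roi_mode <- match.arg(sd_roi_mode)
  arr <- if (inherits(vol, "recon_volume")) vol$values else vol
  stopifnot(all(dim(arr) == layout$grid_shape))
  vs <- layout$voxel_size

  out <- lapply(seq_along(layout$roi_diameters), function(s) {
    d <- layout$roi_diameters[s]
    ch <- roi_stats_slice(arr[, , layout$central_slice],
                          layout$sphere_centers[s, ], d, vs, fractional)$mean
    bg <- unlist(lapply(layout$analysis_slices, function(sl) {
      apply(layout$background_positions, 1, function(p) {
        roi_stats_slice(arr[, , sl], p, d, vs, fractional)$mean
      })
    }))
    cb <- mean(bg)
    sdv <- sd(bg)
    sd_roi <- if (sd_roi_mode == "between") sdv else {
      mean(unlist(lapply(layout$analysis_slices, function(sl) {
        apply(layout$background_positions, 1, function(p) {
          roi_stats_slice(arr[, , sl], p, d, vs, FALSE)$sd
        })
      })))
    }
    rc <- contrast_recovery(ch, cb, R)
    bv <- background_variability(SD = sdv, C_B = cb)
    cn <- if (sd_roi > 0) cnr(ch, cb, sd_roi) else
      list(cnr = NA_real_, rose_visible = NA)
    data.frame(sphere_mm = d, C_H = ch, C_B = cb, SD = sdv, K = length(bg),
               RC = rc, BV = bv, CNR = cn$cnr, rose_visible = cn$rose_visible)
  })
  res <- do.call(rbind, out)
  if (inherits(vol, "recon_volume")) {
    res$duration_s <- vol$duration
    res$iterations <- vol$params$n_iterations
    res$subsets <- vol$params$n_subsets
    res$fwhm_mm <- vol$params$postfilter_fwhm
    res$sd_roi_mode <- sd_roi_mode
  }
  res
}
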