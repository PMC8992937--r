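#' Radiochemical fill plan for the NEMA IEC body phantom
#'
#' Reproduces the bench arithmetic of preparing the phantom: a stock
#' solution of known total activity is prepared in `stock_volume` ml; the
#' six spheres are filled from it (withdrawing the sum of their internal
#' volumes); the remainder is diluted into the background compartment.
#' The sphere-to-background concentration ratio `R` therefore depends only
#' on the volumes involved, not on the total activity.
#'
#' @param total_activity Total stock activity in MBq.
#' @param stock_volume Stock solution volume in ml.
#' @param sphere_diameters Internal sphere diameters in mm (default the six
#'   NEMA IEC spheres, descending).
#' @param background_volume Final background compartment volume in ml.
#' @return An object of class `fill_plan`: concentrations in kBq/ml,
#'   volumes in ml and the concentration ratio `ratio_R`.
#' @examples
#' fp <- compute_fill_plan(214.2, 1200)
#' fp$sphere_concentration    # 178.5 kBq/ml
#' fp$background_concentration
#' fp$ratio_R                 # ~8.5
#' @export
compute_fill_plan <- function(total_activity, stock_volume,
                              sphere_diameters = c(37, 28, 22, 17, 13, 10),
                              background_volume = 9787) {
  .check_positive(total_activity, "total_activity")
  .check_positive(stock_volume, "stock_volume")
  .check_positive(sphere_diameters, "sphere_diameters")
  .check_positive(background_volume, "background_volume")

  withdrawal <- sum(sphere_volume_ml(sphere_diameters))
  if (withdrawal >= stock_volume) {
    stop("infeasible plan: sphere withdrawal volume (", round(withdrawal, 1),
         " ml) is not smaller than the stock volume", call. = FALSE)
  }
  sphere_conc <- total_activity * 1000 / stock_volume          # kBq/ml
  bg_activity <- (stock_volume - withdrawal) * sphere_conc     # kBq
  bg_conc <- bg_activity / background_volume                   # kBq/ml

  structure(list(
    total_activity = total_activity,
    stock_volume = stock_volume,
    sphere_withdrawal_volume = withdrawal,
    background_compartment_volume = background_volume,
    sphere_concentration = sphere_conc,
    background_concentration = bg_conc,
    ratio_R = sphere_conc / bg_conc
  ), class = "fill_plan")
}

#' Internal volume of a sphere from its diameter
#'
#' @param diameter_mm Diameter(s) in mm.
#' @return Volume(s) in ml.
#' @export
sphere_volume_ml <- function(diameter_mm) {
  .check_positive(diameter_mm, "diameter_mm")
  (pi / 6) * diameter_mm^3 / 1000
}

#' @export
print.fill_plan <- function(x, ...) {
  cat("NEMA IEC phantom fill plan\n")
  cat(sprintf("  stock: %.1f MBq in %.0f ml -> %.1f kBq/ml (spheres)\n",
              x$total_activity, x$stock_volume, x$sphere_concentration))
  cat(sprintf("  withdrawal for spheres: %.1f ml\n", x$sphere_withdrawal_volume))
  cat(sprintf("  background: %.1f kBq/ml in %.0f ml\n",
              x$background_concentration, x$background_compartment_volume))
  cat(sprintf("  sphere-to-background ratio R = %.3f\n", x$ratio_R))
  invisible(x)
}

#' Geometric and radiochemical description of the digital NEMA IEC phantom
#'
#' The six fillable spheres sit on a circle of radius 57.2 mm in a single
#' transaxial plane (the standard NEMA IEC arrangement), 60 degrees apart,
#' largest sphere at angle 0. The torso cross-section is modelled as a
#' 300 x 230 mm ellipse extruded over the axial length; this reproduces
#' the ~9.8 l background compartment of the physical phantom.
#'
#' @param sphere_diameters Six internal diameters in mm, descending.
#' @param sphere_ring_radius Radius (mm) of the circle carrying the sphere
#'   centres.
#' @param sphere_angles_deg Angular positions (degrees) of the spheres.
#' @param body_semiaxes Half-width and half-height (mm) of the elliptical
#'   torso cross-section.
#' @param body_length Axial extent (mm) of the phantom cavity.
#' @param fill_plan A [compute_fill_plan()] result; default is the
#'   214.2 MBq / 1200 ml / 9787 ml preparation giving 178.5 and 21 kBq/ml.
#' @param mu_water Linear attenuation coefficient of water at 140 keV
#'   (1/cm).
#' @param lung_insert If `TRUE`, include a central zero-activity low-density
#'   cylinder (25 mm radius, mu 0.04/cm) mimicking the lung insert.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(sphere_diameters = c(37, 28, 22, 17, 13, 10),
                         sphere_ring_radius = 57.2,
                         sphere_angles_deg = seq(0, 300, by = 60),
                         body_semiaxes = c(150, 115),
                         body_length = 180,
                         fill_plan = compute_fill_plan(214.2, 1200,
                                                       sphere_diameters, 9787),
                         mu_water = 0.154,
                         lung_insert = FALSE) {
  stopifnot(length(sphere_diameters) == 6, length(sphere_angles_deg) == 6)
  .check_positive(sphere_diameters, "sphere_diameters")
  .check_positive(body_semiaxes, "body_semiaxes")
  .check_positive(body_length, "body_length")
  .check_positive(mu_water, "mu_water")

  ang <- sphere_angles_deg * pi / 180
  centers <- cbind(x = sphere_ring_radius * cos(ang),
                   y = sphere_ring_radius * sin(ang),
                   z = 0)

  # spheres must be pairwise disjoint and inside the body outline
  r <- sphere_diameters / 2
  for (i in 1:5) for (j in (i + 1):6) {
    d <- sqrt(sum((centers[i, 1:2] - centers[j, 1:2])^2))
    if (d <= r[i] + r[j])
      stop("geometry error: spheres ", i, " and ", j, " overlap", call. = FALSE)
  }
  edge <- sqrt((centers[, "x"] / body_semiaxes[1])^2 +
                 (centers[, "y"] / body_semiaxes[2])^2)
  if (any(edge >= 1))
    stop("geometry error: sphere centre outside the body outline", call. = FALSE)

  structure(list(
    sphere_diameters = sphere_diameters,
    sphere_centers = centers,
    body_semiaxes = body_semiaxes,
    body_length = body_length,
    fill_plan = fill_plan,
    mu_water = mu_water,
    lung_insert = lung_insert
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Digital NEMA IEC body phantom\n")
  cat("  spheres (mm):", paste(x$sphere_diameters, collapse = ", "), "\n")
  cat(sprintf("  body: %.0f x %.0f mm ellipse, %.0f mm long; mu_water %.3f /cm\n",
              2 * x$body_semiaxes[1], 2 * x$body_semiaxes[2], x$body_length,
              x$mu_water))
  print(x$fill_plan)
  invisible(x)
}

# Sub-voxel in/out fraction for one sphere over the voxels of its bounding
# box, computed on an s^3 supersampling lattice.
.sphere_fraction <- function(coords, center, radius, ss) {
  off <- (seq_len(ss) - 0.5) / ss - 0.5   # sub-voxel offsets in voxel units
  vx <- coords$voxel_size
  ix <- which(abs(coords$x - center[1]) <= radius + vx)
  iy <- which(abs(coords$y - center[2]) <= radius + vx)
  iz <- which(abs(coords$z - center[3]) <= radius + vx)
  if (!length(ix) || !length(iy) || !length(iz)) return(NULL)

  frac <- array(0, c(length(ix), length(iy), length(iz)))
  gx <- outer(coords$x[ix] - center[1], off * vx, "+")  # |ix| x ss
  gy <- outer(coords$y[iy] - center[2], off * vx, "+")
  gz <- outer(coords$z[iz] - center[3], off * vx, "+")
  r2 <- radius^2
  for (a in seq_len(ss)) for (b in seq_len(ss)) for (cc in seq_len(ss)) {
    inside <- outer(outer(gx[, a]^2, gy[, b]^2, "+"), gz[, cc]^2, "+") <= r2
    frac <- frac + inside
  }
  list(ix = ix, iy = iy, iz = iz, frac = frac / ss^3)
}

#' Voxelize the digital phantom into activity and attenuation maps
#'
#' Interior voxels carry the compartment concentration; boundary voxels
#' carry the sub-voxel volume-fraction-weighted concentration estimated on
#' a `supersampling`^3 lattice. The attenuation map is `mu_water` inside
#' the body outline (spheres are water-equivalent) and 0 outside.
#'
#' @param spec A [phantom_spec()].
#' @param voxel_size Isotropic voxel size in mm (default 4.8, the native
#'   acquisition pixel size).
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param supersampling Sub-voxel sampling factor per axis (>= 1).
#' @return An object of class `voxel_phantom` with fields `activity`
#'   (kBq/ml), `mu_map` (1/cm), `voxel_size`, `coords` and `spec`.
#' @export
voxelize_phantom <- function(spec, voxel_size = 4.8,
                             grid_shape = c(128, 128, 128),
                             supersampling = 4) {
  stopifnot(inherits(spec, "phantom_spec"))
  .check_positive(voxel_size, "voxel_size")
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8))
  supersampling <- as.integer(supersampling)
  stopifnot(supersampling >= 1)

  coords <- list(x = .axis_coords(grid_shape[1], voxel_size),
                 y = .axis_coords(grid_shape[2], voxel_size),
                 z = .axis_coords(grid_shape[3], voxel_size),
                 voxel_size = voxel_size)

  r <- spec$sphere_diameters / 2
  half_extent <- voxel_size * (grid_shape / 2)
  for (s in 1:6) {
    if (any(abs(spec$sphere_centers[s, ]) + r[s] > half_extent))
      stop("geometry error: sphere ", s, " extends outside the grid",
           call. = FALSE)
  }

  # body fraction is separable: elliptical cross-section (x,y) x axial slab (z)
  off <- ((seq_len(supersampling) - 0.5) / supersampling - 0.5) * voxel_size
  a2 <- spec$body_semiaxes[1]^2; b2 <- spec$body_semiaxes[2]^2
  xy_frac <- matrix(0, grid_shape[1], grid_shape[2])
  for (a in seq_along(off)) for (b in seq_along(off)) {
    xy_frac <- xy_frac + (outer((coords$x + off[a])^2 / a2,
                                (coords$y + off[b])^2 / b2, "+") <= 1)
  }
  xy_frac <- xy_frac / supersampling^2
  zl <- spec$body_length / 2
  z_frac <- colMeans(abs(outer(off, coords$z, "+")) <= zl)
  body_frac <- array(outer(xy_frac, z_frac), dim = grid_shape)

  sph_frac <- array(0, grid_shape)
  for (s in 1:6) {
    f <- .sphere_fraction(coords, spec$sphere_centers[s, ], r[s], supersampling)
    if (!is.null(f)) sph_frac[f$ix, f$iy, f$iz] <- sph_frac[f$ix, f$iy, f$iz] + f$frac
  }
  sph_frac <- pmin(sph_frac, body_frac)

  fp <- spec$fill_plan
  activity <- fp$background_concentration * (body_frac - sph_frac) +
    fp$sphere_concentration * sph_frac
  mu_map <- spec$mu_water * body_frac

  if (isTRUE(spec$lung_insert)) {
    lr <- 25; lmu <- 0.04
    lung <- array(0, grid_shape)
    in_xy <- outer(coords$x^2, coords$y^2, "+") <= lr^2
    lung[] <- outer(in_xy, abs(coords$z) <= zl)
    lung <- lung * body_frac
    activity <- activity - fp$background_concentration * lung * (1 - sph_frac)
    mu_map <- mu_map - (spec$mu_water - lmu) * lung
  }

  structure(list(activity = activity, mu_map = mu_map,
                 voxel_size = voxel_size, coords = coords, spec = spec,
                 supersampling = supersampling),
            class = "voxel_phantom")
}

#' Total activity held by a voxelized phantom grid
#'
#' @param vox A [voxelize_phantom()] result.
#' @return Total activity in kBq.
#' @export
grid_total_activity <- function(vox) {
  stopifnot(inherits(vox, "voxel_phantom"))
  sum(vox$activity) * vox$voxel_size^3 / 1000
}

#' Analytic total activity implied by the phantom geometry
#'
#' Background volume is the body cavity minus the sphere volumes; used as
#' the digitisation reference for [voxelize_phantom()].
#'
#' @param spec A [phantom_spec()].
#' @return Total activity in kBq.
#' @export
analytic_total_activity <- function(spec) {
  fp <- spec$fill_plan
  sph_vol <- sum(sphere_volume_ml(spec$sphere_diameters))
  body_vol <- pi * spec$body_semiaxes[1] * spec$body_semiaxes[2] *
    spec$body_length / 1000  # ml
  fp$background_concentration * (body_vol - sph_vol) +
    fp$sphere_concentration * sph_vol
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("voxel_phantom: %d x %d x %d @ %.2f mm (supersampling %d)\n",
              d[1], d[2], d[3], x$voxel_size, x$supersampling))
  cat(sprintf("  total activity %.1f MBq (analytic %.1f MBq)\n",
              grid_total_activity(x) / 1000,
              analytic_total_activity(x$spec) / 1000))
  invisible(x)
}
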