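#' IOERT beam configuration
#'
#' Describes the applicator and electron beam of the deterministic broad-beam
#' dose model: a cylindrical applicator of given diameter whose end face is
#' cut at the bevel angle, an electron energy with a percentage-depth-dose
#' (PDD) parameterisation, and the calibration source-to-surface distance
#' (SSD) at which the central-axis maximum in water defines 100%.
#'
#' @param applicator_diameter applicator inner diameter, mm.
#' @param bevel_angle bevel of the applicator end face, degrees in [0, 90).
#' @param energy nominal electron energy, MeV (bookkeeping only; the depth
#'   dose is set by `pdd`).
#' @param position center of the applicator end face, mm.
#' @param axis unit beam direction (from applicator into tissue).
#' @param bevel_azimuth direction (degrees in the plane orthogonal to `axis`)
#'   towards which the beveled face drops away.
#' @param ssd_ref calibration source-to-surface distance, mm.
#' @param pdd list with `surface_dose` (fraction at depth 0), `R100`, `R50`,
#'   `Rp` (mm water): the depth-dose curve rises from `surface_dose` to 1 at
#'   `R100`, falls through 0.5 at `R50` and reaches the bremsstrahlung floor
#'   at the practical range `Rp`.
#' @param penumbra_sigma Gaussian penumbra width at the field edge, mm.
#' @return an object of class `beam_config`.
#' @export
beam_config <- function(applicator_diameter = 70, bevel_angle = 30,
                        energy = 9, position = c(0, 0, 0),
                        axis = c(0, 0, -1), bevel_azimuth = 0,
                        ssd_ref = 1000,
                        pdd = list(surface_dose = 0.85, R100 = 20,
                                   R50 = 36, Rp = 45),
                        penumbra_sigma = 4) {
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  stopifnot(applicator_diameter > 0, bevel_angle >= 0, bevel_angle < 90,
            energy > 0, ssd_ref > 0, penumbra_sigma > 0)
  if (!(pdd$R100 < pdd$R50 && pdd$R50 < pdd$Rp))
    stop("PDD anchors must satisfy R100 < R50 < Rp")
  if (pdd$surface_dose <= 0 || pdd$surface_dose > 1)
    stop("surface_dose must be a fraction in (0, 1]")
  structure(list(applicator_diameter = applicator_diameter,
                 bevel_angle = bevel_angle, energy = energy,
                 position = as.numeric(position), axis = axis,
                 bevel_azimuth = bevel_azimuth, ssd_ref = ssd_ref,
                 pdd = pdd, penumbra_sigma = penumbra_sigma),
            class = "beam_config")
}

#' @export
print.beam_config <- function(x, ...) {
  cat(sprintf(
    "beam_config: %g mm applicator, %g deg bevel, %g MeV (R100 %g / R50 %g / Rp %g mm)\n",
    x$applicator_diameter, x$bevel_angle, x$energy, x$pdd$R100, x$pdd$R50,
    x$pdd$Rp))
  invisible(x)
}

# outward normal of the beveled end plane, oriented so dot(axis, n) > 0
beam_plane_normal <- function(beam) {
  a <- beam$axis
  b <- beam$bevel_angle * pi / 180
  if (b == 0) return(a)
  # lateral frame
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(a[2] * ref[3] - a[3] * ref[2], a[3] * ref[1] - a[1] * ref[3],
         a[1] * ref[2] - a[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  az <- beam$bevel_azimuth * pi / 180
  lat <- cos(az) * u + sin(az) * v
  n <- cos(b) * a + sin(b) * lat
  n / sqrt(sum(n^2))
}

#' Convert Hounsfield units to physical density
#'
#' Piecewise-linear HU-to-density mapping with anchors air (-1000 HU,
#' 0.0012 g/cm3), water (0 HU, 1.0 g/cm3) and dense tissue/bone (+1000 HU,
#' 1.6 g/cm3); monotone non-decreasing, values clamped to `[-1024, 3071]` HU
#' with a warning.
#'
#' @param ct `volume_image` in HU.
#' @return `volume_image` of densities in g/cm3.
#' @export
hu_to_density <- function(ct) {
  stopifnot(inherits(ct, "volume_image"))
  v <- ct$values
  if (any(v < -1024 | v > 3071)) {
    warning("HU values outside [-1024, 3071] were clamped")
    v <- pmin(pmax(v, -1024), 3071)
  }
  anchors_hu <- c(-1024, -1000, 0, 1000, 3071)
  anchors_rho <- c(0.0012, 0.0012, 1.0, 1.6,
                   1.6 + (3071 - 1000) * (1.6 - 1.0) / 1000)
  rho <- stats::approx(anchors_hu, anchors_rho, xout = as.vector(v),
                       rule = 2)$y
  volume_image(array(rho, dim = dim(v)), origin = ct$origin,
               spacing = ct$spacing)
}

#' Radiological depth of a point along the beam axis
#'
#' Line integral of physical density from the (beveled) applicator end plane
#' to the point, along the beam axis direction, sampled every 0.2 mm with
#' trilinear interpolation. Returned in mm of water-equivalent depth.
#'
#' @param density `volume_image` of densities (g/cm3), e.g. from
#'   [hu_to_density()].
#' @param beam a `beam_config`.
#' @param point length-3 position, mm.
#' @param step sampling step, mm.
#' @return list with `radiological` (mm water), `tissue_path` (mm of non-air
#'   material) and `geometric` (mm from the end plane).
#' @export
radiological_depth <- function(density, beam, point, step = 0.2) {
  stopifnot(inherits(density, "volume_image"), inherits(beam, "beam_config"))
  g <- vol_grid(density)
  point <- as.numeric(point)
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (g$dim - 0.5) * g$spacing
  if (any(point < lo) || any(point > hi))
    stop("out of bounds: point lies outside the density grid")
  r <- cpp_raddepth(as.numeric(density$values), as.integer(g$dim), g$origin,
                    g$spacing, beam$position, beam$axis,
                    beam_plane_normal(beam), point, step, 0.05)
  list(radiological = r[1], tissue_path = r[2], geometric = r[3])
}

# sampled PDD table: monotone rise to 1.0 at R100, monotone fall through 0.5
# at R50 to a small bremsstrahlung floor beyond Rp
pdd_table <- function(pdd, dx = 0.1) {
  floor_frac <- 0.002
  rise_x <- c(0, 0.6 * pdd$R100, pdd$R100)
  rise_y <- c(pdd$surface_dose, pdd$surface_dose + 0.75 *
                (1 - pdd$surface_dose), 1)
  fall_x <- c(pdd$R100, (pdd$R100 + pdd$R50) / 2, pdd$R50,
              (pdd$R50 + pdd$Rp) / 2, pdd$Rp, pdd$Rp + 8)
  fall_y <- c(1, 0.82, 0.5, 0.17, 0.02, floor_frac)
  f_rise <- splinefun(rise_x, rise_y, method = "monoH.FC")
  f_fall <- splinefun(fall_x, fall_y, method = "monoH.FC")
  xmax <- pdd$Rp + 40
  x <- seq(0, xmax, by = dx)
  y <- ifelse(x <= pdd$R100, f_rise(x),
              ifelse(x <= pdd$Rp + 8, f_fall(x), floor_frac))
  y <- pmax(y, floor_frac)
  list(x0 = 0, dx = dx, y = y)
}

#' Compute a 3D electron dose distribution on a CT/pseudo-CT study
#'
#' Deterministic broad-beam model: for every voxel, dose in percent is
#' `PDD(radiological depth beyond the end plane) x lateral profile x
#' inverse-square factor`. The lateral profile is flat inside the applicator
#' field (projected along the diverging rays from a virtual source at the
#' calibration SSD), falls off as a Gaussian of width `penumbra_sigma` at the
#' field edge, and keeps a 1% scatter tail with 10 mm Gaussian decay outside.
#' The inverse-square factor `((SSD + tissue path) / (SSD + geometric
#' depth))^2` equals 1 in the calibration geometry and reduces the dose by
#' the air-gap divergence otherwise. 100% is the central-axis maximum in
#' water with the surface at the applicator end.
#'
#' @param ct `volume_image` in HU.
#' @param beam a `beam_config`.
#' @param resolution dose-grid voxel size, mm (default 1.0). Ignored when
#'   `grid` is supplied.
#' @param grid optional explicit dose grid spec.
#' @param step ray-marching step, mm.
#' @return a `dose_grid` volume (values in percent of the calibration
#'   maximum).
#' @export
compute_dose <- function(ct, beam, resolution = 1.0, grid = NULL, step = 0.2) {
  stopifnot(inherits(ct, "volume_image"), inherits(beam, "beam_config"))
  dens <- hu_to_density(ct)
  g <- vol_grid(ct)
  if (is.null(grid)) {
    if (max(abs(g$spacing - resolution)) < 1e-9) {
      grid <- g
    } else {
      sp <- rep(resolution, 3)
      dims <- pmax(1L, as.integer(floor((g$spacing * (g$dim - 1)) / sp)) + 1L)
      grid <- list(origin = g$origin, spacing = sp, dim = dims)
    }
  } else grid <- vol_grid(grid)
  # the applicator axis must meet the grid footprint
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$dim - 0.5) * grid$spacing
  hit <- axis_hits_box(beam$position, beam$axis, lo, hi)
  if (!hit) stop("empty field: the applicator axis misses the dose grid")
  pt <- pdd_table(beam$pdd)
  vals <- cpp_dose(as.numeric(dens$values), as.integer(vol_grid(dens)$dim),
                   dens$origin, dens$spacing,
                   grid$origin, grid$spacing, as.integer(grid$dim),
                   beam$position, beam$axis, beam_plane_normal(beam),
                   beam$applicator_diameter / 2, beam$ssd_ref,
                   pt$x0, pt$dx, pt$y,
                   beam$penumbra_sigma, 0.01, 10, 45, step, 0.05)
  out <- volume_image(array(vals, dim = grid$dim), origin = grid$origin,
                      spacing = grid$spacing)
  class(out) <- c("dose_grid", class(out))
  out
}

axis_hits_box <- function(p, a, lo, hi) {
  tmin <- -Inf; tmax <- Inf
  for (j in 1:3) {
    if (abs(a[j]) < 1e-12) {
      if (p[j] < lo[j] || p[j] > hi[j]) return(FALSE)
    } else {
      t1 <- (lo[j] - p[j]) / a[j]; t2 <- (hi[j] - p[j]) / a[j]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  tmax >= tmin
}

#' Dose under the conventional water-equivalence assumption
#'
#' Equivalent to [compute_dose()] on a uniform water volume (0 HU) whose
#' surface coincides with the (beveled) applicator end plane: the flat
#' irradiation surface assumed when no surface information enters the dose
#' calculation. Independent of any patient CT.
#'
#' @param beam a `beam_config`.
#' @param grid dose grid spec (list with `origin`, `spacing`, `dim`) or a
#'   `volume_image` whose grid is reused.
#' @param step ray-marching step, mm.
#' @return a `dose_grid` volume.
#' @export
water_assumption_dose <- function(beam, grid, step = 0.2) {
  stopifnot(inherits(beam, "beam_config"))
  grid <- vol_grid(grid)
  ax <- list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing[1],
             y = grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing[2],
             z = grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing[3])
  np <- beam_plane_normal(beam)
  hu <- array(-1000, dim = grid$dim)
  # water on the far side of the beveled end plane
  px <- outer(outer(ax$x - beam$position[1], rep(1, grid$dim[2])),
              rep(1, grid$dim[3]))
  py <- outer(outer(rep(1, grid$dim[1]), ax$y - beam$position[2]),
              rep(1, grid$dim[3]))
  pz <- outer(outer(rep(1, grid$dim[1]), rep(1, grid$dim[2])),
              ax$z - beam$position[3])
  beyond <- (px * np[1] + py * np[2] + pz * np[3]) > 0
  hu[beyond] <- 0
  water <- volume_image(hu, origin = grid$origin, spacing = grid$spacing)
  compute_dose(water, beam, grid = grid, step = step)
}

#' Place the applicator above a surface at a prescribed maximum air gap
#'
#' Positions the (vertical, -z pointing) applicator so that the maximum
#' distance from the beveled end plane to the surface along the beam axis,
#' over the field footprint, equals `max_gap`.
#'
#' @param height height-map matrix of the surface (mm), with `x0`, `y0`,
#'   `dx` describing its grid.
#' @param beam a `beam_config` (its `position` is replaced).
#' @param max_gap target maximum applicator-end-to-surface distance, mm.
#' @param center xy center of the applicator axis, mm (default: footprint
#'   center of the height map).
#' @param x0,y0,dx height-map grid parameters.
#' @return the `beam_config` with its `position` set; attribute `max_gap`
#'   records the achieved gap.
#' @export
place_applicator <- function(height, beam, max_gap, center = NULL,
                             x0 = 0, y0 = 0, dx = 1) {
  nx <- nrow(height); ny <- ncol(height)
  xs <- x0 + (seq_len(nx) - 1) * dx
  ys <- y0 + (seq_len(ny) - 1) * dx
  if (is.null(center))
    center <- c(mean(range(xs)), mean(range(ys)))
  np <- beam_plane_normal(beam)
  r <- beam$applicator_diameter / 2
  X <- outer(xs, rep(1, ny)); Y <- outer(rep(1, nx), ys)
  infield <- (X - center[1])^2 + (Y - center[2])^2 <= r^2 & !is.na(height)
  if (!any(infield)) stop("applicator footprint misses the surface")
  # end plane: dot(p - position, np) = 0 with position = (cx, cy, z0):
  # plane height over (x, y) is z0 - (np1 (x - cx) + np2 (y - cy)) / np3
  gplane <- -(np[1] * (X - center[1]) + np[2] * (Y - center[2])) / np[3]
  # choose z0: max over footprint of (z0 + gplane - height) = max_gap
  z0 <- max_gap - max(gplane[infield] - height[infield])
  beam$position <- c(center, z0)
  attr(beam, "max_gap") <- max_gap
  beam
}

#' Fluid level that reduces the maximum air gap to a target
#'
#' With the applicator fixed, filling the surgical field with fluid raises
#' (flattens) the low regions of the surface; this solves for the fill level
#' whose maximum applicator-end-to-surface gap equals `target_gap`.
#'
#' @param height surface height map, mm.
#' @param beam a placed `beam_config`.
#' @param target_gap desired maximum gap, mm.
#' @param x0,y0,dx height-map grid parameters.
#' @return fill level (absolute z, mm).
#' @export
blood_level_for_gap <- function(height, beam, target_gap,
                                x0 = 0, y0 = 0, dx = 1) {
  nx <- nrow(height); ny <- ncol(height)
  xs <- x0 + (seq_len(nx) - 1) * dx
  ys <- y0 + (seq_len(ny) - 1) * dx
  np <- beam_plane_normal(beam)
  r <- beam$applicator_diameter / 2
  X <- outer(xs, rep(1, ny)); Y <- outer(rep(1, nx), ys)
  cx <- beam$position[1]; cy <- beam$position[2]; z0 <- beam$position[3]
  infield <- (X - cx)^2 + (Y - cy)^2 <= r^2 & !is.na(height)
  zplane <- z0 - (np[1] * (X - cx) + np[2] * (Y - cy)) / np[3]
  gap_at <- function(level) {
    h <- pmax(height, level)
    max(zplane[infield] - h[infield])
  }
  g0 <- gap_at(-Inf)
  if (g0 <= target_gap)
    stop("surface already within the target gap; no fluid needed")
  stats::uniroot(function(l) gap_at(l) - target_gap,
                 lower = min(height, na.rm = TRUE) - 1,
                 upper = max(zplane), tol = 1e-6)$root
}
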