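#' 3D gamma criteria
#'
#' @param dose_diff_pct dose-difference criterion, percent of the global
#'   normalisation dose (default 3).
#' @param dta_mm distance-to-agreement criterion, mm (default 3).
#' @param threshold_pct evaluate only reference voxels above this percentage
#'   of the global normalisation dose (default 10).
#' @param search_radius candidate search radius, mm (default `3 * dta_mm`).
#' @param search_step sub-voxel search step, mm (default `dta_mm / 10`).
#' @return an object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff_pct = 3, dta_mm = 3, threshold_pct = 10,
                           search_radius = NULL, search_step = NULL) {
  stopifnot(dose_diff_pct > 0, dta_mm > 0, threshold_pct >= 0,
            threshold_pct < 100)
  if (is.null(search_radius)) search_radius <- 3 * dta_mm
  if (is.null(search_step)) search_step <- dta_mm / 10
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 threshold_pct = threshold_pct,
                 search_radius = search_radius, search_step = search_step),
            class = "gamma_criteria")
}

gamma_offsets <- function(radius, step, sort_by_r = TRUE) {
  k <- seq(-floor(radius / step), floor(radius / step))
  off <- as.matrix(expand.grid(x = k * step, y = k * step, z = k * step))
  r2 <- rowSums(off^2)
  keep <- r2 <= radius^2 + 1e-12
  off <- off[keep, , drop = FALSE]
  r2 <- r2[keep]
  if (sort_by_r) {
    o <- order(r2)
    off <- off[o, , drop = FALSE]
    r2 <- r2[o]
  }
  list(off = off, r2 = r2)
}

#' 3D gamma-index map between two dose distributions
#'
#' For every reference voxel inside the mask and above the dose threshold,
#' the gamma index is the minimum over nearby positions `r` of
#' `sqrt((D_eval(r) - D_ref)^2 / dD^2 + |r - r_ref|^2 / dta^2)`, with `dD`
#' equal to `dose_diff_pct`% of the global normalisation dose (the maximum
#' of the reference distribution over the evaluated mask). The evaluated
#' dose is trilinearly interpolated on a sub-voxel search grid. Voxels below
#' the threshold or outside the mask are `NA` (not evaluated).
#'
#' @param ref reference `dose_grid`.
#' @param eval_dose evaluated `dose_grid` (any commensurable grid; sampled in
#'   physical coordinates).
#' @param crit a `gamma_criteria`.
#' @param mask optional binary `volume_image` on the reference grid (1 =
#'   evaluate); e.g. a tissue mask from the reference CT.
#' @param method `"sorted"` (pre-sorted offsets with early termination;
#'   exact) or `"exhaustive"` (plain scan over all offsets; the brute-force
#'   reference used for validation).
#' @param norm_dose optional explicit global normalisation dose (percent);
#'   default: the maximum of the reference distribution over the mask.
#' @return a `volume_image` of gamma values (`NA` where not evaluated) with
#'   attributes `norm_dose` and `criteria`.
#' @export
gamma_map <- function(ref, eval_dose, crit = gamma_criteria(), mask = NULL,
                      method = c("sorted", "exhaustive"), norm_dose = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(ref, "volume_image"), inherits(eval_dose, "volume_image"),
            inherits(crit, "gamma_criteria"))
  g <- vol_grid(ref)
  if (!is.null(mask)) {
    mg <- vol_grid(mask)
    if (!identical(mg$dim, g$dim) || max(abs(mg$origin - g$origin)) > 1e-9 ||
        max(abs(mg$spacing - g$spacing)) > 1e-9)
      stop("mask must live on the reference grid")
    msel <- mask$values > 0
  } else msel <- array(TRUE, dim = g$dim)
  if (is.null(norm_dose)) norm_dose <- max(ref$values[msel])
  if (!is.finite(norm_dose) || norm_dose <= 0)
    stop("empty evaluation: reference has no positive dose inside the mask")
  evalsel <- msel & (ref$values > crit$threshold_pct / 100 * norm_dose)
  if (!any(evalsel))
    stop("empty evaluation: no reference voxel above the dose threshold")
  idx0 <- which(evalsel) - 1L  # 0-based linear indices
  offs <- gamma_offsets(crit$search_radius, crit$search_step,
                        sort_by_r = (method == "sorted"))
  ge <- vol_grid(eval_dose)
  gam <- cpp_gamma(as.numeric(ref$values), as.integer(g$dim), g$origin,
                   g$spacing, as.numeric(eval_dose$values),
                   as.integer(ge$dim), ge$origin, ge$spacing,
                   idx0, offs$off, offs$r2,
                   crit$dose_diff_pct / 100 * norm_dose, crit$dta_mm,
                   method == "sorted")
  vals <- array(NA_real_, dim = g$dim)
  vals[evalsel] <- gam
  out <- list(values = vals, origin = g$origin, spacing = g$spacing)
  class(out) <- "volume_image"  # NA allowed here, bypass constructor
  attr(out, "norm_dose") <- norm_dose
  attr(out, "criteria") <- crit
  out
}

#' Gamma pass rate
#'
#' Percentage of evaluated voxels with gamma <= 1; voxels marked not
#' evaluated (`NA`) are excluded from numerator and denominator.
#'
#' @param gamma a gamma map from [gamma_map()].
#' @return pass rate in percent.
#' @export
pass_rate <- function(gamma) {
  stopifnot(inherits(gamma, "volume_image"))
  v <- gamma$values[!is.na(gamma$values)]
  if (length(v) == 0L) stop("empty evaluation: gamma map has no evaluated voxels")
  100 * mean(v <= 1)
}

#' Resample a volume onto another grid
#'
#' Trilinear interpolation for continuous data (dose, HU); nearest neighbour
#' for binary masks. Target voxels outside the source support are filled
#' with `fill` (default: -1000 for HU-like data, 0 otherwise).
#'
#' @param img source `volume_image`.
#' @param grid target grid spec (or `volume_image`).
#' @param mode `"trilinear"` or `"nearest"`.
#' @param fill out-of-support fill value.
#' @return `volume_image` on the target grid.
#' @export
resample_to_grid <- function(img, grid, mode = c("trilinear", "nearest"),
                             fill = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "volume_image"))
  g <- vol_grid(img)
  tg <- vol_grid(grid)
  # grids must overlap
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (g$dim - 0.5) * g$spacing
  tlo <- tg$origin - tg$spacing / 2
  thi <- tg$origin + (tg$dim - 0.5) * tg$spacing
  if (any(tlo > hi) || any(thi < lo))
    stop("disjoint grids: no overlap between source and target")
  vals <- cpp_resample(as.numeric(img$values), as.integer(g$dim), g$origin,
                       g$spacing, tg$origin, tg$spacing, as.integer(tg$dim),
                       if (mode == "trilinear") 0L else 1L, fill)
  out <- volume_image(array(vals, dim = tg$dim), origin = tg$origin,
                      spacing = tg$spacing)
  if (inherits(img, "dose_grid")) class(out) <- c("dose_grid", class(out))
  out
}
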