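#' Voxelize a watertight solid into a binary occupancy volume
#'
#' A voxel is 1 exactly when its center lies inside the solid by ray-crossing
#' parity (rays cast along +z; degenerate edge/vertex hits are resolved by a
#' deterministic 1e-4-voxel jitter of the ray origin). The default grid is
#' the bounding box of the solid at the requested spacing, optionally snapped
#' to a reference grid so voxel centers line up with an existing CT study.
#'
#' @param solid a watertight `triangle_mesh`.
#' @param spacing voxel size, mm (scalar or length 3). Default 1 mm isotropic.
#' @param grid optional explicit grid spec (list with `origin`, `spacing`,
#'   `dim`) that must cover the solid's bounding box.
#' @param align_to optional `volume_image` (or grid spec) whose voxel centers
#'   the default grid is snapped onto.
#' @return a binary `volume_image` with attribute `solid_bbox`.
#' @export
voxelize <- function(solid, spacing = 1, grid = NULL, align_to = NULL) {
  stopifnot(inherits(solid, "triangle_mesh"))
  if (!is_watertight(solid))
    stop("invalid input: voxelize requires a watertight mesh")
  bb_lo <- apply(solid$vertices, 2, min)
  bb_hi <- apply(solid$vertices, 2, max)
  if (is.null(grid)) {
    spacing <- rep(as.numeric(spacing), length.out = 3L)
    if (is.null(align_to)) {
      origin <- bb_lo + spacing / 2
    } else {
      ref <- vol_grid(align_to)
      if (max(abs(ref$spacing - spacing)) > 1e-9)
        spacing <- ref$spacing
      # snap to the reference lattice of voxel centers
      origin <- ref$origin + floor((bb_lo - ref$origin) / spacing) * spacing
    }
    dims <- pmax(1L, as.integer(ceiling((bb_hi - origin) / spacing + 1e-9)))
    grid <- list(origin = origin, spacing = spacing, dim = dims)
  } else {
    grid <- vol_grid(grid)
    glo <- grid$origin - grid$spacing / 2
    ghi <- grid$origin + (grid$dim - 1) * grid$spacing + grid$spacing / 2
    if (any(glo > bb_lo + 1e-6) || any(ghi < bb_hi - 1e-6))
      stop("grid bounds must cover the solid's bounding box")
  }
  occ <- cpp_voxelize(solid$vertices, solid$faces, grid$origin, grid$spacing,
                      as.integer(grid$dim))
  if (sum(occ) == 0L)
    warning("empty result: solid does not intersect the grid")
  out <- volume_image(array(as.numeric(occ), dim = grid$dim),
                      origin = grid$origin, spacing = grid$spacing)
  attr(out, "solid_bbox") <- rbind(lo = bb_lo, hi = bb_hi)
  out
}

#' Undo the artificial closure volume above the scanned surface
#'
#' The watertight solid produced by [extrude_and_cap()] encloses the region
#' between the scanned surface and the lid, which is air in reality. This
#' correction rewrites the binary volume so that a voxel is 1 exactly when
#' its center lies below the scan-tagged surface of the solid (column-wise
#' vertical ray query); everything between the surface and the lid, above the
#' lid, or outside the scanned columns becomes 0.
#'
#' @param binary binary `volume_image` from [voxelize()].
#' @param solid the same tagged `triangle_mesh` passed to [voxelize()].
#' @return binary `volume_image` on the same grid (1 = tissue side).
#' @export
correct_lid_region <- function(binary, solid) {
  stopifnot(inherits(binary, "volume_image"), inherits(solid, "triangle_mesh"))
  if (is.null(solid$tags) || !any(solid$tags == "scan"))
    stop("invalid input: solid carries no 'scan' face tags")
  ax <- vol_axes(binary)
  g <- vol_grid(binary)
  xy <- expand.grid(x = ax$x, y = ax$y)
  zs <- cpp_mesh_z_at(solid$vertices, solid$faces, xy$x, xy$y,
                      solid$tags == "scan", 1e-4 * g$spacing[1])
  zsurf <- matrix(zs$zmax, g$dim[1], g$dim[2])
  vals <- array(0, dim = g$dim)
  for (iz in seq_len(g$dim[3])) {
    below <- !is.na(zsurf) & (ax$z[iz] <= zsurf)
    vals[, , iz] <- as.numeric(below)
  }
  out <- volume_image(vals, origin = g$origin, spacing = g$spacing)
  attr(out, "solid_bbox") <- attr(binary, "solid_bbox")
  out
}

#' Convert a binary tissue volume into a two-valued pseudo-CT study
#'
#' Voxels with value 1 become water (0 HU) and voxels with value 0 become air
#' (-1000 HU). The matrix is enlarged by `padding` voxels per face; padded
#' voxels below the original grid continue the bottom voxel of their column
#' (water below scanned tissue), all other padding is air. Supplying `grid`
#' instead embeds the binary volume into that explicit grid with the same
#' extension rule.
#'
#' @param binary binary `volume_image` (values in \{0, 1\}).
#' @param padding voxels added per face (default 20).
#' @param grid optional target grid spec overriding `padding`.
#' @return a `pseudo_ct` volume.
#' @export
to_pseudo_ct <- function(binary, padding = 20L, grid = NULL) {
  stopifnot(inherits(binary, "volume_image"))
  if (!all(binary$values %in% c(0, 1)))
    stop("binary volume must contain only 0 and 1")
  g <- vol_grid(binary)
  if (is.null(grid)) {
    padding <- as.integer(padding)
    grid <- list(origin = g$origin - padding * g$spacing,
                 spacing = g$spacing,
                 dim = g$dim + 2L * padding)
  } else {
    grid <- vol_grid(grid)
    if (max(abs(grid$spacing - g$spacing)) > 1e-9)
      stop("target grid must use the binary volume's spacing")
  }
  # index of each target voxel center in the source lattice
  off <- (grid$origin - g$origin) / g$spacing
  if (max(abs(off - round(off))) > 1e-6)
    stop("target grid is not aligned with the binary volume's lattice")
  off <- as.integer(round(off))
  idx <- lapply(1:3, function(a) off[a] + seq_len(grid$dim[a]))
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  inx <- idx[[1]] >= 1L & idx[[1]] <= g$dim[1]
  iny <- idx[[2]] >= 1L & idx[[2]] <= g$dim[2]
  belowz <- idx[[3]] < 1L
  inz <- idx[[3]] >= 1L & idx[[3]] <= g$dim[3]
  vals <- array(0, dim = grid$dim)
  src <- binary$values
  # in-range block and downward continuation of each column's bottom voxel
  zsel <- clamp(idx[[3]], g$dim[3])
  take <- src[clamp(idx[[1]], g$dim[1]), clamp(idx[[2]], g$dim[2]), zsel,
              drop = FALSE]
  keepz <- inz | belowz
  mask <- outer(outer(inx, iny, "&"), keepz, "&")
  vals[mask] <- take[mask]
  hu <- array(-1000, dim = grid$dim)
  hu[vals == 1] <- 0
  as_pseudo_ct(volume_image(hu, origin = grid$origin, spacing = grid$spacing))
}

#' Two-valued tissue/air pseudo-CT from a real CT study
#'
#' Air is segmented by intensity thresholding (default upper limit -500 HU)
#' and set to -1000 HU; everything else (tissue) becomes water, 0 HU. This is
#' the simplification that retains surface irregularities and the air gap but
#' discards tissue heterogeneity.
#'
#' @param ct `volume_image` in HU.
#' @param air_max upper HU limit of the air segment (default -500).
#' @return a `pseudo_ct` volume on the same grid.
#' @export
ct_to_tissue_air <- function(ct, air_max = -500) {
  stopifnot(inherits(ct, "volume_image"))
  hu <- array(0, dim = dim(ct$values))
  hu[ct$values <= air_max] <- -1000
  as_pseudo_ct(volume_image(hu, origin = ct$origin, spacing = ct$spacing))
}

#' Extract the top surface of a tissue volume as a triangle mesh
#'
#' For volumes with height-map topology (every vertical line crosses the
#' tissue/air interface at most once, as in a scanned surgical field), the
#' -500 HU isosurface is recovered column-wise: the crossing height is
#' linearly interpolated between the last tissue voxel and the first air
#' voxel of each column, and the resulting height field is triangulated.
#'
#' @param ct a `volume_image` in HU (CT or pseudo-CT).
#' @param threshold iso level in HU (default -500).
#' @return an open `triangle_mesh` of the air/tissue interface.
#' @export
surface_from_volume <- function(ct, threshold = -500) {
  stopifnot(inherits(ct, "volume_image"))
  g <- vol_grid(ct)
  ax <- vol_axes(ct)
  v <- ct$values
  nz <- g$dim[3]
  H <- matrix(NA_real_, g$dim[1], g$dim[2])
  tissue <- v > threshold
  # topmost tissue voxel per column
  top <- apply(tissue, c(1, 2), function(col) {
    w <- which(col)
    if (length(w) == 0L) NA_integer_ else max(w)
  })
  has <- !is.na(top)
  for (ix in seq_len(g$dim[1])) {
    for (iy in seq_len(g$dim[2])) {
      t <- top[ix, iy]
      if (is.na(t)) next
      if (t == nz) { H[ix, iy] <- ax$z[nz] + 0.5 * g$spacing[3]; next }
      v1 <- v[ix, iy, t]; v2 <- v[ix, iy, t + 1L]
      f <- (v1 - threshold) / (v1 - v2)
      H[ix, iy] <- ax$z[t] + f * g$spacing[3]
    }
  }
  mesh <- heightfield_mesh(H, g$origin[1], g$origin[2], g$spacing[1],
                           g$spacing[2])
  if (is.null(mesh)) stop("no tissue surface found in the volume")
  mesh
}
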