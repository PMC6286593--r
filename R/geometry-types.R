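#' Point cloud in physical (mm) coordinates
#'
#' An unorganised set of 3D points, optionally carrying oriented unit normals
#' (one per point), as produced by a tracked range sensor sweeping a surface.
#'
#' @param points numeric matrix with 3 columns (x, y, z in mm).
#' @param normals optional numeric matrix of unit normals, same shape as
#'   `points`.
#' @return An object of class `point_cloud`: a list with elements `points`
#'   and `normals` (`NULL` if absent).
#' @export
point_cloud <- function(points, normals = NULL) {
  points <- as_xyz_matrix(points, "points")
  if (nrow(points) < 1L) stop("point cloud must contain at least one point")
  if (!all(is.finite(points))) stop("point cloud coordinates must be finite")
  if (!is.null(normals)) {
    normals <- as_xyz_matrix(normals, "normals")
    if (nrow(normals) != nrow(points))
      stop("normals must have one row per point")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("normals must have unit length (within 1e-6)")
  }
  structure(list(points = points, normals = normals), class = "point_cloud")
}

#' Triangle mesh in physical (mm) coordinates
#'
#' @param vertices numeric matrix with 3 columns (mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param tags optional character vector of per-face tags (e.g. `"scan"`,
#'   `"wall"`, `"lid"`), used to identify the artificial closure surfaces
#'   added when making a scanned surface watertight.
#' @param clean drop degenerate (zero-area) faces and unreferenced vertices.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `tags` (`NULL` if untagged).
#' @export
triangle_mesh <- function(vertices, faces, tags = NULL, clean = TRUE) {
  vertices <- as_xyz_matrix(vertices, "vertices")
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (nrow(faces) < 1L) stop("mesh must contain at least one face")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(tags)) {
    tags <- as.character(tags)
    if (length(tags) != nrow(faces)) stop("tags must have one entry per face")
  }
  if (clean) {
    a <- vertices[faces[, 1], , drop = FALSE]
    ar2 <- rowSums(cross3(vertices[faces[, 2], , drop = FALSE] - a,
                          vertices[faces[, 3], , drop = FALSE] - a)^2)
    keep <- ar2 > 1e-24
    if (!all(keep)) {
      faces <- faces[keep, , drop = FALSE]
      if (!is.null(tags)) tags <- tags[keep]
    }
    if (nrow(faces) < 1L) stop("mesh has no non-degenerate faces")
  }
  structure(list(vertices = vertices, faces = faces, tags = tags),
            class = "triangle_mesh")
}

#' Axis-aligned 3D scalar volume
#'
#' Used for CT studies (HU), pseudo-CT studies, binary masks and dose
#' distributions. `origin` is the physical position (mm) of the **center** of
#' the first voxel; grids are axis-aligned (no direction cosines).
#'
#' @param values 3D numeric array (x fastest).
#' @param origin numeric length-3, mm.
#' @param spacing numeric length-3, mm per voxel, strictly positive.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("origin and spacing must have length 3")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (anyNA(values) || any(!is.finite(values)))
    stop("volume values must be finite")
  structure(list(values = values, origin = origin, spacing = spacing),
            class = "volume_image")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s\n", nrow(x$points),
              if (is.null(x$normals)) "" else " with oriented normals"))
  invisible(x)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$tags)) "" else
                sprintf(" (tags: %s)", paste(unique(x$tags), collapse = ", "))))
  invisible(x)
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "%s: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, origin (%.4g, %.4g, %.4g)\n",
    class(x)[1], d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Grid specification of a volume
#'
#' @param x a `volume_image` (or a grid spec list).
#' @return list with `origin`, `spacing`, `dim`.
#' @export
vol_grid <- function(x) {
  if (inherits(x, "volume_image"))
    return(list(origin = x$origin, spacing = x$spacing, dim = dim(x$values)))
  stopifnot(is.list(x), !is.null(x$origin), !is.null(x$spacing), !is.null(x$dim))
  list(origin = as.numeric(x$origin), spacing = as.numeric(x$spacing),
       dim = as.integer(x$dim))
}

#' Voxel-center coordinate vectors of a volume grid
#' @param x a `volume_image` or grid spec.
#' @return list of numeric vectors `x`, `y`, `z` (mm).
#' @export
vol_axes <- function(x) {
  g <- vol_grid(x)
  list(x = g$origin[1] + (seq_len(g$dim[1]) - 1) * g$spacing[1],
       y = g$origin[2] + (seq_len(g$dim[2]) - 1) * g$spacing[2],
       z = g$origin[3] + (seq_len(g$dim[3]) - 1) * g$spacing[3])
}

#' Mark a two-valued air/water volume as a pseudo-CT study
#'
#' A pseudo-CT is a volume on the HU scale not acquired by a CT scanner; here
#' every voxel is exactly air (-1000 HU) or water (0 HU).
#'
#' @param x a `volume_image` whose values are all -1000 or 0.
#' @return `x` with class `pseudo_ct` prepended.
#' @export
as_pseudo_ct <- function(x) {
  stopifnot(inherits(x, "volume_image"))
  if (!all(x$values %in% c(-1000, 0)))
    stop("pseudo-CT values must be exactly -1000 or 0 HU")
  class(x) <- unique(c("pseudo_ct", class(x)))
  x
}

# ---- internal helpers ------------------------------------------------------

as_xyz_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(sprintf("%s must have 3 columns", what))
  dimnames(x) <- NULL
  x
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# signed volume of a closed mesh by the divergence theorem (positive for
# outward-oriented faces)
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
      a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem volume of a closed triangle mesh, in mm^3.
#' @param mesh a watertight `triangle_mesh`.
#' @return volume in mm^3 (non-negative).
#' @export
mesh_volume <- function(mesh) abs(mesh_signed_volume(mesh))
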