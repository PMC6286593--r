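#' Reconstruct an open surface mesh from an oriented point cloud
#'
#' Builds a height-field surface by moving-least-squares (MLS) averaging of
#' the points over a regular grid in the plane orthogonal to the dominant
#' normal direction, then triangulates the grid. Single-viewpoint scans of a
#' surgical field have height-map topology (no overhangs), for which this
#' graph reconstruction is exact in the noiseless limit; the contract is the
#' point-surface error (PSE) of the result, not the algorithm. The mesh is
#' trimmed to the support of the cloud, so an occluded single-viewpoint scan
#' yields an open mesh with boundary.
#'
#' @param cloud a `point_cloud` with oriented normals (>= 100 points).
#' @param grid_spacing node spacing of the reconstruction grid, mm.
#' @param smoothing kernel width multiplier; the Gaussian MLS bandwidth is
#'   `smoothing * max(grid_spacing, median point spacing)`.
#' @param axis optional height axis (length-3); default: the mean normal,
#'   snapped to +z when within 30 degrees of it.
#' @return a `triangle_mesh` approximating the scanned surface.
#' @export
reconstruct_surface <- function(cloud, grid_spacing = 1.0, smoothing = 1.0,
                                axis = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$normals))
    stop("invalid input: cloud must carry oriented normals")
  P <- cloud$points
  if (nrow(P) < 100L)
    stop("invalid input: at least 100 points are required")
  if (is.null(axis)) {
    axis <- colMeans(cloud$normals)
    axis <- axis / sqrt(sum(axis^2))
    # snap to +z only when essentially aligned (keeps grids axis-aligned
    # without distorting genuinely tilted scans)
    if (axis[3] > cos(5 * pi / 180)) axis <- c(0, 0, 1)
  } else {
    axis <- as.numeric(axis) / sqrt(sum(as.numeric(axis)^2))
  }
  # orthonormal frame (u, v, axis)
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(axis[2] * ref[3] - axis[3] * ref[2],
         axis[3] * ref[1] - axis[1] * ref[3],
         axis[1] * ref[2] - axis[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  pu <- P %*% cbind(u, v, axis)

  # median nearest-neighbour spacing (subsampled for speed)
  sub <- P[seq(1L, nrow(P), length.out = min(nrow(P), 2000L)), , drop = FALSE]
  med_sp <- stats::median(cpp_knn(sub, 1L, TRUE)$dist) *
    sqrt(nrow(sub) / nrow(P))
  med_sp <- max(med_sp, 1e-6)
  tau <- smoothing * max(grid_spacing, med_sp)
  radius <- max(2 * tau, 2 * med_sp, grid_spacing)

  x0 <- min(pu[, 1]); y0 <- min(pu[, 2])
  nx <- max(2L, as.integer(ceiling((max(pu[, 1]) - x0) / grid_spacing)) + 1L)
  ny <- max(2L, as.integer(ceiling((max(pu[, 2]) - y0) / grid_spacing)) + 1L)
  hf <- cpp_mls_heightfield(pu[, 1], pu[, 2], pu[, 3], x0, y0, grid_spacing,
                            nx, ny, radius, tau)
  mesh <- heightfield_mesh(hf$z, x0, y0, grid_spacing)
  if (is.null(mesh)) stop("reconstruction produced no supported grid cells")
  # map back to world coordinates
  mesh$vertices <- mesh$vertices %*% rbind(u, v, axis)
  mesh
}

# triangulate a height field matrix (NA = unsupported); vertices in the
# (u, v, h) frame; returns NULL when no complete cell exists
heightfield_mesh <- function(H, x0, y0, dx, dy = dx, tag = NULL) {
  nx <- nrow(H); ny <- ncol(H)
  ok <- !is.na(H)
  vid <- matrix(0L, nx, ny)
  vid[ok] <- seq_len(sum(ok))
  ix <- row(H); iy <- col(H)
  verts <- cbind(x0 + (ix[ok] - 1) * dx, y0 + (iy[ok] - 1) * dy, H[ok])
  # cells with all four corners supported
  c00 <- ok[-nx, -ny] & ok[-1, -ny] & ok[-nx, -1] & ok[-1, -1]
  if (!any(c00)) return(NULL)
  i <- row(c00)[c00]; j <- col(c00)[c00]
  v00 <- vid[cbind(i, j)]; v10 <- vid[cbind(i + 1L, j)]
  v01 <- vid[cbind(i, j + 1L)]; v11 <- vid[cbind(i + 1L, j + 1L)]
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  tags <- if (is.null(tag)) NULL else rep(tag, nrow(faces))
  triangle_mesh(verts, faces, tags = tags)
}

#' Remove statistical outliers from a point cloud
#'
#' Classic k-neighbour outlier filter: a point is dropped when its mean
#' distance to its k nearest neighbours exceeds `mean + std_ratio * sd` of
#' that statistic over the whole cloud.
#'
#' @param cloud a `point_cloud`.
#' @param k neighbourhood size (>= 3).
#' @param std_ratio rejection threshold in standard deviations.
#' @return the retained `point_cloud`; attribute `removed` carries the
#'   indices of dropped points.
#' @export
denoise_cloud <- function(cloud, k = 8L, std_ratio = 2.0) {
  stopifnot(inherits(cloud, "point_cloud"))
  k <- as.integer(k)
  if (k < 3L) stop("invalid parameter: k must be >= 3")
  if (k > nrow(cloud$points) - 1L)
    stop("invalid parameter: k exceeds the cloud size")
  nn <- cpp_knn(cloud$points, k, TRUE)
  md <- rowMeans(nn$dist)
  keep <- md <= mean(md) + std_ratio * sd(md)
  if (!any(keep)) stop("empty cloud after outlier filtering")
  out <- point_cloud(cloud$points[keep, , drop = FALSE],
                     if (is.null(cloud$normals)) NULL else
                       cloud$normals[keep, , drop = FALSE])
  attr(out, "removed") <- which(!keep)
  out
}
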