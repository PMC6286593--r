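#' Point-surface error (PSE)
#'
#' Root-mean-square unsigned distance from every point of a scanned point set
#' to the nearest point on a reconstructed triangle mesh. This is the figure
#' of merit for how well a reconstructed surface fits its source points.
#'
#' @param cloud a `point_cloud` (or bare 3-column matrix).
#' @param mesh a `triangle_mesh`.
#' @return A list with `rmse` (mm) and `distances` (per-point mm, for
#'   diagnostics).
#' @export
point_surface_rmse <- function(cloud, mesh) {
  P <- if (inherits(cloud, "point_cloud")) cloud$points
       else as_xyz_matrix(cloud, "points")
  if (nrow(P) < 1L) stop("invalid input: empty point cloud")
  if (!inherits(mesh, "triangle_mesh") || nrow(mesh$faces) < 1L)
    stop("invalid input: mesh must have at least one face")
  d <- cpp_point_mesh_dist(P, mesh$vertices, mesh$faces)
  list(rmse = sqrt(mean(d^2)), distances = d)
}

#' Surface target registration error (TRE)
#'
#' RMS and maximum unsigned distance from every vertex of an evaluated mesh to
#' the nearest point on a reference surface. Used to quantify how far a
#' registered scanned surface sits from the surface derived from the
#' reference CT. Set `mode = "vertex"` for nearest-vertex (point-to-point)
#' distances instead of point-to-surface.
#'
#' @param eval_mesh,ref_mesh `triangle_mesh` objects.
#' @param mode `"surface"` (default) or `"vertex"`.
#' @return list with `rms` and `max` (mm), plus per-vertex `distances`.
#' @export
mesh_tre <- function(eval_mesh, ref_mesh, mode = c("surface", "vertex")) {
  mode <- match.arg(mode)
  if (!inherits(eval_mesh, "triangle_mesh") || nrow(eval_mesh$vertices) < 1L)
    stop("invalid input: empty evaluated mesh")
  if (!inherits(ref_mesh, "triangle_mesh") || nrow(ref_mesh$vertices) < 1L)
    stop("invalid input: empty reference mesh")
  if (mode == "surface") {
    d <- cpp_point_mesh_dist(eval_mesh$vertices, ref_mesh$vertices,
                             ref_mesh$faces)
  } else {
    nn <- cpp_knn_query(eval_mesh$vertices, ref_mesh$vertices)
    d <- nn
  }
  list(rms = sqrt(mean(d^2)), max = max(d), distances = d)
}

# nearest-vertex distances from each row of A to the vertex set B
cpp_knn_query <- function(A, B) {
  # brute force in blocks to bound memory
  n <- nrow(A)
  out <- numeric(n)
  block <- max(1L, floor(2e7 / nrow(B)))
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(rowSums(A[s:e, , drop = FALSE]^2), rowSums(B^2), "+") -
      2 * (A[s:e, , drop = FALSE] %*% t(B))
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Voxelwise root-mean-square error between two volumes
#'
#' Computed without any alignment; both volumes must live on the identical
#' grid. Used, e.g., to check the stability of a scene between the CT studies
#' acquired before and after surface scanning.
#'
#' @param a,b `volume_image` objects on the same grid.
#' @return RMSE in the value units of the inputs (e.g. HU).
#' @export
image_rmse <- function(a, b) {
  stopifnot(inherits(a, "volume_image"), inherits(b, "volume_image"))
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$origin - b$origin)) > 1e-9 ||
      max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("incompatible grids: volumes must share origin, spacing and size")
  sqrt(mean((a$values - b$values)^2))
}

#' Estimate oriented surface normals of a point cloud
#'
#' Each normal is the direction of smallest variance of the local
#' k-neighbourhood (smallest eigenvector of the neighbourhood covariance),
#' oriented to face the scanner viewpoint.
#'
#' @param cloud a `point_cloud`.
#' @param k neighbourhood size (>= 3).
#' @param viewpoint scanner position (length-3, mm); normals are flipped so
#'   that `dot(normal, viewpoint - point) > 0`.
#' @return a `point_cloud` with unit `normals`.
#' @export
estimate_normals <- function(cloud, k = 12L, viewpoint) {
  stopifnot(inherits(cloud, "point_cloud"))
  P <- cloud$points
  k <- as.integer(k)
  if (k < 3L) stop("invalid parameter: k must be >= 3")
  if (k > nrow(P) - 1L)
    stop("invalid parameter: k exceeds the number of available neighbours")
  viewpoint <- as.numeric(viewpoint)
  stopifnot(length(viewpoint) == 3L)
  nn <- cpp_knn(P, k, TRUE)
  n <- nrow(P)
  N <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- P[c(i, nn$idx[i, ]), , drop = FALSE]
    cv <- stats::cov(nb)
    ev <- eigen(cv, symmetric = TRUE)
    v <- ev$vectors[, 3]
    if (sum(v * (viewpoint - P[i, ])) < 0) v <- -v
    N[i, ] <- v
  }
  N <- N / sqrt(rowSums(N^2))
  point_cloud(P, N)
}
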