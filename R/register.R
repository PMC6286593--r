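#' Named landmark set
#'
#' @param names character vector of unique marker names.
#' @param positions numeric matrix (n x 3), mm.
#' @param frame coordinate-frame label, e.g. `"scanner"` or `"CT"`.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(names, positions, frame = "unknown") {
  positions <- as_xyz_matrix(positions, "positions")
  names <- as.character(names)
  if (length(names) != nrow(positions))
    stop("one name per landmark position is required")
  if (anyDuplicated(names)) stop("landmark names must be unique")
  if (!all(is.finite(positions))) stop("landmark positions must be finite")
  structure(list(names = names, positions = positions, frame = frame),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set (%s): %d landmarks\n", x$frame, length(x$names)))
  invisible(x)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 vector, mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal (R'R = I within 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1 within 1e-9)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rigid_transform(t(t$rotation), -as.vector(t(t$rotation) %*% t$translation))
}

#' Landmark rigid registration by singular value decomposition
#'
#' Closed-form least-squares rigid transform (Arun/Umeyama with reflection
#' guard) mapping the source landmarks onto the destination landmarks, with
#' the fiducial registration error (FRE): the RMS distance between the
#' transformed source markers and the destination markers.
#'
#' @param src,dst `landmark_set` objects sharing the same names (>= 3
#'   non-collinear landmarks).
#' @return list with `transform` (a `rigid_transform`) and `fre` (mm).
#' @export
fit_rigid_landmarks <- function(src, dst) {
  stopifnot(inherits(src, "landmark_set"), inherits(dst, "landmark_set"))
  if (!setequal(src$names, dst$names))
    stop("invalid input: landmark names do not match")
  if (length(src$names) < 3L)
    stop("degenerate configuration: at least 3 landmarks are required")
  A <- src$positions
  B <- dst$positions[match(src$names, dst$names), , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv_cfg <- svd(A0)$d
  if (sv_cfg[2] < 1e-9 * max(sv_cfg[1], 1))
    stop("degenerate configuration: landmarks are collinear")
  H <- crossprod(A0, B0)
  s <- svd(H)
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  tr <- cb - as.vector(R %*% ca)
  tf <- rigid_transform(R, tr)
  res <- sweep(A %*% t(R), 2, tr, "+") - B
  list(transform = tf, fre = sqrt(mean(rowSums(res^2))))
}

#' Apply a rigid transform to a geometric object
#'
#' Positions are mapped by `x -> R x + t`; mesh connectivity, face tags and
#' point normals (rotated only) are preserved.
#'
#' @param geom a `point_cloud`, `triangle_mesh`, `landmark_set` or bare
#'   3-column matrix.
#' @param transform a `rigid_transform`.
#' @return the transformed object, same class as the input.
#' @export
apply_transform <- function(geom, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  R <- transform$rotation; tr <- transform$translation
  map <- function(P) sweep(P %*% t(R), 2, tr, "+")
  if (inherits(geom, "point_cloud")) {
    return(point_cloud(map(geom$points),
                       if (is.null(geom$normals)) NULL else
                         geom$normals %*% t(R)))
  }
  if (inherits(geom, "triangle_mesh")) {
    out <- geom
    out$vertices <- map(geom$vertices)
    return(out)
  }
  if (inherits(geom, "landmark_set")) {
    return(landmark_set(geom$names, map(geom$positions), geom$frame))
  }
  if (is.matrix(geom) && ncol(geom) == 3L) return(map(geom))
  stop("unsupported geometry type")
}

#' Locate a marker head on a scanned surface
#'
#' Centroid of the mesh vertices within `radius` of an approximate position
#' (e.g. a manual click near a fiducial marker).
#'
#' @param mesh a `triangle_mesh`.
#' @param approx approximate position, length-3 mm.
#' @param radius search radius, mm.
#' @return length-3 position (mm).
#' @export
landmark_from_surface <- function(mesh, approx, radius = 2) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  approx <- as.numeric(approx)
  d2 <- rowSums(sweep(mesh$vertices, 2, approx)^2)
  sel <- d2 <= radius^2
  if (!any(sel)) stop("not found: no mesh vertices within the search radius")
  colMeans(mesh$vertices[sel, , drop = FALSE])
}

#' Locate a metallic marker in a CT study
#'
#' Intensity-weighted centroid of voxels above an HU threshold inside a seed
#' sphere around an approximate position; suited to small high-density
#' fiducials.
#'
#' @param ct `volume_image` in HU.
#' @param approx approximate position, length-3 mm.
#' @param radius seed-sphere radius, mm.
#' @param hu_threshold minimum HU of marker voxels (default 800).
#' @return length-3 position (mm).
#' @export
landmark_from_ct <- function(ct, approx, radius = 3, hu_threshold = 800) {
  stopifnot(inherits(ct, "volume_image"))
  g <- vol_grid(ct)
  approx <- as.numeric(approx)
  i0 <- pmax(1L, floor((approx - radius - g$origin) / g$spacing) + 1L)
  i1 <- pmin(g$dim, ceiling((approx + radius - g$origin) / g$spacing) + 1L)
  if (any(i0 > i1)) stop("not found: seed sphere outside the volume")
  sub <- ct$values[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
  ax <- vol_axes(ct)
  gx <- ax$x[i0[1]:i1[1]]; gy <- ax$y[i0[2]:i1[2]]; gz <- ax$z[i0[3]:i1[3]]
  pos <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  w <- as.vector(sub)
  sel <- w > hu_threshold &
    rowSums(sweep(pos, 2, approx)^2) <= radius^2
  if (!any(sel)) stop("not found: no marker voxels in the seed sphere")
  w <- w[sel] - hu_threshold
  colSums(pos[sel, , drop = FALSE] * w) / sum(w)
}

#' Read a landmark file (JSON or CSV)
#'
#' JSON layout: `{"frame": "...", "landmarks": [{"name": "...",
#' "xyz": [x, y, z]}, ...]}`. CSV layout: columns `name,x,y,z`.
#'
#' @param path file path.
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    pos <- j$landmarks$xyz
    if (is.list(pos)) pos <- do.call(rbind, pos)
    return(landmark_set(j$landmarks$name, pos,
                        frame = if (is.null(j$frame)) "unknown" else j$frame))
  }
  if (ext == "csv") {
    tab <- utils::read.csv(path)
    return(landmark_set(tab$name, as.matrix(tab[, c("x", "y", "z")])))
  }
  stop(sprintf("unsupported landmark format '%s'", ext))
}

#' Write a landmark file (JSON or CSV)
#' @param lms a `landmark_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_landmarks <- function(lms, path) {
  stopifnot(inherits(lms, "landmark_set"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    j <- list(frame = lms$frame,
              landmarks = lapply(seq_along(lms$names), function(i)
                list(name = lms$names[i], xyz = as.numeric(lms$positions[i, ]))))
    jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  if (ext == "csv") {
    tab <- data.frame(name = lms$names, x = lms$positions[, 1],
                      y = lms$positions[, 2], z = lms$positions[, 3])
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(path))
  }
  stop(sprintf("unsupported landmark format '%s'", ext))
}
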