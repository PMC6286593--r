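#' Test whether a mesh is watertight
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces with consistent (opposite) orientation, so the mesh bounds a finite
#' volume. Multiple disjoint closed components count as watertight.
#'
#' @param mesh a `triangle_mesh`.
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  he <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
              cbind(f[, 3], f[, 1]))
  key <- (pmin(he[, 1], he[, 2]) - 1) * as.double(nv) + pmax(he[, 1], he[, 2])
  cnt <- table(key)
  if (any(cnt != 2L)) return(FALSE)
  # orientation: each undirected edge must appear once in each direction
  dirkey <- (he[, 1] - 1) * as.double(nv) + he[, 2]
  !any(duplicated(dirkey))
}

# directed boundary edges (edges with exactly one incident face), oriented as
# they appear in the faces
boundary_edges <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  he <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
              cbind(f[, 3], f[, 1]))
  key <- (pmin(he[, 1], he[, 2]) - 1) * as.double(nv) + pmax(he[, 1], he[, 2])
  cnt <- table(key)
  single <- names(cnt)[cnt == 1L]
  he[key %in% as.numeric(single), , drop = FALSE]
}

# all closed boundary loops as ordered vertex-index vectors; walks directed
# boundary edges (not vertices), so non-manifold "bowtie" boundary vertices
# with several incident loops are handled
boundary_loops <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0L) return(list())
  out_by_vertex <- split(seq_len(nrow(be)), be[, 1])
  used <- rep(FALSE, nrow(be))
  loops <- list()
  for (e0 in seq_len(nrow(be))) {
    if (used[e0]) next
    loop <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      loop <- c(loop, be[e, 1])
      nxtv <- be[e, 2]
      cand <- out_by_vertex[[as.character(nxtv)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) {
        if (nxtv == be[e0, 1]) loops[[length(loops) + 1L]] <- loop
        break
      }
      e <- cand[1]
    }
  }
  loops
}

# connected-component label per face (union-find over shared vertices)
face_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    ra <- find(f[i, 1])
    rb <- find(f[i, 2]); if (ra != rb) parent[rb] <- ra
    rc <- find(f[i, 3]); rc <- find(rc); if (find(f[i, 1]) != rc) parent[rc] <- find(f[i, 1])
  }
  vapply(f[, 1], find, integer(1))
}

# keep the largest connected component (the scanned surgical field); stray
# islands (e.g. isolated marker patches after trimming) are dropped
largest_component <- function(mesh) {
  comp <- face_components(mesh)
  tab <- table(comp)
  if (length(tab) <= 1L) return(mesh)
  keep <- comp == as.integer(names(tab)[which.max(tab)])
  drop_unused_vertices(
    triangle_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE],
                  tags = if (is.null(mesh$tags)) NULL else mesh$tags[keep],
                  clean = FALSE))
}

#' Extract the boundary contour of an open mesh
#'
#' Returns the longest boundary loop of the mesh (by polyline length),
#' optionally inset towards the interior by `offset` millimetres: with a
#' positive offset the mesh is (virtually) trimmed by removing vertices
#' within `offset` of the raw boundary, and the boundary of the trimmed mesh
#' is returned. The contour delineates where the extrusion walls will be
#' raised, just outside the surgical field.
#'
#' @param mesh an open `triangle_mesh`.
#' @param offset inset distance along the surface, mm (>= 0).
#' @return A `contour_path`: list with `points` (closed loop, first row not
#'   repeated), `extrusion_direction` and `extrusion_distance` (filled by
#'   [extrude_and_cap()] defaults if `NULL`), plus the trimmed mesh when
#'   `offset > 0` (element `mesh`).
#' @export
extract_boundary_contour <- function(mesh, offset = 0) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  loops <- boundary_loops(mesh)
  if (length(loops) == 0L)
    stop("no boundary: mesh is closed (watertight input)")
  trimmed <- mesh
  if (offset > 0) {
    # Euclidean distance of each vertex to the raw boundary polyline
    bverts <- unique(unlist(loops))
    d <- cpp_knn_query(mesh$vertices, mesh$vertices[bverts, , drop = FALSE])
    keepv <- d > offset
    keepf <- keepv[mesh$faces[, 1]] & keepv[mesh$faces[, 2]] &
      keepv[mesh$faces[, 3]]
    if (!any(keepf)) stop("offset removed the whole mesh")
    trimmed <- drop_unused_vertices(
      triangle_mesh(mesh$vertices, mesh$faces[keepf, , drop = FALSE],
                    tags = if (is.null(mesh$tags)) NULL else mesh$tags[keepf]))
    loops <- boundary_loops(trimmed)
    if (length(loops) == 0L) stop("trimmed mesh has no boundary")
  }
  len <- vapply(loops, function(l) {
    p <- trimmed$vertices[l, , drop = FALSE]
    sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2)))
  }, numeric(1))
  loop <- loops[[which.max(len)]]
  if (length(loop) < 3L) stop("boundary loop has fewer than 3 points")
  structure(list(points = trimmed$vertices[loop, , drop = FALSE],
                 vertex_ids = loop,
                 extrusion_direction = c(0, 0, 1),
                 extrusion_distance = NULL,
                 mesh = if (offset > 0) trimmed else NULL),
            class = "contour_path")
}

drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(map[mesh$faces], ncol = 3L), tags = mesh$tags,
                clean = FALSE)
}

#' Close an open scanned surface into a watertight solid
#'
#' Raises vertical walls from the boundary contour up to a planar lid normal
#' to the extrusion direction, and triangulates the lid as a planar fan
#' about the projected contour's centroid. Face tags are set to `"scan"` (the original
#' surface, preserved bit-identically), `"wall"` and `"lid"`, so the
#' voxelizer can later undo the artificial closure volume.
#'
#' @param mesh the open `triangle_mesh` (scan surface).
#' @param contour a `contour_path` from [extract_boundary_contour()]; when it
#'   carries a trimmed mesh, that mesh is closed instead.
#' @param extrusion_distance lid clearance above the highest surface point
#'   along the extrusion direction; default `1.2 *` the surface height range
#'   (at least 5 mm).
#' @return a watertight `triangle_mesh` with face tags.
#' @export
extrude_and_cap <- function(mesh, contour, extrusion_distance = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(contour, "contour_path"))
  if (!is.null(contour$mesh)) mesh <- contour$mesh
  if (nrow(contour$points) < 3L)
    stop("invalid input: contour must have at least 3 points")
  # contour must lie on/near the mesh
  dctr <- cpp_point_mesh_dist(contour$points, mesh$vertices, mesh$faces)
  if (max(dctr) > 2)
    stop("invalid input: contour lies farther than 2 mm from the mesh")
  dirz <- contour$extrusion_direction
  if (max(abs(dirz - c(0, 0, 1))) > 1e-9)
    stop("only +z extrusion is supported; rotate the mesh first")
  mesh <- largest_component(mesh)
  loops <- boundary_loops(mesh)
  if (length(loops) == 0L) stop("mesh has no boundary to extrude")
  len <- vapply(loops, function(l) {
    p <- mesh$vertices[l, , drop = FALSE]
    sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2)))
  }, numeric(1))
  ord <- order(len, decreasing = TRUE)
  loop <- loops[[ord[1]]]
  # close small interior holes first so the solid has a single boundary
  if (length(loops) > 1L) {
    mesh <- fill_loops(mesh, loops[ord[-1]], tag = "scan")
  }
  hrange <- diff(range(mesh$vertices[, 3]))
  if (is.null(extrusion_distance))
    extrusion_distance <- contour$extrusion_distance
  if (is.null(extrusion_distance))
    extrusion_distance <- max(0.2 * hrange, 5)
  z_lid <- max(mesh$vertices[, 3]) + extrusion_distance

  nv <- nrow(mesh$vertices)
  nL <- length(loop)
  topidx <- nv + seq_len(nL)
  topverts <- cbind(mesh$vertices[loop, 1:2, drop = FALSE], z_lid)
  verts <- rbind(mesh$vertices, topverts)

  # scan faces flipped so their normals point out of the solid (downwards)
  scanf <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  ntag <- rep("scan", nrow(scanf))
  # walls: boundary loop of the *flipped* scan runs opposite to `loop`;
  # wind wall quads against the flipped boundary for consistent orientation
  nxt <- c(2:nL, 1L)
  wall <- rbind(cbind(loop, loop[nxt], topidx[nxt]),
                cbind(loop, topidx[nxt], topidx))
  # lid: planar fan from the loop to its centroid. A fan is robust for any
  # simple loop (collinear runs along a straight boundary produce no
  # degenerate triangles) and pairs each wall top edge exactly once.
  apex <- nrow(verts) + 1L
  verts <- rbind(verts, c(mean(topverts[, 1]), mean(topverts[, 2]), z_lid))
  nxt2 <- c(2:nL, 1L)
  lid <- cbind(topidx, topidx[nxt2], apex)

  solid <- triangle_mesh(verts, rbind(scanf, wall, lid),
                         tags = c(ntag, rep("wall", nrow(wall)),
                                  rep("lid", nrow(lid))), clean = FALSE)
  if (mesh_signed_volume(solid) < 0) {
    solid$faces <- solid$faces[, c(1, 3, 2), drop = FALSE]
  }
  if (!is_watertight(solid))
    stop("geometry error: extrusion did not produce a watertight solid")
  if (mesh_volume(solid) <= 0)
    stop("geometry error: extruded solid has non-positive volume")
  solid
}

# fill a set of boundary loops (vertex-index vectors) with centroid fans;
# the fan traverses each loop opposite to its directed boundary edges, which
# is what edge pairing needs
fill_loops <- function(mesh, loops, tag = "scan") {
  verts <- mesh$vertices
  faces <- mesh$faces
  tags <- mesh$tags
  if (is.null(tags)) tags <- rep("scan", nrow(faces))
  for (l in loops) {
    nL <- length(l)
    if (nL < 3L) next
    apex <- nrow(verts) + 1L
    verts <- rbind(verts, colMeans(mesh$vertices[l, , drop = FALSE]))
    nxt <- c(2:nL, 1L)
    newf <- cbind(l[nxt], l, apex)
    faces <- rbind(faces, newf)
    tags <- c(tags, rep(tag, nrow(newf)))
  }
  triangle_mesh(verts, faces, tags = tags, clean = FALSE)
}
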