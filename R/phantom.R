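#' Synthetic surgical-field phantom
#'
#' Generates a seeded, fully reproducible CT study of a simulated surgical
#' field: a rough height-map tissue surface (filtered Gaussian noise) with
#' deep narrow holes, optional fluid ("blood") fill that flattens the low
#' regions, tissue HU texture (mean 40, SD 30 HU) with optional
#' fat/muscle-like heterogeneity bands at -60 HU, and air (-1000 HU) above
#' the surface. The exact surface, the binary tissue mask and the height map
#' are returned alongside the CT.
#'
#' @param seed integer RNG seed; the phantom is a pure function of
#'   `(seed, params)`.
#' @param extent xy extent of the field, mm (length 2 or scalar).
#' @param spacing isotropic voxel size, mm.
#' @param z_extent height of the CT volume, mm.
#' @param base_height mean surface height above the volume floor, mm.
#' @param roughness standard deviation of the smooth surface relief, mm.
#' @param n_holes number of deep narrow depressions.
#' @param hole_depth depth of each hole, mm.
#' @param hole_width full width (at half depth) of each hole, mm.
#' @param blood_level optional absolute fill level, mm; surface points below
#'   it are raised to it (fluid pooling flattens the field).
#' @param heterogeneity add internal -60 HU slabs so that full-HU and
#'   two-valued dose inputs can be distinguished.
#' @return An object of class `iort_phantom`: list with `ct`
#'   (`volume_image`, HU), `surface` (exact `triangle_mesh`), `mask`
#'   (binary `volume_image`), `height` (matrix), and grid metadata
#'   `x0`, `y0`, `dx`.
#' @export
make_surgical_field <- function(seed, extent = c(150, 150), spacing = 1,
                                z_extent = 150, base_height = 55,
                                roughness = 6, n_holes = 2, hole_depth = 20,
                                hole_width = 14, blood_level = NULL,
                                heterogeneity = TRUE) {
  extent <- rep(as.numeric(extent), length.out = 2L)
  if (any(extent <= 0) || spacing <= 0 || z_extent <= 0)
    stop("invalid parameter: extents and spacing must be positive")
  if (hole_width >= min(extent) / 4)
    stop("invalid parameter: hole_width must be below extent/4")
  nx <- as.integer(round(extent[1] / spacing))
  ny <- as.integer(round(extent[2] / spacing))
  nz <- as.integer(round(z_extent / spacing))
  x0 <- spacing / 2; y0 <- spacing / 2
  xs <- x0 + (seq_len(nx) - 1) * spacing
  ys <- y0 + (seq_len(ny) - 1) * spacing
  zs <- spacing / 2 + (seq_len(nz) - 1) * spacing

  with_seed(seed, {
    # smooth relief: coarse white noise, bilinear upsampling, binomial blur
    coarse_dx <- 15
    cnx <- as.integer(ceiling(extent[1] / coarse_dx)) + 3L
    cny <- as.integer(ceiling(extent[2] / coarse_dx)) + 3L
    cz <- matrix(rnorm(cnx * cny), cnx, cny)
    fx <- (xs / coarse_dx) + 1
    fy <- (ys / coarse_dx) + 1
    relief <- bilinear_mat(cz, fx, fy)
    relief <- blur5(blur5(relief))
    relief <- relief / max(sd(as.vector(relief)), 1e-9)

    h <- base_height + roughness * relief
    # deep narrow holes in the central region (inside the beam footprint)
    if (n_holes > 0) {
      sig <- hole_width / 2.355  # full width at half depth
      ctr <- cbind(extent[1] * runif(n_holes, 0.35, 0.65),
                   extent[2] * runif(n_holes, 0.35, 0.65))
      if (n_holes > 1) {
        for (i in 2:n_holes) {
          tries <- 0
          while (min(sqrt(rowSums(sweep(ctr[seq_len(i - 1), , drop = FALSE],
                                        2, ctr[i, ])^2))) < 1.5 * hole_width &&
                 tries < 50) {
            ctr[i, ] <- c(extent[1] * runif(1, 0.3, 0.7),
                          extent[2] * runif(1, 0.3, 0.7))
            tries <- tries + 1
          }
        }
      }
      X <- outer(xs, rep(1, ny)); Y <- outer(rep(1, nx), ys)
      for (i in seq_len(n_holes)) {
        h <- h - hole_depth *
          exp(-((X - ctr[i, 1])^2 + (Y - ctr[i, 2])^2) / (2 * sig^2))
      }
    }
    h <- pmax(h, 2 * spacing)  # keep some tissue above the volume floor
    if (!is.null(blood_level)) h <- pmax(h, blood_level)

    # CT: air above the surface, textured tissue below
    ct <- array(-1000, dim = c(nx, ny, nz))
    mask <- array(0, dim = c(nx, ny, nz))
    hu_noise <- array(rnorm(nx * ny * nz, 0, 30), dim = c(nx, ny, nz))
    band <- if (heterogeneity)
      rep(ifelse((floor(zs / 12) %% 2L) == 0L, 0, -60), each = nx * ny)
    else 0
    base_hu <- array(40 + band, dim = c(nx, ny, nz)) + hu_noise
    for (iz in seq_len(nz)) {
      tissue <- zs[iz] < h
      slab <- ct[, , iz]
      slab[tissue] <- pmin(pmax(base_hu[, , iz][tissue], -400), 400)
      ct[, , iz] <- slab
      mask[, , iz] <- as.numeric(tissue)
    }

    surface <- heightfield_mesh(h, x0, y0, spacing)
    structure(list(
      ct = volume_image(ct, origin = c(x0, y0, spacing / 2),
                        spacing = rep(spacing, 3)),
      mask = volume_image(mask, origin = c(x0, y0, spacing / 2),
                          spacing = rep(spacing, 3)),
      surface = surface, height = h,
      x0 = x0, y0 = y0, dx = spacing,
      params = list(seed = seed, extent = extent, spacing = spacing,
                    blood_level = blood_level,
                    heterogeneity = heterogeneity)),
      class = "iort_phantom")
  })
}

bilinear_mat <- function(M, fx, fy) {
  nx <- nrow(M); ny <- ncol(M)
  fx <- pmin(pmax(fx, 1), nx - 1e-9)
  fy <- pmin(pmax(fy, 1), ny - 1e-9)
  ix <- pmin(floor(fx), nx - 1); iy <- pmin(floor(fy), ny - 1)
  tx <- fx - ix; ty <- fy - iy
  M00 <- M[cbind(rep(ix, length(iy)), rep(iy, each = length(ix)))]
  dim(M00) <- c(length(ix), length(iy))
  M10 <- M[cbind(rep(ix + 1, length(iy)), rep(iy, each = length(ix)))]
  dim(M10) <- c(length(ix), length(iy))
  M01 <- M[cbind(rep(ix, length(iy)), rep(iy + 1, each = length(ix)))]
  dim(M01) <- c(length(ix), length(iy))
  M11 <- M[cbind(rep(ix + 1, length(iy)), rep(iy + 1, each = length(ix)))]
  dim(M11) <- c(length(ix), length(iy))
  TX <- matrix(tx, length(ix), length(iy))
  TY <- matrix(ty, length(ix), length(iy), byrow = TRUE)
  (1 - TX) * (1 - TY) * M00 + TX * (1 - TY) * M10 +
    (1 - TX) * TY * M01 + TX * TY * M11
}

blur5 <- function(M) {
  k <- c(1, 4, 6, 4, 1) / 16
  pad <- function(v) c(v[2], v[1], v, v[length(v)], v[length(v) - 1])
  out <- apply(M, 2, function(col) stats::filter(pad(col), k)[3:(2 + length(col))])
  out <- t(apply(out, 1, function(rw) stats::filter(pad(rw), k)[3:(2 + length(rw))]))
  out
}

#' @export
print.iort_phantom <- function(x, ...) {
  cat(sprintf(
    "iort_phantom: %s voxels, surface height %.1f-%.1f mm%s\n",
    paste(dim(x$ct$values), collapse = " x "),
    min(x$height), max(x$height),
    if (is.null(x$params$blood_level)) "" else
      sprintf(", fluid level %.1f mm", x$params$blood_level)))
  invisible(x)
}

#' Place fiducial markers around the surgical field
#'
#' Inserts `n` small metallic markers (1 mm diameter) on cuboid pedestals of
#' different heights arranged on a ring around the field, outside the
#' applicator footprint, and returns the exact marker centers as ground
#' truth. Pedestal heights are measured above the local tissue surface so
#' every marker protrudes into air. A sub-voxel metal sphere is rendered
#' into the CT through a Gaussian point-spread blur (sigma 0.75 mm, peak
#' about +3000 HU), the way a 1 mm fiducial appears in a clinical CT; the
#' pedestals are added to the height map so simulated scans see them.
#'
#' @param phantom an `iort_phantom`.
#' @param n number of markers (>= 3, default 6).
#' @param heights pedestal heights above the local surface, mm (recycled to
#'   length `n`).
#' @param seed RNG seed for the angular jitter of the ring positions.
#' @return the updated phantom; element `markers` is the ground-truth
#'   `landmark_set` (CT frame).
#' @export
place_markers <- function(phantom, n = 6L, heights = NULL, seed = 1L) {
  stopifnot(inherits(phantom, "iort_phantom"))
  n <- as.integer(n)
  if (n < 3L) stop("invalid parameter: at least 3 markers are required")
  ext <- phantom$params$extent
  if (is.null(heights)) heights <- seq(8, 33, length.out = n)
  heights <- rep(heights, length.out = n)
  ring_r <- min(ext) / 2 - 14
  ct <- phantom$ct$values
  g <- vol_grid(phantom$ct)
  ax <- vol_axes(phantom$ct)
  h <- phantom$height
  marker_r <- 0.5
  psf_sigma <- 0.75
  centers <- matrix(0, n, 3)
  with_seed(seed, {
    angles <- (seq_len(n) - 1) * 2 * pi / n + runif(1, 0, 2 * pi / n)
    for (i in seq_len(n)) {
      cx <- ext[1] / 2 + ring_r * cos(angles[i])
      cy <- ext[2] / 2 + ring_r * sin(angles[i])
      ped_half <- 5
      sel_x <- which(abs(ax$x - cx) <= ped_half)
      sel_y <- which(abs(ax$y - cy) <= ped_half)
      top <- max(h[sel_x, sel_y]) + heights[i]
      # pedestal in the height map (flat top) and in the CT (+100 HU plastic)
      h[sel_x, sel_y] <- top
      sel_z <- which(ax$z < top)
      ct[sel_x, sel_y, sel_z] <- pmax(ct[sel_x, sel_y, sel_z], 100)
      if (ax$z[g$dim[3]] < top + 3)
        stop("placement error: marker would leave the CT volume")
      center <- c(cx, cy, top + marker_r)
      centers[i, ] <- center
      # sub-voxel metal sphere rendered through the CT point spread
      bx <- which(abs(ax$x - center[1]) <= 2.5)
      by <- which(abs(ax$y - center[2]) <= 2.5)
      bz <- which(abs(ax$z - center[3]) <= 2.5)
      for (jx in bx) for (jy in by) for (jz in bz) {
        d2 <- (ax$x[jx] - center[1])^2 + (ax$y[jy] - center[2])^2 +
          (ax$z[jz] - center[3])^2
        hu <- -1000 + 4100 * exp(-d2 / (2 * psf_sigma^2))
        ct[jx, jy, jz] <- max(ct[jx, jy, jz], min(hu, 3071))
      }
    }
  })
  if (n > 1) {
    dd <- as.matrix(stats::dist(centers[, 1:2]))
    diag(dd) <- Inf
    if (min(dd) < 30)
      warning("markers closer than 30 mm; consider fewer markers")
  }
  phantom$ct <- volume_image(ct, origin = g$origin, spacing = g$spacing)
  phantom$height <- h
  phantom$surface <- heightfield_mesh(h, phantom$x0, phantom$y0, phantom$dx)
  phantom$markers <- landmark_set(sprintf("M%d", seq_len(n)), centers,
                                  frame = "CT")
  phantom
}

#' Simulate a single-viewpoint range-scanner acquisition
#'
#' Samples surface points visible from one viewpoint (ray-cast occlusion on
#' the height map, so deep narrow holes self-occlude), rejects grazing
#' incidence, and perturbs each point along its view ray with Gaussian range
#' noise. Deterministic per seed.
#'
#' @param phantom an `iort_phantom` (its exact height map is scanned), or a
#'   `triangle_mesh` with height-map topology.
#' @param viewpoint scanner position, mm; must be above the surface.
#' @param noise_sigma range-noise SD along the view ray, mm.
#' @param point_density sampling density, points per mm^2 (before occlusion
#'   and incidence rejection).
#' @param max_incidence_deg maximum angle between view ray and surface
#'   normal, degrees.
#' @param seed RNG seed.
#' @return a `point_cloud` in the phantom (CT) frame.
#' @export
simulate_scan <- function(phantom, viewpoint, noise_sigma = 1.0,
                          point_density = 1.0, max_incidence_deg = 75,
                          seed = 1L) {
  hm <- phantom_heightmap(phantom)
  viewpoint <- as.numeric(viewpoint)
  if (viewpoint[3] <= max(hm$H, na.rm = TRUE))
    stop("invalid parameter: viewpoint must be above the surface")
  with_seed(seed, {
    sp <- 1 / sqrt(point_density)
    gx <- seq(hm$x0, hm$x0 + (nrow(hm$H) - 1) * hm$dx, by = sp)
    gy <- seq(hm$y0, hm$y0 + (ncol(hm$H) - 1) * hm$dx, by = sp)
    pts <- as.matrix(expand.grid(x = gx, y = gy))
    pts <- pts + matrix(runif(length(pts), -sp / 2, sp / 2), ncol = 2)
    fx <- (pts[, 1] - hm$x0) / hm$dx + 1
    fy <- (pts[, 2] - hm$y0) / hm$dx + 1
    inside <- fx >= 1 & fx <= nrow(hm$H) & fy >= 1 & fy <= ncol(hm$H)
    pts <- pts[inside, , drop = FALSE]
    fx <- fx[inside]; fy <- fy[inside]
    # exact heights on the triangulated true surface (the bilinear height
    # map differs from the triangle interpolant by the cell twist term)
    mesh <- if (inherits(phantom, "iort_phantom")) phantom$surface else phantom
    zq <- cpp_mesh_z_at(mesh$vertices, mesh$faces, pts[, 1], pts[, 2],
                        logical(0), 1e-5 * hm$dx)
    pz <- zq$zmax
    ok <- !is.na(pz)
    pts <- pts[ok, , drop = FALSE]; pz <- pz[ok]
    fx <- fx[ok]; fy <- fy[ok]

    # incidence angle from height-map gradient
    eps <- hm$dx
    gxp <- bilinear_vec(hm$H, pmin(fx + 1, nrow(hm$H)), fy)
    gxm <- bilinear_vec(hm$H, pmax(fx - 1, 1), fy)
    gyp <- bilinear_vec(hm$H, fx, pmin(fy + 1, ncol(hm$H)))
    gym <- bilinear_vec(hm$H, fx, pmax(fy - 1, 1))
    nrm <- cbind(-(gxp - gxm) / (2 * eps), -(gyp - gym) / (2 * eps), 1)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    ray <- cbind(viewpoint[1] - pts[, 1], viewpoint[2] - pts[, 2],
                 viewpoint[3] - pz)
    rayl <- sqrt(rowSums(ray^2))
    ray <- ray / rayl
    cosi <- rowSums(nrm * ray)
    keep <- cosi >= cos(max_incidence_deg * pi / 180)

    vis <- cpp_visible_from(hm$H, hm$x0, hm$y0, hm$dx, hm$dx,
                            pts[, 1], pts[, 2], pz, viewpoint,
                            hm$dx / 2, 0.05)
    keep <- keep & vis
    if (!any(keep)) stop("no visible surface points from this viewpoint")
    P <- cbind(pts[keep, 1], pts[keep, 2], pz[keep])
    if (noise_sigma > 0) {
      P <- P + ray[keep, , drop = FALSE] * rnorm(sum(keep), 0, noise_sigma)
    }
    point_cloud(P)
  })
}

#' Simulate a structured-light scanner acquisition (triangle-mesh output)
#'
#' Returns the visible-region submesh of the true surface with vertex range
#' noise along the view rays; faces with any occluded vertex are dropped and
#' small interior holes (sub-threshold occlusions) are closed by ear
#' clipping, mimicking the vendor's post-processing.
#'
#' @param phantom an `iort_phantom` or height-map `triangle_mesh`.
#' @param viewpoint scanner position, mm.
#' @param noise_sigma vertex range-noise SD, mm.
#' @param seed RNG seed.
#' @param small_hole_perimeter interior boundary loops shorter than this
#'   (mm) are closed.
#' @return a `triangle_mesh` in the phantom (CT) frame.
#' @export
simulate_mesh_scan <- function(phantom, viewpoint, noise_sigma = 0.3,
                               seed = 1L, small_hole_perimeter = 40) {
  hm <- phantom_heightmap(phantom)
  mesh <- if (inherits(phantom, "iort_phantom")) phantom$surface else phantom
  viewpoint <- as.numeric(viewpoint)
  if (viewpoint[3] <= max(hm$H, na.rm = TRUE))
    stop("invalid parameter: viewpoint must be above the surface")
  V <- mesh$vertices
  vis <- cpp_visible_from(hm$H, hm$x0, hm$y0, hm$dx, hm$dx,
                          V[, 1], V[, 2], V[, 3], viewpoint, hm$dx / 2, 0.05)
  keepf <- vis[mesh$faces[, 1]] & vis[mesh$faces[, 2]] & vis[mesh$faces[, 3]]
  if (!any(keepf)) stop("no visible faces from this viewpoint")
  sub <- drop_unused_vertices(
    triangle_mesh(V, mesh$faces[keepf, , drop = FALSE]))
  # close small interior occlusion holes
  loops <- boundary_loops(sub)
  if (length(loops) > 1L) {
    len <- vapply(loops, function(l) {
      p <- sub$vertices[l, , drop = FALSE]
      sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2)))
    }, numeric(1))
    small <- which(len < small_hole_perimeter & len < max(len))
    if (length(small)) sub <- fill_loops(sub, loops[small])
  }
  with_seed(seed, {
    if (noise_sigma > 0) {
      ray <- cbind(viewpoint[1] - sub$vertices[, 1],
                   viewpoint[2] - sub$vertices[, 2],
                   viewpoint[3] - sub$vertices[, 3])
      ray <- ray / sqrt(rowSums(ray^2))
      sub$vertices <- sub$vertices +
        ray * rnorm(nrow(sub$vertices), 0, noise_sigma)
    }
    sub$tags <- NULL
    sub
  })
}

phantom_heightmap <- function(x) {
  if (inherits(x, "iort_phantom"))
    return(list(H = x$height, x0 = x$x0, y0 = x$y0, dx = x$dx))
  if (inherits(x, "triangle_mesh")) {
    v <- x$vertices
    dx <- stats::median(cpp_knn(v, 1L, TRUE)$dist)
    x0 <- min(v[, 1]); y0 <- min(v[, 2])
    nx <- as.integer(ceiling((max(v[, 1]) - x0) / dx)) + 1L
    ny <- as.integer(ceiling((max(v[, 2]) - y0) / dx)) + 1L
    xs <- x0 + (seq_len(nx) - 1) * dx
    ys <- y0 + (seq_len(ny) - 1) * dx
    xy <- expand.grid(x = xs, y = ys)
    zs <- cpp_mesh_z_at(x$vertices, x$faces, xy$x, xy$y, logical(0), 1e-6)
    return(list(H = matrix(zs$zmax, nx, ny), x0 = x0, y0 = y0, dx = dx))
  }
  stop("expected an iort_phantom or a triangle_mesh")
}

bilinear_vec <- function(M, fx, fy) {
  nx <- nrow(M); ny <- ncol(M)
  fx <- pmin(pmax(fx, 1), nx - 1e-9)
  fy <- pmin(pmax(fy, 1), ny - 1e-9)
  ix <- pmin(floor(fx), nx - 1); iy <- pmin(floor(fy), ny - 1)
  tx <- fx - ix; ty <- fy - iy
  (1 - tx) * (1 - ty) * M[cbind(ix, iy)] +
    tx * (1 - ty) * M[cbind(ix + 1, iy)] +
    (1 - tx) * ty * M[cbind(ix, iy + 1)] +
    tx * ty * M[cbind(ix + 1, iy + 1)]
}
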