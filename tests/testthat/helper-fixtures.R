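# Shared fixtures and independent (brute-force) oracles. The oracles are
# deliberately written without the package's C++ kernels so they can validate
# them.

# --- mesh builders ---------------------------------------------------------

cube_mesh <- function(a = c(0, 0, 0), b = c(10, 10, 10)) {
  v <- rbind(c(a[1], a[2], a[3]), c(b[1], a[2], a[3]), c(b[1], b[2], a[3]),
             c(a[1], b[2], a[3]), c(a[1], a[2], b[3]), c(b[1], a[2], b[3]),
             c(b[1], b[2], b[3]), c(a[1], b[2], b[3]))
  f <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
             c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8))
  triangle_mesh(v, f)
}

# closed UV sphere with optional smooth radial perturbation r(theta, phi)
uv_sphere <- function(r = 10, nth = 24, nph = 12, center = c(0, 0, 0),
                      radial_fun = NULL) {
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  ph <- seq(0, pi, length.out = nph + 1)
  rad <- function(t, p) if (is.null(radial_fun)) r else r * radial_fun(t, p)
  v <- rbind(c(0, 0, rad(0, 0)), c(0, 0, -rad(0, pi)))
  for (j in 2:nph) for (i in seq_len(nth)) {
    rr <- rad(th[i], ph[j])
    v <- rbind(v, c(rr * sin(ph[j]) * cos(th[i]),
                    rr * sin(ph[j]) * sin(th[i]), rr * cos(ph[j])))
  }
  idx <- function(i, j) 2L + (j - 2L) * nth + i
  f <- NULL
  for (i in seq_len(nth)) {
    i2 <- i %% nth + 1L
    f <- rbind(f, c(1, idx(i, 2), idx(i2, 2)),
               c(2, idx(i2, nph), idx(i, nph)))
    for (j in 2:(nph - 1))
      f <- rbind(f, c(idx(i, j), idx(i, j + 1), idx(i2, j + 1)),
                 c(idx(i, j), idx(i2, j + 1), idx(i2, j)))
  }
  triangle_mesh(sweep(v, 2, center, "+"), f)
}

# open height-map patch z = fn(x, y) sampled on [0, w] x [0, w]
patch_mesh <- function(fn, w = 40, dx = 1, x0 = 0, y0 = 0) {
  xs <- seq(x0, x0 + w, by = dx)
  H <- outer(xs, xs, fn)
  surfdose:::heightfield_mesh(H, x0, y0, dx)
}

random_rotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# --- independent oracles ---------------------------------------------------

# exact point-to-triangle distance (plain R, region-by-region projection)
r_point_tri_dist <- function(p, a, b, c2) {
  ab <- b - a; ac <- c2 - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3); return(sqrt(sum((a + v * ab - p)^2)))
  }
  cp <- p - c2
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6); return(sqrt(sum((a + w * ac - p)^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((b + w * (c2 - b) - p)^2)))
  }
  den <- va + vb + vc
  v <- vb / den; w <- vc / den
  sqrt(sum((a + ab * v + ac * w - p)^2))
}

# brute-force min distance from each point to every triangle of a mesh
brute_point_mesh_dist <- function(P, mesh) {
  apply(P, 1, function(p) {
    min(vapply(seq_len(nrow(mesh$faces)), function(t) {
      f <- mesh$faces[t, ]
      r_point_tri_dist(p, mesh$vertices[f[1], ], mesh$vertices[f[2], ],
                       mesh$vertices[f[3], ])
    }, numeric(1)))
  })
}

# point-in-polyhedron by the generalised winding number (solid-angle sum,
# van Oosterom & Strackee) -- independent of any ray casting
winding_inside <- function(P, mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  apply(P, 1, function(p) {
    a <- sweep(V[Fc[, 1], , drop = FALSE], 2, p)
    b <- sweep(V[Fc[, 2], , drop = FALSE], 2, p)
    cc <- sweep(V[Fc[, 3], , drop = FALSE], 2, p)
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(cc^2))
    num <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
           a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
           a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    den <- la * lb * lc + rowSums(a * b) * lc + rowSums(a * cc) * lb +
           rowSums(b * cc) * la
    omega <- 2 * atan2(num, den)
    abs(sum(omega)) > 2 * pi
  })
}

# uniform water-like volume with a flat surface at `surface_z`; voxel centers
# on the half-integer lattice so the air/water interface falls exactly at
# `surface_z`
flat_water_volume <- function(surface_z, nxy = 80, nz = 120, sp = 1,
                              z_lo = -60) {
  v <- volume_image(array(0, c(nxy, nxy, nz)),
                    origin = c(-(nxy / 2) * sp + sp / 2,
                               -(nxy / 2) * sp + sp / 2, z_lo + sp / 2),
                    spacing = rep(sp, 3))
  ax <- vol_axes(v)
  for (iz in which(ax$z > surface_z)) v$values[, , iz] <- -1000
  v
}

# coarse but complete experiment configuration used by end-to-end tests
coarse_experiment_config <- function(seed = 1L) {
  cfg <- default_experiment_config(seed)
  cfg$phantom$extent <- c(90, 90)
  cfg$phantom$z_extent <- 110
  cfg$phantom$base_height <- 45
  cfg$dose$resolution <- 2
  cfg$scan$conoprobe$point_density <- 0.5
  cfg$scan$conoprobe$recon_spacing <- 2
  cfg$beam$applicator_diameter <- 50
  cfg
}

# temp file removed when the calling test block finishes
withr_local_file <- function(name, env = parent.frame()) {
  path <- file.path(tempdir(), paste0(sample.int(1e9, 1), "_", name))
  withr::defer(unlink(c(path, sub("\\.mhd$", ".raw", path))), envir = env)
  path
}
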