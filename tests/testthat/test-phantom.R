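test_that("phantom generation is bit-identical per seed and validates input", {
  a <- make_surgical_field(3, extent = c(60, 60), z_extent = 80)
  b <- make_surgical_field(3, extent = c(60, 60), z_extent = 80)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$height, b$height)
  c2 <- make_surgical_field(4, extent = c(60, 60), z_extent = 80)
  expect_false(identical(a$ct$values, c2$ct$values))
  expect_error(make_surgical_field(3, extent = c(60, 60), hole_width = 20),
               "invalid parameter")
})

test_that("fluid fill flattens the surface and raises its minimum", {
  dry <- make_surgical_field(5, extent = c(80, 80), z_extent = 100)
  lvl <- as.numeric(stats::quantile(dry$height, 0.4))
  wet <- make_surgical_field(5, extent = c(80, 80), z_extent = 100,
                             blood_level = lvl)
  expect_lt(stats::var(as.vector(wet$height)),
            stats::var(as.vector(dry$height)))
  expect_gte(min(wet$height), lvl)
  expect_identical(pmax(dry$height, lvl), wet$height)
})

test_that("the CT is air above and tissue below the exact surface", {
  ph <- make_surgical_field(6, extent = c(60, 60), z_extent = 70,
                            heterogeneity = FALSE)
  ax <- vol_axes(ph$ct)
  for (probe in list(c(10, 10), c(25, 30), c(40, 12))) {
    ix <- which.min(abs(ax$x - probe[1]))
    iy <- which.min(abs(ax$y - probe[2]))
    h <- ph$height[ix, iy]
    col <- ph$ct$values[ix, iy, ]
    expect_true(all(col[ax$z > h] == -1000))
    expect_true(all(col[ax$z < h] > -500))
  }
  # exact surface mesh agrees with the height map
  expect_lt(abs(max(ph$surface$vertices[, 3]) - max(ph$height)), 1e-12)
})

test_that("applicator placement reaches the requested maximum air gap", {
  ph <- make_surgical_field(7)
  beam <- place_applicator(ph$height, beam_config(), 33.5,
                           x0 = ph$x0, y0 = ph$y0, dx = ph$dx)
  np <- surfdose:::beam_plane_normal(beam)
  xs <- ph$x0 + (seq_len(nrow(ph$height)) - 1) * ph$dx
  ys <- ph$y0 + (seq_len(ncol(ph$height)) - 1) * ph$dx
  X <- outer(xs, rep(1, length(ys))); Y <- outer(rep(1, length(xs)), ys)
  infield <- (X - beam$position[1])^2 + (Y - beam$position[2])^2 <= 35^2
  zplane <- beam$position[3] -
    (np[1] * (X - beam$position[1]) + np[2] * (Y - beam$position[2])) / np[3]
  gap <- max((zplane - ph$height)[infield])
  expect_equal(gap, 33.5, tolerance = 1e-6)

  # fluid level that shrinks the gap to 13.2 mm
  lvl <- blood_level_for_gap(ph$height, beam, 13.2,
                             x0 = ph$x0, y0 = ph$y0, dx = ph$dx)
  wet <- pmax(ph$height, lvl)
  gap_wet <- max((zplane - wet)[infield])
  expect_equal(gap_wet, 13.2, tolerance = 0.5)
})

test_that("markers are distinct, elevated, and recoverable from the CT", {
  ph <- make_surgical_field(8)
  ph <- place_markers(ph, n = 6, seed = 9)
  expect_equal(length(ph$markers$names), 6L)
  dd <- as.matrix(stats::dist(ph$markers$positions))
  diag(dd) <- Inf
  expect_gte(min(dd), 30)
  for (i in 1:6) {
    got <- landmark_from_ct(ph$ct, ph$markers$positions[i, ], radius = 3)
    expect_lt(sqrt(sum((got - ph$markers$positions[i, ])^2)), 0.5)
  }
  expect_error(place_markers(ph, n = 2), "at least 3")
})

test_that("noiseless scans lie exactly on the surface and are seeded", {
  ph <- make_surgical_field(10, extent = c(60, 60), z_extent = 80,
                            n_holes = 0)
  vp <- c(30, 30, 300)
  cl <- simulate_scan(ph, vp, noise_sigma = 0, point_density = 1, seed = 2)
  expect_lt(point_surface_rmse(cl, ph$surface)$rmse, 1e-6)
  cl2 <- simulate_scan(ph, vp, noise_sigma = 0, point_density = 1, seed = 2)
  expect_identical(cl$points, cl2$points)
  expect_error(simulate_scan(ph, c(30, 30, 10), seed = 2),
               "above the surface")
})

test_that("deep holes self-occlude under an oblique viewpoint", {
  # single deep narrow hole; viewpoint far to the side
  ph <- make_surgical_field(11, extent = c(80, 80), z_extent = 100,
                            roughness = 0.5, n_holes = 1, hole_depth = 20,
                            hole_width = 14)
  hole_ij <- which(ph$height == min(ph$height), arr.ind = TRUE)[1, ]
  hole_xy <- c(ph$x0 + (hole_ij[1] - 1) * ph$dx,
               ph$y0 + (hole_ij[2] - 1) * ph$dx)
  vp <- c(hole_xy[1] - 150, hole_xy[2], max(ph$height) + 120)
  cl <- simulate_scan(ph, vp, noise_sigma = 0, point_density = 2, seed = 3)

  # independent visibility oracle: dense sampling along each return ray
  # against the analytic height map
  hm_at <- function(x, y) {
    fx <- (x - ph$x0) / ph$dx + 1; fy <- (y - ph$y0) / ph$dx + 1
    surfdose:::bilinear_vec(ph$height, fx, fy)
  }
  in_hole <- sqrt((cl$points[, 1] - hole_xy[1])^2 +
                  (cl$points[, 2] - hole_xy[2])^2) < 10 &
    cl$points[, 3] < max(ph$height) - 5
  pts <- cl$points[in_hole, , drop = FALSE]
  if (nrow(pts) > 0) {
    for (i in seq_len(nrow(pts))) {
      dir <- vp - pts[i, ]
      L <- sqrt(sum(dir^2)); dir <- dir / L
      ts <- seq(0.4, L - 0.4, by = 0.2)
      sx <- pts[i, 1] + ts * dir[1]; sy <- pts[i, 2] + ts * dir[2]
      sz <- pts[i, 3] + ts * dir[3]
      hh <- hm_at(sx, sy)
      expect_true(all(hh <= sz + 0.05, na.rm = TRUE))
    }
  }
  # the deep wall tilted away from the viewpoint (viewpoint side of the
  # hole) lies below the shadow line and must return no points
  wall_pts <- cl$points[sqrt((cl$points[, 1] - hole_xy[1])^2 +
                             (cl$points[, 2] - hole_xy[2])^2) < 4 &
                        cl$points[, 1] < hole_xy[1] - 0.5 &
                        cl$points[, 3] < min(ph$height) + 8, , drop = FALSE]
  expect_equal(nrow(wall_pts), 0L)
})

test_that("mesh scans return the visible submesh with range noise", {
  ph <- make_surgical_field(12, extent = c(60, 60), z_extent = 80,
                            n_holes = 0)
  vp <- c(30, 30, 280)
  clean <- simulate_mesh_scan(ph, vp, noise_sigma = 0, seed = 4)
  expect_lt(mesh_tre(clean, ph$surface)$rms, 1e-9)
  expect_identical(clean$vertices,
                   simulate_mesh_scan(ph, vp, noise_sigma = 0,
                                      seed = 4)$vertices)
  # vertex RMS displacement tracks the injected sigma within 15%
  noisy <- simulate_mesh_scan(ph, vp, noise_sigma = 0.5, seed = 4)
  disp <- sqrt(mean((noisy$vertices - clean$vertices)^2) * 3)
  expect_lt(abs(disp - 0.5) / 0.5, 0.15)
})
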