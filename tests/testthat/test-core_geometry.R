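test_that("point-surface RMSE reproduces analytic plane distances", {
  plane <- triangle_mesh(rbind(c(0, 0, 0), c(100, 0, 0), c(100, 100, 0),
                               c(0, 100, 0)),
                         rbind(c(1, 2, 3), c(1, 3, 4)))
  set.seed(11)
  on_plane <- cbind(runif(50, 1, 99), runif(50, 1, 99), 0)
  expect_equal(point_surface_rmse(on_plane, plane)$rmse, 0, tolerance = 1e-12)
  above <- cbind(runif(100, 1, 99), runif(100, 1, 99), 2)
  res <- point_surface_rmse(above, plane)
  expect_equal(res$rmse, 2.0, tolerance = 1e-12)
  expect_equal(res$distances, rep(2, 100), tolerance = 1e-12)
})

test_that("point-surface RMSE matches the exhaustive point-triangle oracle", {
  set.seed(12)
  for (rep in 1:3) {
    mesh <- uv_sphere(r = runif(1, 5, 15), nth = 10, nph = 6,
                      center = rnorm(3, 0, 3))
    P <- matrix(rnorm(30 * 3, 0, 12), ncol = 3)
    got <- point_surface_rmse(P, mesh)$distances
    want <- brute_point_mesh_dist(P, mesh)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("point-surface RMSE and TRE are rigid-motion invariant", {
  set.seed(13)
  mesh <- uv_sphere(r = 8, nth = 12, nph = 7)
  P <- matrix(rnorm(60, 0, 10), ncol = 3)
  base_pse <- point_surface_rmse(P, mesh)$rmse
  mesh2 <- patch_mesh(function(x, y) 0.1 * x + sin(y / 5), w = 20)
  base_tre <- mesh_tre(mesh2, mesh)$rms
  for (rep in 1:5) {
    R <- random_rotation(); tr <- rnorm(3, 0, 40)
    tf <- rigid_transform(R, tr)
    expect_equal(point_surface_rmse(apply_transform(P, tf),
                                    apply_transform(mesh, tf))$rmse,
                 base_pse, tolerance = 1e-6)
    expect_equal(mesh_tre(apply_transform(mesh2, tf),
                          apply_transform(mesh, tf))$rms,
                 base_tre, tolerance = 1e-6)
  }
})

test_that("mesh TRE handles identity, translation and the brute-force oracle", {
  mesh <- patch_mesh(function(x, y) sin(x / 7) + 0.05 * y, w = 20)
  same <- mesh_tre(mesh, mesh)
  expect_equal(same$rms, 0, tolerance = 1e-12)
  expect_equal(same$max, 0, tolerance = 1e-12)

  plane <- patch_mesh(function(x, y) 0 * x, w = 20)
  shifted <- plane
  shifted$vertices[, 3] <- shifted$vertices[, 3] + 1.5
  res <- mesh_tre(shifted, plane)
  # vertices at the patch rim project onto the rim edge, still 1.5 mm away
  expect_equal(res$rms, 1.5, tolerance = 1e-9)
  expect_equal(res$max, 1.5, tolerance = 1e-9)

  set.seed(14)
  small <- uv_sphere(r = 6, nth = 8, nph = 5)
  eval_m <- uv_sphere(r = 7.5, nth = 7, nph = 5, center = c(1, 0, 0.5))
  got <- mesh_tre(eval_m, small)
  want <- brute_point_mesh_dist(eval_m$vertices, small)
  expect_equal(got$rms, sqrt(mean(want^2)), tolerance = 1e-10)
  expect_equal(got$max, max(want), tolerance = 1e-10)
})

test_that("image RMSE follows the direct formula and metric properties", {
  set.seed(15)
  mk <- function(vals) volume_image(array(vals, c(6, 5, 4)))
  a <- mk(rnorm(120)); b <- mk(rnorm(120)); c3 <- mk(rnorm(120))
  expect_equal(image_rmse(a, a), 0)
  expect_equal(image_rmse(a, mk(a$values + 10)), 10)
  expect_equal(image_rmse(a, b), sqrt(mean((a$values - b$values)^2)))
  # symmetry and triangle inequality on a fixed grid
  expect_equal(image_rmse(a, b), image_rmse(b, a))
  expect_lte(image_rmse(a, c3), image_rmse(a, b) + image_rmse(b, c3) + 1e-12)
  shifted <- volume_image(a$values, origin = c(1, 0, 0))
  expect_error(image_rmse(a, shifted), "incompatible grids")
})

test_that("normal estimation recovers plane and sphere normals, oriented", {
  set.seed(16)
  plane_pts <- cbind(runif(400, 0, 50), runif(400, 0, 50), 0)
  cl <- estimate_normals(point_cloud(plane_pts), k = 10,
                         viewpoint = c(25, 25, 100))
  expect_true(all(abs(cl$normals[, 3] - 1) < 1e-6))

  # sphere sampled away from the poles; viewpoint far outside
  th <- runif(2000, 0, 2 * pi); phi <- acos(runif(2000, -0.7, 0.7))
  r <- 20
  sp <- cbind(r * sin(phi) * cos(th), r * sin(phi) * sin(th), r * cos(phi))
  outward <- sp / r
  cs <- estimate_normals(point_cloud(sp), k = 12, viewpoint = c(0, 0, 0))
  # viewpoint at center: normals face inward; compare directions to radial
  ang <- acos(pmin(1, abs(rowSums(cs$normals * outward))))
  expect_lt(stats::quantile(ang, 0.99), 5 * pi / 180)

  expect_error(estimate_normals(point_cloud(plane_pts), k = 2,
                                viewpoint = c(0, 0, 1)),
               "invalid parameter")
  expect_error(estimate_normals(point_cloud(plane_pts[1:5, ]), k = 10,
                                viewpoint = c(0, 0, 1)),
               "invalid parameter")
})

test_that("type invariants are enforced", {
  expect_error(point_cloud(matrix(numeric(0), 0, 3)), "at least one")
  expect_error(point_cloud(cbind(1, 2, Inf)), "finite")
  expect_error(point_cloud(cbind(1, 2, 3), cbind(1, 1, 0)), "unit length")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 4))), "out of range")
  expect_error(volume_image(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "strictly positive")
  expect_error(as_pseudo_ct(volume_image(array(7, c(2, 2, 2)))),
               "-1000 or 0")
  ok <- as_pseudo_ct(volume_image(array(c(-1000, 0), c(2, 2, 2))))
  expect_s3_class(ok, "pseudo_ct")
  # degenerate faces are cleaned
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 1, 2)))
  expect_equal(nrow(m$faces), 1L)
})
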