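test_that("rigid registration recovers exact transforms and reports FRE", {
  set.seed(71)
  src <- landmark_set(paste0("M", 1:6), matrix(rnorm(18, 0, 50), 6, 3),
                      "scanner")
  same <- fit_rigid_landmarks(src, src)
  expect_equal(same$fre, 0, tolerance = 1e-12)
  expect_equal(same$transform$rotation, diag(3), tolerance = 1e-9)

  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  tr <- c(5, -3, 2)
  dst <- landmark_set(src$names, sweep(src$positions %*% t(R), 2, tr, "+"),
                      "CT")
  fit <- fit_rigid_landmarks(src, dst)
  expect_lt(fit$fre, 1e-9)
  expect_equal(fit$transform$rotation, R, tolerance = 1e-9)
  expect_equal(fit$transform$translation, tr, tolerance = 1e-9)
})

test_that("noiseless recovery is exact over random rigid motions", {
  set.seed(72)
  worst <- 0
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    src <- landmark_set(paste0("M", 1:n), matrix(rnorm(3 * n, 0, 60), n, 3))
    R <- random_rotation(); tr <- rnorm(3, 0, 100)
    dst <- landmark_set(src$names, sweep(src$positions %*% t(R), 2, tr, "+"))
    fit <- fit_rigid_landmarks(src, dst)
    worst <- max(worst, fit$fre)
  }
  expect_lt(worst, 1e-9)
})

test_that("mean FRE under isotropic noise follows the Fitzpatrick relation", {
  set.seed(73)
  sigma <- 0.5; n <- 6
  base <- matrix(rnorm(18, 0, 60), n, 3)
  fres <- vapply(1:1000, function(i) {
    src <- landmark_set(paste0("M", 1:n), base)
    dst <- landmark_set(src$names, base + matrix(rnorm(3 * n, 0, sigma), n, 3))
    fit_rigid_landmarks(src, dst)$fre
  }, numeric(1))
  expected <- sigma * sqrt(3 * (1 - 2 / n))
  expect_lt(abs(mean(fres) - expected) / expected, 0.10)
})

test_that("degenerate and mismatched landmark sets are rejected", {
  two <- landmark_set(c("A", "B"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(fit_rigid_landmarks(two, two), "at least 3")
  line <- landmark_set(paste0("M", 1:4),
                       cbind(1:4, 2 * (1:4), -1 * (1:4)))
  expect_error(fit_rigid_landmarks(line, line), "collinear")
  a <- landmark_set(c("A", "B", "C"), diag(3))
  b <- landmark_set(c("A", "B", "D"), diag(3))
  expect_error(fit_rigid_landmarks(a, b), "names")
})

test_that("FRE is invariant under a common rigid motion of both sets", {
  set.seed(74)
  src <- landmark_set(paste0("M", 1:6), matrix(rnorm(18, 0, 40), 6, 3))
  dst <- landmark_set(src$names,
                      src$positions + matrix(rnorm(18, 0, 1), 6, 3))
  base <- fit_rigid_landmarks(src, dst)$fre
  for (rep in 1:5) {
    tf <- rigid_transform(random_rotation(), rnorm(3, 0, 80))
    fre <- fit_rigid_landmarks(apply_transform(src, tf),
                               apply_transform(dst, tf))$fre
    expect_equal(fre, base, tolerance = 1e-9)
  }
})

test_that("transforms apply to geometry and compose with their inverses", {
  set.seed(75)
  mesh <- uv_sphere(r = 5, nth = 10, nph = 6)
  mesh$tags <- rep("scan", nrow(mesh$faces))
  idt <- rigid_transform()
  expect_identical(apply_transform(mesh, idt)$vertices, mesh$vertices)

  tf <- rigid_transform(random_rotation(), c(10, -4, 2))
  back <- apply_transform(apply_transform(mesh, tf), invert_transform(tf))
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-9)
  expect_identical(back$tags, mesh$tags)

  pure_t <- rigid_transform(diag(3), c(1, 2, 3))
  moved <- apply_transform(mesh, pure_t)
  disp <- moved$vertices - mesh$vertices
  expect_equal(unique(round(disp, 9)), matrix(c(1, 2, 3), 1))

  # normals rotate but do not translate
  cl <- point_cloud(matrix(rnorm(30), 10, 3),
                    matrix(rep(c(0, 0, 1), each = 10), ncol = 3))
  rcl <- apply_transform(cl, tf)
  expect_equal(rcl$normals[1, ], as.vector(tf$rotation %*% c(0, 0, 1)),
               tolerance = 1e-9)
})

test_that("marker heads are located on surfaces and in CT volumes", {
  # spherical cap marker mesh around its apex
  cap <- uv_sphere(r = 2, nth = 24, nph = 16, center = c(10, 20, 5))
  keep <- cap$vertices[, 3] > 5.5
  f <- cap$faces[keep[cap$faces[, 1]] & keep[cap$faces[, 2]] &
                 keep[cap$faces[, 3]], ]
  capm <- surfdose:::drop_unused_vertices(triangle_mesh(cap$vertices, f))
  apex <- c(10, 20, 7)
  got <- landmark_from_surface(capm, apex, radius = 2)
  centroid <- colMeans(capm$vertices)
  expect_lt(sqrt(sum((got - centroid)^2)), 0.5)
  expect_error(landmark_from_surface(capm, c(100, 100, 100), 2), "not found")
  all_v <- landmark_from_surface(capm, apex, radius = 100)
  expect_equal(all_v, colMeans(capm$vertices))

  # CT marker: intensity-weighted centroid of a rendered fiducial
  ph <- make_surgical_field(77, extent = c(60, 60), z_extent = 90,
                            base_height = 30, n_holes = 0)
  # a 60 mm field forces a tight ring; the proximity warning is expected
  ph <- suppressWarnings(place_markers(ph, n = 3, seed = 3))
  for (i in 1:3) {
    got <- landmark_from_ct(ph$ct, ph$markers$positions[i, ], radius = 3)
    expect_lt(sqrt(sum((got - ph$markers$positions[i, ])^2)), 0.5)
  }
})

test_that("registered-surface TRE shrinks as landmark noise vanishes", {
  ph <- make_surgical_field(78, extent = c(80, 80), z_extent = 120,
                            base_height = 40)
  ph <- suppressWarnings(place_markers(ph, n = 6, seed = 5))
  ref <- ph$surface
  truth <- ph$markers
  tre_at <- function(sigma) {
    mean(vapply(1:5, function(rep) {
      set.seed(1000 + 17 * rep + round(100 * sigma))
      tf <- rigid_transform(random_rotation(), rnorm(3, 0, 80))
      moved <- apply_transform(ref, tf)
      src <- apply_transform(truth, tf)
      noisy <- landmark_set(src$names,
                            src$positions + matrix(rnorm(18, 0, sigma), 6, 3))
      fit <- fit_rigid_landmarks(noisy, truth)
      mesh_tre(apply_transform(moved, fit$transform), ref)$rms
    }, numeric(1)))
  }
  t0 <- tre_at(0); t1 <- tre_at(0.5); t2 <- tre_at(2)
  expect_lt(t0, 1e-9)
  expect_lt(t0, t1)
  expect_lt(t1, t2)
})
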