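test_that("HU-to-density mapping hits its anchors and interpolates linearly", {
  ct <- volume_image(array(c(0, -1000, 1000, -500, 500, 40), c(6, 1, 1)))
  rho <- hu_to_density(ct)$values
  expect_equal(rho[1], 1.0)
  expect_equal(rho[2], 0.0012)
  expect_equal(rho[3], 1.6)
  # independent evaluation of the stated piecewise map
  expect_equal(rho[4], 0.0012 + 500 / 1000 * (1.0 - 0.0012))
  expect_equal(rho[5], 1.0 + 500 / 1000 * 0.6)
  expect_true(all(diff(hu_to_density(volume_image(array(seq(-1000, 1000,
    length.out = 64), c(64, 1, 1))))$values) >= 0))
  expect_warning(hu_to_density(volume_image(array(5000, c(1, 1, 1)))),
                 "clamped")
})

test_that("radiological depth integrates density along the beam axis", {
  beam <- beam_config(bevel_angle = 0, position = c(0, 0, 40),
                      axis = c(0, 0, -1))
  # fully uniform water: depth equals geometric distance from the end plane
  water <- volume_image(array(0, c(40, 40, 120)),
                        origin = c(-19.5, -19.5, -59.5), spacing = c(1, 1, 1))
  dens <- hu_to_density(water)
  r <- radiological_depth(dens, beam, c(0, 0, 20))
  expect_equal(r$radiological, 20, tolerance = 0.1)
  expect_equal(r$geometric, 20, tolerance = 1e-9)

  # 10 mm air gap then water
  gap <- flat_water_volume(30, nxy = 40)
  r2 <- radiological_depth(hu_to_density(gap), beam, c(0, 0, 10))
  expect_equal(r2$radiological, 20, tolerance = 0.2)

  # 10 mm half-density slab then water down from z = 30
  half <- flat_water_volume(40, nxy = 40)
  axz <- vol_axes(half)$z
  hu_half <- (0.5 - 0.0012) * 1000 / (1 - 0.0012) - 1000
  half$values[, , axz > 30 & axz < 40] <- hu_half
  r3 <- radiological_depth(hu_to_density(half), beam, c(0, 0, 10))
  expect_equal(r3$radiological, 25, tolerance = 0.2)

  expect_error(radiological_depth(dens, beam, c(500, 0, 0)), "out of bounds")
})

test_that("water-phantom central axis is normalised to 100% at R100", {
  beam <- beam_config(bevel_angle = 0, position = c(0, 0, 40),
                      axis = c(0, 0, -1))
  # integer z lattice: pure water everywhere below the end plane
  water <- volume_image(array(0, c(60, 60, 121)),
                        origin = c(-29.5, -29.5, -60), spacing = c(1, 1, 1))
  axw <- vol_axes(water)
  for (iz in which(axw$z > 40)) water$values[, , iz] <- -1000
  d <- compute_dose(water, beam, grid = vol_grid(water))
  ic <- 30
  ax <- vol_axes(d)
  prof <- d$values[ic, ic, ]
  depth <- 40 - ax$z
  expect_equal(prof[depth == 20], 100, tolerance = 0.1)    # R100
  expect_equal(prof[depth == 36], 50, tolerance = 0.5)     # R50
  expect_equal(max(prof), 100, tolerance = 0.1)
  # monotone decrease beyond R100
  deep <- prof[depth >= 20 & depth <= 70][order(depth[depth >= 20 &
                                                        depth <= 70])]
  expect_true(all(diff(deep) <= 1e-9))
})

test_that("an air gap shifts the depth dose modified only by inverse square", {
  sp <- 0.5
  beam <- beam_config(bevel_angle = 0, position = c(0, 0, 40),
                      axis = c(0, 0, -1))
  mk <- function(z) flat_water_volume(z, nxy = 48, nz = 240, sp = sp)
  g <- vol_grid(mk(40))
  d0 <- compute_dose(mk(40), beam, grid = g)
  dg <- compute_dose(mk(30), beam, grid = g)
  ic <- 24
  zax <- vol_axes(d0)$z
  p0 <- d0$values[ic, ic, ]; pg <- dg$values[ic, ic, ]
  depth0 <- 40 - zax; depthg <- 30 - zax
  sel <- which(depthg >= 0.5 & depthg <= 44)
  pred <- stats::approx(depth0, p0, xout = depthg[sel])$y *
    ((1000 + depthg[sel]) / (1000 + 10 + depthg[sel]))^2
  expect_lt(max(abs(pg[sel] - pred)), 1)
})

test_that("uniform density scaling compresses the depth axis by 1/rho", {
  sp <- 0.5
  beam <- beam_config(bevel_angle = 0, position = c(0, 0, 40),
                      axis = c(0, 0, -1))
  w <- flat_water_volume(40, nxy = 48, nz = 240, sp = sp)
  g <- vol_grid(w)
  d0 <- compute_dose(w, beam, grid = g)
  half <- w
  hu_half <- (0.5 - 0.0012) * 1000 / (1 - 0.0012) - 1000
  half$values[half$values == 0] <- hu_half
  dh <- compute_dose(half, beam, grid = g)
  ic <- 24
  zax <- vol_axes(d0)$z
  depth0 <- 40 - zax
  sel <- which(depth0 >= 0.5 & depth0 <= 80)
  pred <- stats::approx(depth0, d0$values[ic, ic, ],
                        xout = 0.5 * depth0[sel])$y
  expect_lt(max(abs(dh$values[ic, ic, sel] - pred), na.rm = TRUE), 1)
})

test_that("water-assumption dose equals dose on a constructed water volume", {
  beam <- beam_config(position = c(0, 0, 40))   # 30 degree bevel
  g <- list(origin = c(-39.5, -39.5, -59.5), spacing = c(1, 1, 1),
            dim = c(80, 80, 120))
  dw <- water_assumption_dose(beam, g)
  np <- surfdose:::beam_plane_normal(beam)
  vw <- volume_image(array(-1000, c(80, 80, 120)), origin = g$origin,
                     spacing = g$spacing)
  axs <- vol_axes(vw)
  for (ix in 1:80) for (iy in 1:80) {
    dt <- np[1] * axs$x[ix] + np[2] * axs$y[iy] + np[3] * (axs$z - 40)
    vw$values[ix, iy, dt > 0] <- 0
  }
  expect_lt(max(abs(dw$values - compute_dose(vw, beam, grid = g)$values)),
            1e-6)
  # independent of any patient CT by construction; bevel 0 is symmetric
  b0 <- beam_config(bevel_angle = 0, position = c(0, 0, 40))
  d0 <- water_assumption_dose(b0, g)
  expect_lt(max(abs(d0$values - d0$values[80:1, , ])), 1e-6)
  expect_lt(max(abs(d0$values - d0$values[, 80:1, ])), 1e-6)
})

test_that("the beveled 50% isodose follows the tilted end-plane geometry", {
  beam <- beam_config(position = c(0, 0, 40))   # 30 deg, tilts along -y
  g <- list(origin = c(-49.5, -49.5, -59.5), spacing = c(1, 1, 1),
            dim = c(100, 100, 130))
  dw <- water_assumption_dose(beam, g)
  np <- surfdose:::beam_plane_normal(beam)
  axs <- vol_axes(dw)
  ix <- which.min(abs(axs$x))
  ys <- seq(-25, 25, 5)
  z50 <- vapply(ys, function(y) {
    iy <- which.min(abs(axs$y - y))
    prof <- dw$values[ix, iy, ]
    i <- min(which(prof >= 50))
    stats::approx(prof[c(i - 1, i)], axs$z[c(i - 1, i)], xout = 50)$y
  }, numeric(1))
  plane_pred <- 40 - (np[2] * ys) / np[3] - 36
  # deviation within 5% of the R50 depth scale
  expect_lt(max(abs(z50 - plane_pred)), 0.05 * 36)
  # depth of the 50% isodose varies linearly across the field
  fit <- stats::lm(z50 ~ ys)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("identical densities give identical doses for two-valued CTs", {
  ph <- make_surgical_field(55, extent = c(60, 60), z_extent = 90,
                            base_height = 35, heterogeneity = FALSE)
  ta <- ct_to_tissue_air(ph$ct)
  beam <- place_applicator(ph$height, beam_config(applicator_diameter = 40),
                           20, x0 = ph$x0, y0 = ph$y0, dx = ph$dx)
  d1 <- compute_dose(ta, beam, grid = vol_grid(ta))
  d2 <- compute_dose(ct_to_tissue_air(ta), beam, grid = vol_grid(ta))
  expect_equal(d1$values, d2$values, tolerance = 1e-12)
})

test_that("beam misses and invalid beams are rejected", {
  w <- flat_water_volume(10, nxy = 20, nz = 30)
  beam <- beam_config(position = c(500, 500, 50), axis = c(0, 0, -1))
  expect_error(compute_dose(w, beam, grid = vol_grid(w)), "empty field")
  expect_error(beam_config(pdd = list(surface_dose = 0.85, R100 = 40,
                                      R50 = 36, Rp = 45)), "R100 < R50")
})
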