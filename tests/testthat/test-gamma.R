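# small structured dose blob with smooth gradients
blob_dose <- function(seed, n = 24, sp = 2) {
  set.seed(seed)
  ctr <- c(runif(2, n * sp * 0.3, n * sp * 0.7), runif(1, n * sp * 0.3,
                                                       n * sp * 0.6))
  sig <- runif(3, 8, 16)
  ax <- (seq_len(n) - 0.5) * sp
  X <- outer(outer(ax, rep(1, n)), rep(1, n))
  Y <- outer(outer(rep(1, n), ax), rep(1, n))
  Z <- outer(outer(rep(1, n), rep(1, n)), ax)
  vals <- 100 * exp(-((X - ctr[1])^2 / (2 * sig[1]^2) +
                      (Y - ctr[2])^2 / (2 * sig[2]^2) +
                      (Z - ctr[3])^2 / (2 * sig[3]^2)))
  volume_image(vals, origin = rep(sp / 2, 3), spacing = rep(sp, 3))
}

test_that("gamma of a distribution against itself is zero everywhere", {
  d <- blob_dose(81)
  gm <- gamma_map(d, d, gamma_criteria())
  expect_equal(max(gm$values, na.rm = TRUE), 0)
  expect_equal(pass_rate(gm), 100)
})

test_that("a uniform 3.1% offset fails everywhere under 3%/3 mm", {
  # flat fields: no spatial gradient can rescue a uniform dose offset
  mk <- function(v) volume_image(array(v, c(12, 12, 12)), spacing = c(2, 2, 2))
  gm <- gamma_map(mk(50), mk(53.1), gamma_criteria(threshold_pct = 10),
                  norm_dose = 100)
  expect_equal(min(gm$values, na.rm = TRUE), 3.1 / 3, tolerance = 1e-9)
  expect_equal(pass_rate(gm), 0)
})

test_that("a 3 mm shift of a linear ramp passes at 3 mm DTA", {
  n <- 20; sp <- 1
  ax <- (seq_len(n) - 0.5) * sp
  ramp <- function(shift) {
    vals <- array(rep(pmin(pmax(2 * (ax - shift), 0), 100), each = n * n),
                  dim = c(n, n, n))
    aperm(vals, c(2, 3, 1))
  }
  r0 <- volume_image(ramp(0), spacing = rep(sp, 3))
  r3 <- volume_image(ramp(3), spacing = rep(sp, 3))
  crit <- gamma_criteria(threshold_pct = 10)
  gm <- gamma_map(r0, r3, crit, norm_dose = 100)
  # interior along the gradient axis: the shifted comparison stays on-grid
  interior <- gm$values[, 5:15, ]
  expect_lte(max(interior, na.rm = TRUE), 1 + 1e-6)
})

test_that("pass rate counts evaluated voxels only", {
  g <- list(values = array(NA_real_, c(4, 4, 4)), origin = c(0, 0, 0),
            spacing = c(1, 1, 1))
  class(g) <- "volume_image"
  g$values[1:2, , ] <- 0.5
  g$values[3, , ] <- 2
  expect_equal(pass_rate(g), 100 * 32 / 48)
  g$values[] <- NA_real_
  expect_error(pass_rate(g), "empty")
})

test_that("sorted-search gamma equals the exhaustive oracle", {
  crit <- gamma_criteria(search_radius = 6, search_step = 0.5,
                         threshold_pct = 50)
  for (seed in c(82, 83)) {
    ref <- blob_dose(seed)
    ev <- blob_dose(seed + 100)
    ev$values <- 0.5 * ev$values + 0.5 * ref$values
    fast <- gamma_map(ref, ev, crit)
    slow <- gamma_map(ref, ev, crit, method = "exhaustive")
    expect_lt(max(abs(fast$values - slow$values), na.rm = TRUE), 1e-6)
  }
})

test_that("pass rate is monotone in dose error and criteria tightness", {
  ref <- blob_dose(84)
  crit <- gamma_criteria(threshold_pct = 10)
  rates <- vapply(c(1.00, 1.02, 1.04, 1.06, 1.08, 1.10), function(f) {
    ev <- ref; ev$values <- ev$values * f
    pass_rate(gamma_map(ref, ev, crit))
  }, numeric(1))
  expect_true(all(diff(rates) <= 1e-9))

  ev <- ref; ev$values <- ev$values * 1.04
  loose <- pass_rate(gamma_map(ref, ev, crit))
  tight_dd <- pass_rate(gamma_map(ref, ev,
    gamma_criteria(dose_diff_pct = 1.5, threshold_pct = 10)))
  tight_dta <- pass_rate(gamma_map(ref, ev,
    gamma_criteria(dta_mm = 1.5, threshold_pct = 10)))
  expect_lte(tight_dd, loose)
  expect_lte(tight_dta, loose)
})

test_that("gamma respects the tissue mask and dose threshold", {
  ref <- blob_dose(85)
  ev <- ref; ev$values <- ev$values * 1.2
  mask <- volume_image(array(0, dim(ref$values)), origin = ref$origin,
                       spacing = ref$spacing)
  mask$values[1:12, , ] <- 1
  gm <- gamma_map(ref, ev, gamma_criteria(threshold_pct = 10), mask = mask)
  expect_true(all(is.na(gm$values[13:24, , ])))
  thr <- attr(gm, "norm_dose") * 0.10
  expect_true(all(is.na(gm$values[ref$values <= thr])))
  expect_error(gamma_map(ref, ev, gamma_criteria(threshold_pct = 99.9),
                         mask = mask, norm_dose = 200), "empty")
})

test_that("resampling is exact on identical grids, constants and ramps", {
  d <- blob_dose(86)
  same <- resample_to_grid(d, vol_grid(d))
  expect_identical(same$values, d$values)

  const <- volume_image(array(7, c(6, 6, 6)))
  tg <- list(origin = c(0.3, 0.2, 0.4), spacing = c(0.7, 0.9, 1.1),
             dim = c(5, 5, 4))
  expect_equal(max(abs(resample_to_grid(const, tg)$values - 7)), 0,
               tolerance = 1e-9)

  # linear ramp downsampled 2x matches the analytic ramp at voxel centers
  n <- 16
  ramp <- volume_image(array(rep(1:n, each = 1), c(n, 1, 1)) * 2,
                       origin = c(1, 0, 0), spacing = c(1, 1, 1))
  tg2 <- list(origin = c(2, 0, 0), spacing = c(2, 1, 1), dim = c(7, 1, 1))
  got <- resample_to_grid(ramp, tg2)
  expect_equal(as.vector(got$values), 2 * seq(2, 14, 2), tolerance = 1e-6)

  # nearest-neighbour keeps masks binary
  mask <- volume_image(array(rep(c(0, 1), 108), c(6, 6, 6)))
  rs <- resample_to_grid(mask, tg, mode = "nearest")
  expect_true(all(rs$values %in% c(0, 1)))

  far <- list(origin = c(1000, 0, 0), spacing = c(1, 1, 1), dim = c(4, 4, 4))
  expect_error(resample_to_grid(d, far), "disjoint")
})
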