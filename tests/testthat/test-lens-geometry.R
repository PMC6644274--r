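# Geometry of the meridional lens-surface circles.

test_that("fit_circle recovers exact circles from noise-free samples", {
  # three exact points determine the circle
  pts <- cbind(c(0, 1, 0), c(1, 0, -1))
  fit <- fit_circle(pts)
  expect_equal(fit$center_depth, 0, tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)
  expect_equal(attr(fit, "center_height_mm"), 0, tolerance = 1e-12)

  # dense noise-free arc on a lens-like circle, several apertures
  for (ap in c(4, 2, 1)) {
    h <- seq(-ap / 2, ap / 2, length.out = 50)
    z <- 13.00 - sqrt(10.21^2 - h^2)
    fit <- fit_circle(cbind(z, h))
    expect_equal(fit$center_depth, 13.00, tolerance = 1e-9)
    expect_equal(fit$radius, 10.21, tolerance = 1e-9)
    # cross-check against the exact 3-point solve on an arbitrary triple
    tri <- circle_through_3(c(z[1], h[1]), c(z[25], h[25]), c(z[50], h[50]))
    expect_equal(fit$radius, tri$radius, tolerance = 1e-9)
  }
})

test_that("fit_circle under noise is unbiased in the mean and matches a grid search", {
  # a 4 mm arc of a 10.21 mm circle carries little curvature information,
  # so single-fit radius errors of a few tenths of a mm are intrinsic at
  # 0.01 mm depth noise; the fit must instead be close to unbiased in the
  # mean and must agree with a brute-force minimiser of its own objective.
  h <- seq(-2, 2, length.out = 50)
  bias <- sapply(c(0.01, 0.005, 0.0025), function(s) {
    set.seed(11)
    radii <- replicate(400, {
      z <- 13.00 - sqrt(10.21^2 - h^2) + rnorm(50, 0, s)
      fit_circle(cbind(z, h), tilt_tol_mm = Inf)$radius
    })
    mean(radii) - 10.21
  })
  # algebraic-fit bias vanishes quadratically with the noise level
  expect_true(all(diff(abs(bias)) < 0))
  expect_lt(abs(bias[2]), 0.15)

  # brute-force minimisation of the same algebraic objective over a grid
  set.seed(12)
  z <- 13.00 - sqrt(10.21^2 - h^2) + rnorm(50, 0, 0.01)
  fit <- fit_circle(cbind(z, h), tilt_tol_mm = Inf)
  obj <- function(cz, ch, r) mean(((z - cz)^2 + (h - ch)^2 - r^2)^2)
  grid <- expand.grid(cz = seq(12.0, 14.0, by = 0.005),
                      r = seq(9.2, 11.2, by = 0.005))
  vals <- mapply(function(cz, r) obj(cz, attr(fit, "center_height_mm"), r),
                 grid$cz, grid$r)
  best <- grid[which.min(vals), ]
  # the closed-form solution minimises the same objective: no grid point
  # beats it, and the well-determined vertex (cz - r) agrees; cz and r
  # individually sit in a flat valley and are only weakly identified
  expect_lte(obj(fit$center_depth, attr(fit, "center_height_mm"), fit$radius),
             min(vals) + 1e-12)
  expect_lt(abs((fit$center_depth - fit$radius) - (best$cz - best$r)), 0.005)
})

test_that("fit_circle rejects degenerate and tilted input", {
  expect_error(fit_circle(cbind(c(0, 1), c(0, 1))), "degenerate")
  expect_error(fit_circle(cbind(0:4, 2 * (0:4))), "collinear")
  # circle whose center sits 1 mm off-axis: tilt guard must fire
  th <- seq(-0.2, 0.2, length.out = 20)
  z <- 13 - 10 * cos(th); h <- 1 + 10 * sin(th)
  expect_error(fit_circle(cbind(z, h)), "tilt exceeds tolerance")
  expect_silent(fit_circle(cbind(z, h), tilt_tol_mm = 1.5))
})

test_that("lens shape from circles reproduces the construction identities", {
  ant <- axis_circle(13.00, 10.21)
  post <- axis_circle(1.26, 6.01)
  shp <- lens_shape_from_circles(ant, post)
  expect_equal(shp$asd_mm, 2.79, tolerance = 1e-12)
  expect_equal(shp$psd_mm, 7.27, tolerance = 1e-12)
  expect_equal(shp$lt_mm, 4.48, tolerance = 1e-12)
  expect_identical(shp$psd_mm - shp$asd_mm - shp$lt_mm, 0)

  # vertex arithmetic holds even when the circles only touch and the
  # equator is undefined (ESD stays NA)
  shp2 <- lens_shape_from_circles(axis_circle(2, 1), axis_circle(4, 1))
  expect_equal(c(shp2$asd_mm, shp2$psd_mm, shp2$lt_mm), c(1, 5, 4))
  expect_true(is.na(shp2$esd_mm))

  # inverted geometry is an error
  expect_error(lens_shape_from_circles(axis_circle(10, 2), axis_circle(2, 1)),
               "inverted lens geometry")
})

test_that("equatorial depth matches the printed-mean geometry and symmetry", {
  z <- equatorial_depth(axis_circle(13.00, 10.21), axis_circle(1.26, 6.01))
  expect_equal(z, 4.229, tolerance = 1e-3)
  expect_lt(abs(z - 4.24), 0.02)

  # mirror-symmetric equal circles cross exactly at the midplane
  expect_equal(equatorial_depth(axis_circle(8, 4), axis_circle(2, 4)), 5.0,
               tolerance = 1e-12)

  expect_error(equatorial_depth(axis_circle(5, 2), axis_circle(5, 3)),
               "concentric")
  # radii far too small for the vertex separation: no crossing
  expect_error(equatorial_depth(axis_circle(3.79, 1), axis_circle(6.27, 1)),
               "do not intersect")
})

test_that("equatorial depth agrees with the circle-crossing oracle on random pairs", {
  set.seed(202)
  for (i in seq_len(1000)) {
    pr <- random_lens_circle_pair()
    z <- equatorial_depth(pr$anterior, pr$posterior)
    expect_lt(abs(z - esd_crossing_oracle(pr$anterior, pr$posterior)), 1e-6)
    expect_gt(z, pr$asd)
    expect_lt(z, pr$psd)
  }
})

test_that("narrower apertures inflate the variance of the fitted radius", {
  radius_sds <- sapply(c(4, 2), function(ap) {
    set.seed(500 + ap)
    fits <- replicate(300, {
      h <- seq(-ap / 2, ap / 2, length.out = 50)
      z <- 13.00 - sqrt(10.21^2 - h^2) + rnorm(50, 0, 0.01)
      fit_circle(cbind(z, h), tilt_tol_mm = Inf)$radius
    })
    sd(fits)
  })
  expect_gt(radius_sds[2], radius_sds[1])
})
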