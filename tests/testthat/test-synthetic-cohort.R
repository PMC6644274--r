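# Calibration and emergent structure of the synthetic cohort.

test_that("default parameters carry the cohort calibration", {
  p <- cohort_params()
  expect_equal(c(p$lt$mean, p$lt$sd), c(4.48, 0.37))
  expect_equal(c(p$asd$mean, p$asd$sd), c(2.79, 0.38))
  expect_equal(p$r_lt_asd, -0.65)
  expect_equal(unlist(p$position[c("asd", "esd", "psd", "intercept")]),
               c(asd = 0.25, esd = 0.15, psd = 0.44, intercept = -0.47))
  expect_equal(p$position$r_squared, 0.71)
  expect_equal(p$error$sd, 0.45)
  expect_equal(p$iol_thickness_mm, 1.02)
  expect_error(cohort_params(bogus = 1), "unknown cohort parameter")
  expect_error(cohort_params(lt = list(mean = 4.48, sd = -1, range = c(3, 6))),
               "infeasible calibration")
})

test_that("generation is reproducible and every record is geometrically valid", {
  a <- generate_cohort(cohort_params(n = 79, seed = 42))
  b <- generate_cohort(cohort_params(n = 79, seed = 42))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(cohort_params(n = 79, seed = 43))
  expect_false(identical(a$lt_mm, c2$lt_mm))

  expect_equal(a$psd_mm, a$asd_mm + a$lt_mm, tolerance = 1e-12)
  expect_true(all(a$esd_mm > a$asd_mm & a$esd_mm < a$psd_mm))
  expect_true(all(a$lt_mm > 0 & a$acr_mm > 0 & a$pcr_mm > 0))
  expect_equal(a$central_iol_mm, (a$anterior_iol_mm + a$posterior_iol_mm) / 2,
               tolerance = 1e-12)
  # every per-eye equatorial depth agrees with the geometry operation
  for (i in sample(nrow(a), 10)) {
    expect_equal(a$esd_mm[i],
                 esd_from_biometry(a$acr_mm[i], a$pcr_mm[i],
                                   a$asd_mm[i], a$lt_mm[i]),
                 tolerance = 1e-12)
  }
})

test_that("large cohorts reproduce the calibrated moments and emergent structure", {
  co <- generate_cohort(cohort_params(n = 5000, seed = 42))
  expect_lt(abs(mean(co$lt_mm) - 4.48), 0.02)
  expect_lt(abs(sd(co$lt_mm) - 0.37), 0.02)
  expect_lt(abs(mean(co$asd_mm) - 2.79), 0.02)
  expect_lt(abs(cor(co$lt_mm, co$asd_mm) - (-0.65)), 0.03)

  # emergent: never calibrated directly
  expect_lt(abs(cor(co$lt_mm, co$psd_mm) - 0.41), 0.04)
  expect_lt(abs(mean(co$esd_mm) - 4.24), 0.05)
  expect_lt(abs(sd(co$psd_mm) - 0.32), 0.015)
  iol_r <- as.numeric(cor(co$anterior_iol_mm,
                          co[, c("asd_mm", "esd_mm", "psd_mm")]))
  expect_true(all(abs(iol_r - c(0.67, 0.72, 0.74)) < 0.06))

  # age-controlled partial correlation of LT with ASD
  expect_lt(abs(partial_corr(co$lt_mm, co$asd_mm, co$age_years) - (-0.61)),
            0.05)

  # parameter recovery of the position model
  fit <- multiple_regression(co, "anterior_iol_mm",
                             c("asd_mm", "esd_mm", "psd_mm"))
  expect_true(all(abs(fit$terms$coefficient - c(0.25, 0.15, 0.44)) < 0.05))
  expect_lt(abs(fit$r_squared_multiple - 0.71), 0.03)

  # refractive error model: sd and correlation with the position gap
  aug <- augment_cohort(co)
  expect_lt(abs(sd(aug$prediction_error_d) - 0.45), 0.03)
  expect_lt(abs(cor(aug$prediction_error_d,
                    aug$anterior_iol_mm - aug$srkt_acd_mm) - 0.65), 0.05)
})

test_that("parameter overrides pass through to the generated cohort", {
  co <- generate_cohort(cohort_params(n = 800, seed = 9,
                                      lt = list(mean = 5.0, sd = 0.37,
                                                range = c(3.6, 6.4))))
  expect_lt(abs(mean(co$lt_mm) - 5.0), 0.05)
})

test_that("surface sampling round-trips through the circle fit", {
  co <- generate_cohort(cohort_params(n = 5, seed = 31))
  rec <- co[3, ]
  sp <- sample_surface_points(rec, aperture_mm = 4, noise_sd = 0)
  expect_equal(fit_circle(sp$anterior)$radius, rec$acr_mm, tolerance = 1e-6)
  expect_equal(fit_circle(sp$posterior)$radius, rec$pcr_mm, tolerance = 1e-6)
  ant <- fit_circle(sp$anterior); post <- fit_circle(sp$posterior)
  expect_equal(equatorial_depth(ant, post), rec$esd_mm, tolerance = 1e-6)
  expect_error(sample_surface_points(rec, aperture_mm = 0), "invalid aperture")
  expect_error(sample_surface_points(rec, aperture_mm = 12), "lens diameter")
})

test_that("radius estimates degrade with narrower apertures and improve with less noise", {
  co <- generate_cohort(cohort_params(n = 1, seed = 77))
  rec <- co[1, ]
  sds <- sapply(c(4, 2), function(ap) {
    set.seed(600 + ap)
    est <- replicate(500, fit_circle(
      sample_surface_points(rec, aperture_mm = ap, noise_sd = 0.01)$anterior,
      tilt_tol_mm = Inf)$radius)
    sd(est)
  })
  expect_gt(sds[2], sds[1])

  # median absolute ESD error shrinks as the sampling noise vanishes
  med_err <- sapply(c(0.02, 0.005, 0), function(ns) {
    set.seed(71)
    errs <- replicate(60, {
      sp <- sample_surface_points(rec, aperture_mm = 4, noise_sd = ns)
      ant <- fit_circle(sp$anterior, tilt_tol_mm = Inf)
      post <- fit_circle(sp$posterior, tilt_tol_mm = Inf)
      abs(equatorial_depth(ant, post) - rec$esd_mm)
    })
    median(errs)
  })
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[3], 1e-9)
})
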