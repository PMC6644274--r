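# lenspos

Anterior-segment biometry of the crystalline lens and prediction of the
postoperative intraocular lens (IOL) position and refraction after cataract
surgery.

Refractive surprise after cataract surgery is dominated by errors in
predicting where the implanted IOL settles. This package is aimed at
researchers in ocular biometry who want to study how the *shape* of the
crystalline lens — not just its thickness — relates to the achieved IOL
position. It provides:

* **Lens-surface geometry.** Each lens surface in a meridional OCT section
  is modelled as a circle. `fit_circle()` performs the algebraic (Kåsa)
  least-squares fit to sampled surface points; `lens_shape_from_circles()`
  derives the anterior and posterior surface depths (ASD, PSD, both
  measured from the posterior corneal vertex, corneal thickness excluded)
  and the lens thickness LT = PSD − ASD. The *equatorial surface depth*
  (ESD) is the depth of the plane through the two points where the
  anterior and posterior surface circles cross:

  ```
  z* = (z_a² − z_p² − R_a² + R_p²) / (2 (z_a − z_p))
  ```

  — the radical plane of the two circles, restricted to the intersecting
  case (`equatorial_depth()`).

* **IOL position and refraction predictors.** The Olsen C constant,
  `C = (ACD_post + t_IOL/2 − ACD_pre)/LT_pre`, with its position predictor
  `IOL_C = ACD_pre + C·LT_pre`; the SRK/T formula's predicted postoperative
  ACD (corneal radius `r = 337.5/K`, long-eye axial correction, corneal
  width and dome height via the Pythagorean construction) and its thin-lens
  vergence chain for predicted spectacle refraction; and A-constant
  optimisation that zeroes the cohort mean refractive prediction error
  (`optimize_a_constant()`).

* **Cohort statistics.** Pearson correlations with per-block Bonferroni
  correction, first-order partial correlations controlling for age,
  multiple regression with standard partial regression coefficients, and
  report/figure-data writers (`run_analyze()`).

* **A calibrated synthetic cohort.** `generate_cohort()` draws eyes whose
  moments and correlation structure match a published cataract cohort
  (n = 79; LT 4.48 ± 0.37 mm, ASD 2.79 ± 0.38 mm, corr(LT, ASD) = −0.65,
  …), with PSD forced to ASD + LT and ESD always computed through the
  circle geometry, so the full pipeline is testable without patient data.

## Worked example

```r
library(lenspos)

# mean lens geometry: anterior circle (center 13.00, radius 10.21),
# posterior circle (center 1.26, radius 6.01)
lens_shape_from_circles(axis_circle(13.00, 10.21), axis_circle(1.26, 6.01))
#> lens_shape: ACR 10.21, PCR 6.01, LT 4.48, ASD 2.79, ESD 4.23, PSD 7.27 (mm)

effective_c_constant(2.79, 4.48, 4.04, 1.02)   # -> 0.39
predict_iol_center(2.79, 4.48, 0.39)           # -> 4.54 mm
srkt_predicted_acd(24.60, 43.5, 118.4)         # -> 5.48 mm

cohort <- generate_cohort(cohort_params(n = 79, seed = 42))
res <- run_analyze(cohort, "reports")
round(attr(res$cohort, "a_constant_optimized"), 2)   # -> 118.34
round(mean(res$cohort$prediction_error_d), 2)        # -> 0.00
res$table4
#> Multiple regression: anterior_iol_mm ~ asd_mm + esd_mm + psd_mm
#>    name coefficient standardized_coefficient
#>  asd_mm       0.303                    0.397
#>  esd_mm       0.065                    0.085
#>  psd_mm       0.485                    0.515
#> Intercept -0.598, multiple R^2 = 0.745
```

The lens shape reproduces the construction identity PSD = ASD + LT and
places the lens equator at 4.23 mm; the effective C constant of 0.39 says
the IOL center settles 39% of the way through the emptied capsular bag;
after A-constant optimisation the mean refractive prediction error is
exactly zero by construction, and regressing the achieved anterior IOL
surface position on the three lens depths at n = 79 recovers the
generating linear model up to sampling noise (at n = 5000 the coefficients
and the multiple R² ≈ 0.71 are recovered closely).

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "lenspos.R", package = "lenspos"))')" \
    esd --acr 10.21 --pcr 6.01 --asd 2.79 --lt 4.48
# ESD = 4.23 mm (circles intersect: yes)
```

with `simulate`, `analyze`, `esd` and `srkt` subcommands (exit codes:
0 success, 2 usage/schema, 3 statistical precondition, 4 geometry failure).

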