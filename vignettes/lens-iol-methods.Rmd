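---
title: "Methods: lens geometry, IOL position predictors and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lens geometry, IOL position predictors and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenspos)
```

## The problem

After cataract surgery the crystalline lens is replaced by a thin
intraocular lens (IOL), and the largest single source of refractive
surprise is the error in predicting the axial position at which that IOL
settles. Third-generation power formulas such as SRK/T estimate an
*optical* postoperative anterior chamber depth (ACD) from axial length and
keratometry alone; newer approaches use the preoperative anatomy of the
lens itself. This package implements the geometric and statistical
machinery needed to study that anatomy: the depths of the anterior,
equatorial and posterior lens surfaces, two position predictors (Olsen's
C constant and SRK/T), and the cohort-level correlation/regression
analysis connecting them.

## Coordinate convention and lens geometry

All depths are in millimetres along the eye's axis, measured from the
**posterior corneal vertex**, positive toward the retina; corneal
thickness is excluded throughout. Heights are perpendicular distances from
the axis. The package works in a single meridional section and assumes the
lens axis coincides with the measurement axis.

Each lens surface is modelled as a circle in that section. From the two
fitted circles (centers on the axis at depths $z_a$, $z_p$; radii $R_a$,
$R_p$):

* ASD (anterior surface depth) $= z_a - R_a$,
* PSD (posterior surface depth) $= z_p + R_p$,
* LT (lens thickness) $=$ PSD $-$ ASD, enforced exactly as a construction
  identity,
* ESD (equatorial surface depth) $=$ the depth of the plane through the
  two intersection points of the circles,
  $$z^\* = \frac{z_a^2 - z_p^2 - R_a^2 + R_p^2}{2\,(z_a - z_p)},$$
  the radical plane of the two circles restricted to the intersecting
  case.

The closed form is validated in the test suite against an independent
numeric oracle that root-finds the crossing of the two surface height
profiles; the two agree to $10^{-6}$ mm over 1000 random lens-like pairs.
Circle pairs that do not genuinely intersect are a hard error in
`equatorial_depth()` — the equatorial construction has no meaning for them
— while `lens_shape_from_circles()` reports the vertex-derived quantities
and leaves ESD as `NA` in that (non-physiologic) case.

### Circle fitting

`fit_circle()` uses the algebraic (Kåsa) least-squares objective, solved
as a linear system after centering the coordinates: closed-form,
deterministic, and adequate for the shallow arcs a 2–5 mm pupil permits on
a 6–13 mm radius surface. Numerical behaviour worth knowing:

* On noise-free on-circle points the fit is exact to $10^{-9}$ mm down to
  1 mm apertures.
* On shallow noisy arcs the *radius* is only weakly identified: the
  objective has a flat valley along $z_{\text{center}} - R \approx$
  const (the vertex is well determined, the curvature is not). At depth
  noise of 0.01 mm on a 4 mm aperture of a 10.21 mm surface, single-fit
  radius errors of a few tenths of a millimetre are intrinsic, and the
  Kåsa estimate carries a small-arc bias (measured $-0.26$ mm at that
  noise) that vanishes quadratically as the noise shrinks. The tests
  assert exactly these properties rather than a spuriously tight
  single-fit tolerance. A Pratt or Taubin refinement could be swapped in
  behind the same interface if smaller-arc bias matters.
* A fitted center more than `tilt_tol_mm` (default 0.2 mm) off the axis is
  rejected as surface tilt rather than silently projected onto the axis.

## Position and refraction predictors

**C constant.** The effective constant is computed from postoperative
measurements as $C = (\mathrm{ACD}_{post} + t_{IOL}/2 -
\mathrm{ACD}_{pre})/\mathrm{LT}_{pre}$, and the predictor places the IOL
center at $\mathrm{ACD}_{pre} + C\cdot\mathrm{LT}_{pre}$. The two are
exact algebraic inverses, which the tests exploit as a round-trip
property. The cohort-level predictor uses the cohort *mean* C, treating C
as a property of the lens model rather than of the individual eye.

**SRK/T.** The predicted optical ACD follows the published chain —
corneal radius $r = 337.5/K$; long-eye axial correction
$\mathrm{LCOR} = -3.446 + 1.715\,\mathrm{AL} - 0.0237\,\mathrm{AL}^2$
above 24.2 mm; corneal width $C_w = -5.41 + 0.58412\,\mathrm{LCOR} +
0.098\,K$; dome height $H = r - \sqrt{r^2 - C_w^2/4}$ with the radicand
clamped at zero; ACD constant $0.62467\,A - 68.747$ and offset 3.336 —
and the refraction chain uses the retinal-thickness-corrected optical
axial length ($\mathrm{AL} + 0.65696 - 0.02029\,\mathrm{AL}$), indices
1.336/1.333, and a 12 mm spectacle vertex (a parameter; the source cohort
did not state one). All constants live in one internal table
(`srkt_constants()`) so errata can be applied in one place.

Two numerical notes. First, the "deeper ACD for steeper K" monotonicity
holds across the clinical range for normal-to-long eyes but *fails by
design of the published chain* in very long eyes with very steep corneas
(AL ≳ 27 mm, K ≳ 47.5 D), where the clamped radicand caps $H$ at $r$
while $r$ keeps shrinking with $K$; the property tests therefore cover
AL 22–26 mm. Second, `optimize_a_constant()` zeroes the cohort **mean**
error (not the median) by `uniroot` bracketing on $A \in [110, 125]$; the
residual mean error is below $10^{-6}$ D.

## Statistical surface

Pearson correlations use the product-moment estimate with the exact $t$
distribution on $n-2$ df. Bonferroni correction is applied **within each
analytic block** of the correlation table — the correlates of LT
($m = 9$), of the C-constant prediction ($m = 3$), of the achieved
anterior IOL position ($m = 3$), and of the refractive prediction error
($m = 4$) — because those blocks are the natural hypothesis families; the
family map is configurable and corrected p-values cap at 1.000. The
first-order partial correlation (single control, age) uses the closed
form; the residual-on-residual route is kept as an independent test oracle
(agreement $10^{-9}$). Multiple regression is ordinary least squares with
standard partial regression coefficients $b_j\,\mathrm{sd}(x_j)/
\mathrm{sd}(y)$ and $R^2 = 1 - SS_{res}/SS_{tot}$, cross-checked against
an explicit normal-equations solve ($10^{-8}$). No multiplicity
correction is applied to regression inference. Rounding (2 dp for mm and
diopters, 3 dp for p-values, `<0.001` below threshold) happens only in
the markdown renderers; TSV and CSV outputs keep full precision.

## The synthetic cohort

The generator emulates a 79-eye cataract cohort and is the package's test
bed; its defaults are the study conditions and are not tuned per test.

Calibrated inputs (each traceable to a published summary cell): age
69 ± 11 y; LT 4.48 ± 0.37 mm; ASD 2.79 ± 0.38 mm; ACR 10.21 ± 1.32 mm;
PCR 6.01 ± 0.53 mm; AL 24.60 ± 1.51 mm; corr(age, LT) = 0.53,
corr(LT, ASD) = −0.65, corr(LT, ACR) = −0.60, corr(LT, PCR) = −0.12; IOL
thickness 1.02 mm; anterior IOL position $= 0.25\,\mathrm{ASD} +
0.15\,\mathrm{ESD} + 0.44\,\mathrm{PSD} - 0.47 + \eta$ with
$\mathrm{sd}(\eta)$ calibrated on a 4000-eye pilot sample so the
population multiple $R^2$ is 0.71; refractive error sd 0.45 D with
correlation 0.65 to the standardized (anterior IOL − SRK/T ACD) gap.

Design choices that matter:

* **ASD given LT** is drawn from the conditional normal implied by the
  moment triplet (mean 2.79, sd 0.38, r = −0.65), i.e. slope
  $-0.65 \times 0.38/0.37 \approx -0.668$. The source analysis prints the
  rounded line $\mathrm{ASD} = -0.66\,\mathrm{LT} + 5.72$; slope, sd and
  correlation are mutually overdetermined at 2 dp, and the moments are
  what downstream checks anchor on, so the moments win.
* **PSD is never drawn** — it is ASD + LT. Its sd (≈ 0.314 by the closed
  form $\sqrt{\sigma^2_{ASD} + \sigma^2_{LT} + 2\rho\,\sigma_{ASD}
  \sigma_{LT}}$, vs 0.32 printed) and its LT correlation (≈ 0.39 vs 0.41
  printed) are *emergent validation*, not calibration.
* **ESD is never drawn** — it is computed through `equatorial_depth()` on
  the per-eye circles, so generator bugs surface as geometry failures.
  Its emergent mean (≈ 4.24 mm) matches the printed cohort mean.
* **Range handling.** The published per-variable ranges are the empirical
  extremes of 79 eyes, not distribution bounds. Enforcing them as hard
  truncation (available via `enforce_ranges = TRUE`) measurably distorts
  the calibration — the age maximum sits only 1.55 sd above the mean, and
  joint rejection drags sd(LT) from 0.37 to ≈ 0.33 and corr(LT, ASD) from
  −0.65 to ≈ −0.61 — so the default rejects only physically invalid
  geometry (non-positive dimensions, non-intersecting surface circles,
  equator outside the lens), and the rejection count is recorded in the
  output's attributes.
* **Keratometry is an assumption.** The source cohort's K distribution is
  unreported; K ~ N(43.5, 1.5) D is a typical adult distribution, and it
  is quarantined: no calibrated or checked quantity depends on it. For the
  same reason the cohort mean of the SRK/T predicted ACD (printed
  5.68 ± 0.41 mm) is *not* reproducible here and is not asserted anywhere.
  IOL power is chosen per eye by the analytic SRK/T inversion targeting
  −1.5 D, rounded to commercial 0.5 D steps within 10–25.5 D, with
  generation A constant 118.4.
* **Seeding.** One master seed; the pilot calibration and the cohort draw
  use fixed-offset sub-seeds derived from it, so `generate_cohort()` is
  byte-reproducible and the pilot does not perturb the cohort stream.

What the generator does **not** emulate: measurement error in the traced
circles (surface sampling noise is available separately through
`sample_surface_points()`, but the cohort's ESD is the exact geometric
value, whereas a device's ESD inherits ACR/PCR fitting error); age-related
skewness of the real cohort (all conditionals are normal); longitudinal
lens growth; axial-length/keratometry correlation with lens shape; and
per-eye A-constant heterogeneity. Passing cohort-level tests therefore
demonstrates internal consistency of the pipeline under the published
correlation structure, not device-level accuracy on real OCT data.

## Problem sizes and determinism

The test suite and the reproduction script use n = 79 for cohort-scale
checks (the published cohort size), n = 5000 for emergent-moment checks
(sampling sd of a correlation ≈ 0.012 there, comfortably inside the
±0.04–0.06 bands), 400–500 replicates for Monte-Carlo variance
comparisons, and a 4000-eye pilot for the position-noise calibration; the
whole suite runs in well under a minute. All formula evaluations are pure
functions; reports are deterministic given cohort and configuration.

## Known limitations

* Single-meridian geometry; no lens tilt/decentration modelling beyond
  the tilt-tolerance guard, and no two-meridian averaging.
* The Kåsa fit's small-arc radius bias (see above) is inherited by any
  ESD computed from refitted noisy surfaces.
* The C-constant predictor uses the cohort mean C; per-eye C modelling
  (e.g. LT-adjusted) is deliberately out of scope.
* Only the SRK/T formula is implemented; Holladay, Hoffer Q, Haigis,
  Barrett and full Olsen ray tracing are out of scope, as are toric
  powers and cylinder handling.
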