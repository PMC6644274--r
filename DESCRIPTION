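Package: lenspos
Title: Crystalline Lens Geometry and Intraocular Lens Position Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for anterior-segment biometry of the crystalline lens and
    for predicting the postoperative intraocular lens (IOL) position and
    refraction after cataract surgery. Fits meridional circles to lens
    surface profiles, derives the anterior, equatorial and posterior surface
    depths (the equatorial depth via the radical-plane construction on the
    two fitted circles), implements the Olsen C-constant position predictor
    and the SRK/T vergence formula with A-constant optimisation, and
    reproduces a cohort statistical analysis (Pearson and age-controlled
    partial correlations with Bonferroni correction, multiple regression
    with standardized coefficients). Includes a calibrated synthetic-cohort
    generator so the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
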