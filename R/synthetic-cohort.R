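# Synthetic cohort generator.
#
# Generates per-eye biometry records with the marginal moments and
# correlation structure of a cataract-surgery cohort, so the geometry,
# formula and statistics modules can be exercised end-to-end without
# patient data. Two quantities are deliberately never drawn:
#   * PSD is forced to ASD + LT (construction identity), so its standard
#     deviation and its correlation with LT are emergent checks, not
#     calibrated inputs;
#   * ESD is always computed through the circle-intersection geometry, so a
#     generator bug surfaces as a geometry invariant failure.

#' Default calibration of the synthetic cohort
#'
#' Marginal means/SDs and truncation ranges for age, lens thickness (LT),
#' anterior surface depth (ASD), anterior/posterior curvature radii
#' (ACR/PCR) and axial length; the pairwise correlations of LT with age,
#' ASD, ACR and PCR; the linear model placing the anterior IOL surface at
#' `0.25 ASD + 0.15 ESD + 0.44 PSD - 0.47` plus noise calibrated to a
#' multiple R^2 of 0.71; and the refractive-error model (sd 0.45 D,
#' correlation 0.65 with the standardized gap between the achieved IOL
#' position and the SRK/T predicted ACD). Keratometry is not part of the
#' calibrated surface: its normal(43.5, 1.5) distribution is a documented
#' assumption, quarantined so nothing downstream that is checked against
#' cohort statistics depends on it.
#'
#' @param n Number of eyes; default 79.
#' @param seed Master seed; every random draw derives from it.
#' @param ... Named overrides for any listed field.
#' @return An object of class `cohort_params` (a named list).
#' @export
cohort_params <- function(n = 79, seed = 42, ...) {
  p <- list(
    n = n, seed = seed,
    age   = list(mean = 69,    sd = 11,   range = c(26, 86)),
    lt    = list(mean = 4.48,  sd = 0.37, range = c(3.64, 5.40)),
    asd   = list(mean = 2.79,  sd = 0.38, range = c(1.75, 3.80)),
    acr   = list(mean = 10.21, sd = 1.32, range = c(7.73, 13.97)),
    pcr   = list(mean = 6.01,  sd = 0.53, range = c(4.72, 7.67)),
    al    = list(mean = 24.60, sd = 1.51, range = c(21.74, 28.47)),
    k     = list(mean = 43.5,  sd = 1.5),           # assumption, see vignette
    r_age_lt = 0.53, r_lt_asd = -0.65, r_lt_acr = -0.60, r_lt_pcr = -0.12,
    position = list(asd = 0.25, esd = 0.15, psd = 0.44, intercept = -0.47,
                    r_squared = 0.71),
    error = list(sd = 0.45, r_with_position_gap = 0.65),
    iol_thickness_mm = 1.02,
    a_constant = 118.4,
    target_refraction_d = -1.5,
    power_step_d = 0.5,
    power_range_d = c(10, 25.5),
    aperture_mm = 4.0,
    pilot_n = 4000,
    enforce_ranges = FALSE
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown cohort parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  if (p$n < 1) stop("n must be at least 1")
  for (v in c("age", "lt", "asd", "acr", "pcr", "al", "k"))
    if (p[[v]]$sd <= 0) stop("infeasible calibration: sd of ", v, " must be positive")
  rs <- c(p$r_age_lt, p$r_lt_asd, p$r_lt_acr, p$r_lt_pcr,
          p$error$r_with_position_gap)
  if (any(abs(rs) > 1)) stop("infeasible calibration: |r| must be <= 1")
  if (p$position$r_squared <= 0 || p$position$r_squared >= 1)
    stop("infeasible calibration: target R^2 must be in (0, 1)")
  invisible(p)
}

# Deterministic sub-seed derivation: one master seed, fixed odd offsets per
# stage, reduced into 32-bit integer range.
derive_seed <- function(master, stage) {
  offs <- c(pilot = 1000003L, cohort = 2000029L, surface = 3000017L)
  if (!stage %in% names(offs)) stop("unknown seeding stage: ", stage)
  as.integer((as.numeric(master) + offs[[stage]]) %% 2147483629)
}

# Vectorized radical-plane depth with validity flags; NA where the circle
# pair has no real intersection. Mirrors equatorial_depth() for batch use.
esd_vectorized <- function(asd, acr, psd, pcr) {
  za <- asd + acr
  zp <- psd - pcr
  dz <- za - zp
  z <- ifelse(dz == 0, NA_real_, (za^2 - zp^2 - acr^2 + pcr^2) / (2 * dz))
  h2 <- acr^2 - (z - za)^2
  ifelse(is.na(z) | h2 <= 0, NA_real_, z)
}

# Draw the preoperative lens block (age, LT, ASD, ACR, PCR and the derived
# PSD/ESD), rejecting rows that fail physical validity (positive
# dimensions, intersecting surface circles with the equator between the
# vertices). The `range` entries record the observed extremes of the
# emulated cohort; they are enforced as hard bounds only when
# `enforce_ranges = TRUE`, because joint rejection at those bounds
# (notably the asymmetric age maximum) measurably attenuates the
# calibrated moments and correlations. Uses the current RNG stream.
draw_lens_block <- function(n, p) {
  cols <- c("age_years", "lt_mm", "asd_mm", "acr_mm", "pcr_mm",
            "psd_mm", "esd_mm")
  got <- matrix(numeric(0), ncol = length(cols),
                dimnames = list(NULL, cols))
  rejected <- 0L
  while (nrow(got) < n) {
    m <- max(2L * (n - nrow(got)), 64L)
    lt <- stats::rnorm(m, p$lt$mean, p$lt$sd)
    zlt <- (lt - p$lt$mean) / p$lt$sd
    cond <- function(spec, r) {
      spec$mean + r * spec$sd * zlt +
        stats::rnorm(m, 0, spec$sd * sqrt(1 - r^2))
    }
    age <- cond(p$age, p$r_age_lt)
    asd <- cond(p$asd, p$r_lt_asd)
    acr <- cond(p$acr, p$r_lt_acr)
    pcr <- cond(p$pcr, p$r_lt_pcr)
    psd <- asd + lt
    esd <- esd_vectorized(asd, acr, psd, pcr)
    ok <- lt > 0 & asd > 0 & acr > 0 & pcr > 0 &
      !is.na(esd) & esd > asd & esd < psd
    if (isTRUE(p$enforce_ranges)) {
      in_range <- function(x, spec) x >= spec$range[1] & x <= spec$range[2]
      ok <- ok & in_range(age, p$age) & in_range(lt, p$lt) &
        in_range(asd, p$asd) & in_range(acr, p$acr) & in_range(pcr, p$pcr)
    }
    rejected <- rejected + sum(!ok)
    got <- rbind(got, cbind(age_years = age, lt_mm = lt, asd_mm = asd,
                            acr_mm = acr, pcr_mm = pcr, psd_mm = psd,
                            esd_mm = esd)[ok, , drop = FALSE])
  }
  out <- as.data.frame(got[seq_len(n), , drop = FALSE])
  attr(out, "rejected") <- rejected
  out
}

#' Calibrate the IOL-position noise to the target multiple R^2
#'
#' The anterior IOL surface position is modelled as a linear function of
#' ASD, ESD and PSD plus Gaussian noise. Because ESD is a nonlinear
#' function of the drawn geometry, the variance of the linear predictor has
#' no closed form; it is estimated once on a pilot lens sample (seed
#' derived from the master seed) and the noise sd is set so the population
#' explained-variance fraction equals the target R^2:
#' `sd_noise = sd_fitted * sqrt((1 - R2) / R2)`.
#'
#' @param params A `cohort_params` object.
#' @return Noise standard deviation, mm.
#' @export
calibrate_position_noise <- function(params) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(params$seed, "pilot"))
  pilot <- draw_lens_block(params$pilot_n, params)
  b <- params$position
  fitted <- b$asd * pilot$asd_mm + b$esd * pilot$esd_mm +
    b$psd * pilot$psd_mm + b$intercept
  stats::sd(fitted) * sqrt((1 - b$r_squared) / b$r_squared)
}

#' Generate a synthetic cohort of eyes
#'
#' Produces one row per eye with the full preoperative biometry, the
#' implanted IOL, the achieved postoperative IOL surface positions and the
#' postoperative refraction. Deterministic given `params` (including its
#' master seed). Eyes with physically invalid geometry (non-positive
#' dimensions, surface circles that fail to intersect, or an equator
#' outside the lens) are rejected and redrawn; the count is recorded in
#' the `rejected` attribute. Setting `enforce_ranges = TRUE` additionally
#' rejects draws outside the recorded cohort extremes, at the cost of
#' attenuating the calibrated moments.
#'
#' Generation model, in order: (age, LT) bivariate normal; ASD conditionally
#' normal given LT; ACR and PCR conditionally normal given LT; PSD = ASD +
#' LT; ESD through the circle geometry; anterior IOL position linear in
#' (ASD, ESD, PSD) plus calibrated noise; AL truncated normal, K normal;
#' IOL power from the SRK/T inversion at the target refraction, rounded to
#' the commercial half-diopter step and clamped to the available range;
#' postoperative spherical equivalent = predicted refraction + an error
#' term with the configured sd and the configured correlation with the
#' standardized (anterior IOL - SRK/T ACD) gap.
#'
#' @param params A `cohort_params` object; see [cohort_params()].
#' @return A data frame of class `eye_cohort`, one row per eye, with
#'   attributes `params`, `rejected` and `position_noise_sd`.
#' @examples
#' cohort <- generate_cohort(cohort_params(n = 79, seed = 42))
#' summary(cohort$lt_mm)
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  noise_sd <- calibrate_position_noise(params)
  set.seed(derive_seed(params$seed, "cohort"))
  n <- params$n
  lens <- draw_lens_block(n, params)

  b <- params$position
  fitted <- b$asd * lens$asd_mm + b$esd * lens$esd_mm +
    b$psd * lens$psd_mm + b$intercept
  anterior_iol <- fitted + stats::rnorm(n, 0, noise_sd)
  pos <- iol_positions(anterior_iol, params$iol_thickness_mm)

  # AL and K are independent of the lens block; AL is range-limited only
  # when ranges are enforced.
  al <- stats::rnorm(n, params$al$mean, params$al$sd)
  if (isTRUE(params$enforce_ranges)) {
    bad <- al < params$al$range[1] | al > params$al$range[2]
    while (any(bad)) {
      al[bad] <- stats::rnorm(sum(bad), params$al$mean, params$al$sd)
      bad <- al < params$al$range[1] | al > params$al$range[2]
    }
  }
  k <- stats::rnorm(n, params$k$mean, params$k$sd)

  a_const <- params$a_constant
  power_raw <- srkt_power_for_target(al, k, a_const, params$target_refraction_d)
  power <- pmin(pmax(round(power_raw / params$power_step_d) * params$power_step_d,
                     params$power_range_d[1]), params$power_range_d[2])
  pred_ref <- srkt_predicted_refraction(al, k, a_const, power)
  srkt_acd <- srkt_predicted_acd(al, k, a_const)

  gap <- anterior_iol - srkt_acd
  zgap <- (gap - mean(gap)) / stats::sd(gap)
  rho <- params$error$r_with_position_gap
  err <- params$error$sd * (rho * zgap + sqrt(1 - rho^2) * stats::rnorm(n))
  postop_se <- pred_ref + err

  cohort <- data.frame(
    eye_id = sprintf("eye%03d", seq_len(n)),
    age_years = lens$age_years,
    al_mm = al, mean_k_d = k,
    acr_mm = lens$acr_mm, pcr_mm = lens$pcr_mm,
    lt_mm = lens$lt_mm, asd_mm = lens$asd_mm,
    esd_mm = lens$esd_mm, psd_mm = lens$psd_mm,
    iol_power_d = power, iol_thickness_mm = params$iol_thickness_mm,
    a_constant = a_const,
    anterior_iol_mm = pos$anterior_mm,
    central_iol_mm = pos$central_mm,
    posterior_iol_mm = pos$posterior_mm,
    srkt_acd_mm = srkt_acd,
    predicted_refraction_d = pred_ref,
    postop_se_d = postop_se,
    stringsAsFactors = FALSE
  )
  structure(cohort, class = c("eye_cohort", "data.frame"),
            params = params, rejected = attr(lens, "rejected"),
            position_noise_sd = noise_sd)
}

#' Sample noisy surface points from one eye's lens circles
#'
#' Reconstructs the two meridional surface circles from a cohort row and
#' samples points on each within the pupil aperture, adding Gaussian noise
#' along the depth axis (the axial direction in which an OCT scan measures).
#' Feeding the samples back through [fit_circle()] recovers the curvature
#' radii, degraded gracefully with noise and with narrower apertures.
#'
#' @param record One row of an `eye_cohort` data frame (or any list with
#'   `asd_mm`, `acr_mm`, `psd_mm`, `pcr_mm`).
#' @param aperture_mm Chord width of the sampled arc, mm (> 0, <= 10).
#' @param n_points Points per surface; default 50.
#' @param noise_sd Gaussian depth noise sd, mm; default 0 (exact points).
#' @return List with elements `anterior` and `posterior`, each a two-column
#'   matrix `(depth_mm, height_mm)`, plus an `aperture_mm` attribute.
#' @export
sample_surface_points <- function(record, aperture_mm = 4, n_points = 50,
                                  noise_sd = 0) {
  if (aperture_mm <= 0) stop("invalid aperture")
  if (aperture_mm > 10) stop("aperture exceeds the physical lens diameter")
  h <- seq(-aperture_mm / 2, aperture_mm / 2, length.out = n_points)
  za <- record$asd_mm + record$acr_mm   # anterior circle center depth
  zp <- record$psd_mm - record$pcr_mm   # posterior circle center depth
  ant_z <- za - sqrt(record$acr_mm^2 - h^2)
  post_z <- zp + sqrt(record$pcr_mm^2 - h^2)
  if (noise_sd > 0) {
    ant_z <- ant_z + stats::rnorm(n_points, 0, noise_sd)
    post_z <- post_z + stats::rnorm(n_points, 0, noise_sd)
  }
  out <- list(anterior = cbind(depth_mm = ant_z, height_mm = h),
              posterior = cbind(depth_mm = post_z, height_mm = h))
  attr(out, "aperture_mm") <- aperture_mm
  out
}
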