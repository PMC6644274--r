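# IOL position and refraction predictors.
#
# Two predictors of the postoperative lens position are implemented: the
# Olsen C constant, which places the IOL center at a fixed fraction of the
# preoperative lens thickness behind the preoperative anterior chamber depth,
# and the SRK/T formula's optical (non-anatomic) postoperative ACD derived
# from axial length and keratometry. The SRK/T vergence chain then converts
# an implanted power into a predicted spectacle-plane refraction.

# All SRK/T numerical constants live here so an erratum can be applied in
# one place. Values follow the published third-generation formula.
srkt_constants <- function() {
  list(
    n_aqueous       = 1.336,    # aqueous/vitreous refractive index
    n_cornea        = 1.333,    # fictitious corneal index; ncm1 = 0.333
    ncm1            = 0.333,
    radius_from_k   = 337.5,    # corneal radius r = 337.5 / K
    lcor_a          = -3.446,   # long-eye axial correction polynomial
    lcor_b          = 1.715,
    lcor_c          = -0.0237,
    lcor_threshold  = 24.2,
    cw_a            = -5.41,    # corneal width regression
    cw_b            = 0.58412,
    cw_c            = 0.098,
    acd_const_slope = 0.62467,  # ACD constant from the A constant
    acd_const_int   = -68.747,
    acd_offset      = 3.336,    # mean-height offset in the ACD estimate
    ret_thick_int   = 0.65696,  # retinal thickness correction
    ret_thick_slope = -0.02029,
    vertex_mm       = 12        # default spectacle vertex distance
  )
}

check_biometry_range <- function(al, k) {
  if (any(!is.finite(al)) || any(!is.finite(k)) ||
      any(al <= 15) || any(al >= 40) || any(k <= 30) || any(k >= 60))
    stop("biometry out of supported range: need 15 < AL < 40 mm and 30 < K < 60 D")
}

#' Effective (postoperatively measured) C constant
#'
#' The Olsen C constant expresses where the IOL center settles inside the
#' emptied capsular bag as a fraction of the preoperative lens thickness:
#' `C = (ACD_post + IOL_thickness/2 - ACD_pre) / LT_pre`, where `ACD_post`
#' is the postoperative anterior IOL surface depth and `ACD_pre` the
#' preoperative anterior lens surface depth (both from the posterior
#' cornea, corneal thickness excluded).
#'
#' @param acd_pre Preoperative anterior chamber depth (= anterior lens
#'   surface depth), mm.
#' @param lt Preoperative lens thickness, mm (> 0).
#' @param anterior_iol Postoperative anterior IOL surface depth, mm.
#' @param iol_thickness IOL central thickness, mm.
#' @return The dimensionless C constant (vectorized over its arguments).
#' @examples
#' effective_c_constant(2.79, 4.48, 4.04, 1.02)  # about 0.39
#' @export
effective_c_constant <- function(acd_pre, lt, anterior_iol, iol_thickness) {
  if (any(lt <= 0)) stop("invalid lens thickness")
  (anterior_iol + iol_thickness / 2 - acd_pre) / lt
}

#' Predict the central IOL position from the C constant
#'
#' `IOL_C = ACD_pre + C * LT_pre`: the predicted postoperative central IOL
#' depth. `c = 0` pins the IOL at the anterior capsule plane, `c = 1` at
#' the posterior capsule plane.
#'
#' @param acd_pre Preoperative anterior chamber depth, mm.
#' @param lt Preoperative lens thickness, mm (> 0).
#' @param c C constant (dimensionless).
#' @return Predicted central IOL depth, mm.
#' @examples
#' predict_iol_center(2.79, 4.48, 0.39)  # about 4.54 mm
#' @export
predict_iol_center <- function(acd_pre, lt, c) {
  if (any(lt <= 0)) stop("invalid lens thickness")
  acd_pre + c * lt
}

#' Anterior, central and posterior IOL surface depths
#'
#' @param anterior_iol Anterior IOL surface depth, mm.
#' @param iol_thickness IOL central thickness, mm (> 0).
#' @return A data frame with columns `anterior_mm`, `central_mm`,
#'   `posterior_mm`; central is always the midpoint of the other two.
#' @export
iol_positions <- function(anterior_iol, iol_thickness) {
  if (any(iol_thickness <= 0)) stop("IOL thickness must be positive")
  data.frame(anterior_mm = anterior_iol,
             central_mm = anterior_iol + iol_thickness / 2,
             posterior_mm = anterior_iol + iol_thickness)
}

#' SRK/T predicted postoperative anterior chamber depth
#'
#' The formula's optical ACD (not an anatomic depth): corneal radius
#' `r = 337.5/K`; axial length corrected for long eyes
#' (`LCOR = -3.446 + 1.715 AL - 0.0237 AL^2` above 24.2 mm); computed
#' corneal width `Cw = -5.41 + 0.58412 LCOR + 0.098 K`; corneal dome height
#' `H = r - sqrt(r^2 - Cw^2/4)` (radicand clamped at zero); and
#' `ACD = H + 0.62467 A - 68.747 - 3.336` where `A` is the lens A constant.
#' A steeper cornea (larger K) yields a deeper predicted ACD.
#'
#' @param al Axial length, mm (15-40).
#' @param k Mean keratometry, diopters (30-60).
#' @param a_constant IOL A constant (roughly 110-125).
#' @return Predicted optical ACD, mm (vectorized).
#' @examples
#' srkt_predicted_acd(24.60, 43.5, 118.4)
#' @export
srkt_predicted_acd <- function(al, k, a_constant) {
  check_biometry_range(al, k)
  sc <- srkt_constants()
  r <- sc$radius_from_k / k
  lcor <- ifelse(al <= sc$lcor_threshold, al,
                 sc$lcor_a + sc$lcor_b * al + sc$lcor_c * al^2)
  cw <- sc$cw_a + sc$cw_b * lcor + sc$cw_c * k
  h <- r - sqrt(pmax(r^2 - cw^2 / 4, 0))
  acd_const <- sc$acd_const_slope * a_constant + sc$acd_const_int
  h + acd_const - sc$acd_offset
}

# Optical axial length with the SRK/T retinal thickness correction.
srkt_optical_al <- function(al) {
  sc <- srkt_constants()
  al + sc$ret_thick_int + sc$ret_thick_slope * al
}

#' SRK/T predicted refraction for an implanted power
#'
#' Thin-lens vergence refraction at the spectacle plane for a given IOL
#' power, using the SRK/T optical axial length (axial length plus the
#' retinal thickness correction `0.65696 - 0.02029 AL`) and refractive
#' indices 1.336 (aqueous) / 1.333 (cornea).
#'
#' @inheritParams srkt_predicted_acd
#' @param iol_power Implanted IOL power, diopters (-10 to 40).
#' @param vertex Spectacle vertex distance, mm; default 12.
#' @return Predicted spectacle refraction, diopters (vectorized).
#' @examples
#' srkt_predicted_refraction(24.60, 43.5, 118.4, 19.5)
#' @export
srkt_predicted_refraction <- function(al, k, a_constant, iol_power,
                                      vertex = srkt_constants()$vertex_mm) {
  check_biometry_range(al, k)
  if (any(iol_power <= -10) || any(iol_power >= 40))
    stop("biometry out of supported range: IOL power must be in (-10, 40) D")
  sc <- srkt_constants()
  na <- sc$n_aqueous; ncm1 <- sc$ncm1
  r <- sc$radius_from_k / k
  lopt <- srkt_optical_al(al)
  acd <- srkt_predicted_acd(al, k, a_constant)
  num <- 1000 * na * (na * r - ncm1 * lopt) -
    iol_power * (lopt - acd) * (na * r - ncm1 * acd)
  den <- na * (vertex * (na * r - ncm1 * lopt) + lopt * r) -
    0.001 * iol_power * (lopt - acd) * (vertex * (na * r - ncm1 * acd) + acd * r)
  if (any(!is.finite(den)) || any(abs(den) < 1e-8))
    stop("non-physical vergence configuration")
  num / den
}

#' SRK/T emmetropia power
#'
#' The IOL power at which the predicted refraction is exactly zero.
#'
#' @inheritParams srkt_predicted_acd
#' @return Emmetropia IOL power, diopters (vectorized).
#' @export
srkt_emmetropia_power <- function(al, k, a_constant) {
  check_biometry_range(al, k)
  sc <- srkt_constants()
  na <- sc$n_aqueous; ncm1 <- sc$ncm1
  r <- sc$radius_from_k / k
  lopt <- srkt_optical_al(al)
  acd <- srkt_predicted_acd(al, k, a_constant)
  den <- (lopt - acd) * (na * r - ncm1 * acd)
  if (any(!is.finite(den)) || any(abs(den) < 1e-8))
    stop("non-physical vergence configuration")
  1000 * na * (na * r - ncm1 * lopt) / den
}

#' SRK/T power for a target refraction
#'
#' Analytic inversion of the vergence chain: the IOL power whose predicted
#' spectacle refraction equals `target_ref`.
#'
#' @inheritParams srkt_predicted_refraction
#' @param target_ref Target spectacle refraction, diopters.
#' @return IOL power, diopters (vectorized).
#' @export
srkt_power_for_target <- function(al, k, a_constant, target_ref,
                                  vertex = srkt_constants()$vertex_mm) {
  check_biometry_range(al, k)
  sc <- srkt_constants()
  na <- sc$n_aqueous; ncm1 <- sc$ncm1
  r <- sc$radius_from_k / k
  lopt <- srkt_optical_al(al)
  acd <- srkt_predicted_acd(al, k, a_constant)
  num <- 1000 * na * (na * r - ncm1 * lopt) -
    target_ref * na * (vertex * (na * r - ncm1 * lopt) + lopt * r)
  den <- (lopt - acd) * (na * r - ncm1 * acd) -
    0.001 * target_ref * (lopt - acd) * (vertex * (na * r - ncm1 * acd) + acd * r)
  if (any(!is.finite(den)) || any(abs(den) < 1e-8))
    stop("non-physical vergence configuration")
  num / den
}

#' Refractive prediction error
#'
#' Measured postoperative spherical equivalent minus the formula-predicted
#' refraction, diopters. Positive errors are hyperopic surprises.
#'
#' @param measured_se Measured postoperative spherical equivalent, D.
#' @param predicted Predicted refraction, D.
#' @return Prediction error, D (vectorized).
#' @export
refractive_prediction_error <- function(measured_se, predicted) {
  measured_se - predicted
}

#' Optimize the A constant to zero the mean prediction error
#'
#' Finds, by scalar root bracketing on A in [110, 125], the A constant at
#' which the cohort mean of (measured spherical equivalent - SRK/T predicted
#' refraction) is zero. Zeroing the mean (not the median) matches the usual
#' constant-optimisation convention.
#'
#' @param cohort Data frame with columns `al_mm`, `mean_k_d`, `iol_power_d`,
#'   `postop_se_d`.
#' @param interval Bracketing interval for A; default `c(110, 125)`.
#' @param tol Root-finding tolerance on A; default 1e-10 (gives a mean
#'   error well below 1e-6 D).
#' @return The optimized A constant (numeric scalar).
#' @export
optimize_a_constant <- function(cohort, interval = c(110, 125), tol = 1e-10) {
  need <- c("al_mm", "mean_k_d", "iol_power_d", "postop_se_d")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(cohort) < 2L) stop("need at least 2 eyes with measured refraction")
  mean_err <- function(a) {
    pred <- srkt_predicted_refraction(cohort$al_mm, cohort$mean_k_d, a,
                                      cohort$iol_power_d)
    mean(cohort$postop_se_d - pred)
  }
  lo <- mean_err(interval[1L]); hi <- mean_err(interval[2L])
  if (!is.finite(lo) || !is.finite(hi) || sign(lo) == sign(hi))
    stop("A constant not identifiable for cohort: no sign change in bracket")
  stats::uniroot(mean_err, interval, tol = tol, f.lower = lo, f.upper = hi)$root
}
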