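# Meridional lens-surface geometry.
#
# All depths are measured in mm along the eye axis from the posterior corneal
# vertex, positive toward the retina; corneal thickness is excluded. Heights
# are measured perpendicular to the axis. Each lens surface is modelled as a
# circle in the meridional plane, so a surface is fully described by its
# on-axis center depth and its radius.

#' Create an on-axis meridional circle
#'
#' A lens surface is modelled as a circle in the meridional section whose
#' center lies on the measurement axis.
#'
#' @param center_depth Depth of the circle center, mm from the posterior
#'   corneal vertex (positive toward the retina).
#' @param radius Circle radius, mm; must be positive.
#' @return An object of class `axis_circle` with fields `center_depth` and
#'   `radius`.
#' @examples
#' axis_circle(13.00, 10.21)  # a typical anterior lens surface
#' @export
axis_circle <- function(center_depth, radius) {
  stopifnot(is.numeric(center_depth), length(center_depth) == 1L,
            is.numeric(radius), length(radius) == 1L, is.finite(center_depth))
  if (!is.finite(radius) || radius <= 0)
    stop("radius must be a positive finite number")
  structure(list(center_depth = as.numeric(center_depth),
                 radius = as.numeric(radius)),
            class = "axis_circle")
}

#' @export
print.axis_circle <- function(x, ...) {
  cat(sprintf("axis_circle: center depth %.4f mm, radius %.4f mm\n",
              x$center_depth, x$radius))
  invisible(x)
}

#' Fit a circle to lens-surface sample points
#'
#' Least-squares circle fit by the algebraic (Kasa) method: the circle
#' \eqn{z^2 + h^2 + D z + E h + F = 0} minimising the algebraic residual is
#' obtained from a linear least-squares solve, which is closed-form and
#' deterministic. For small-aperture arcs typical of pupil-limited lens
#' profiles this is adequate; a Pratt or Taubin refinement could be swapped
#' in without changing the interface.
#'
#' The fitted center is allowed a small off-axis height (lens tilt or
#' decentration); if it exceeds `tilt_tol_mm` the fit is rejected rather
#' than silently collapsed onto the axis.
#'
#' @param points Two-column matrix or data frame of sample points
#'   `(depth_mm, height_mm)` on one lens surface; at least 3 non-collinear
#'   points are required.
#' @param tilt_tol_mm Maximum tolerated |center height| before the surface is
#'   declared tilted, mm. Default 0.2.
#' @return An `axis_circle` (center collapsed onto the axis) with attribute
#'   `center_height_mm` giving the fitted off-axis center height.
#' @examples
#' pts <- cbind(depth_mm = c(0, 1, 0), height_mm = c(1, 0, -1))
#' fit_circle(pts)  # unit circle at the origin
#' @export
fit_circle <- function(points, tilt_tol_mm = 0.2) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2L)
    stop("points must be a two-column numeric matrix (depth_mm, height_mm)")
  if (nrow(pts) < 3L || !all(is.finite(pts)))
    stop("degenerate samples: need at least 3 finite points")
  z <- pts[, 1L]; h <- pts[, 2L]
  # Kasa design matrix; center the coordinates first for conditioning.
  z0 <- mean(z); h0 <- mean(h)
  zc <- z - z0; hc <- h - h0
  A <- cbind(zc, hc, 1)
  b <- -(zc^2 + hc^2)
  qrA <- qr(A)
  if (qrA$rank < 3L)
    stop("degenerate samples: points are collinear")
  coef <- qr.coef(qrA, b)  # (D, E, F) in centered coordinates
  cz <- -coef[1L] / 2 + z0
  ch <- -coef[2L] / 2 + h0
  r2 <- coef[1L]^2 / 4 + coef[2L]^2 / 4 - coef[3L]
  if (!is.finite(r2) || r2 <= 0)
    stop("degenerate samples: no circle fits these points")
  if (abs(ch) > tilt_tol_mm)
    stop(sprintf("surface tilt exceeds tolerance: fitted center height %.4f mm (tolerance %.4f mm)",
                 ch, tilt_tol_mm))
  out <- axis_circle(unname(cz), unname(sqrt(r2)))
  attr(out, "center_height_mm") <- unname(ch)
  out
}

#' Create a lens shape
#'
#' Bundles the preoperative crystalline-lens geometry: anterior and posterior
#' curvature radii (ACR, PCR), lens thickness (LT), and the anterior,
#' equatorial and posterior surface depths (ASD, ESD, PSD). The construction
#' identity `psd = asd + lt` is enforced exactly, and a valid equatorial
#' depth must lie strictly between ASD and PSD.
#'
#' @param acr_mm,pcr_mm Anterior/posterior curvature radius, mm (> 0).
#' @param lt_mm Lens thickness, mm (> 0).
#' @param asd_mm Anterior surface depth, mm (> 0).
#' @param esd_mm Equatorial surface depth, mm, or `NA` if not yet derived.
#' @return An object of class `lens_shape`.
#' @export
lens_shape <- function(acr_mm, pcr_mm, lt_mm, asd_mm, esd_mm = NA_real_) {
  if (lt_mm <= 0) stop("inverted lens geometry: lens thickness must be positive")
  if (acr_mm <= 0 || pcr_mm <= 0) stop("curvature radii must be positive")
  if (asd_mm <= 0) stop("anterior surface depth must be positive")
  psd_mm <- asd_mm + lt_mm
  if (!is.na(esd_mm) && (esd_mm <= asd_mm || esd_mm >= psd_mm))
    stop("equatorial depth must lie strictly between the anterior and posterior depths")
  structure(list(acr_mm = acr_mm, pcr_mm = pcr_mm, lt_mm = lt_mm,
                 asd_mm = asd_mm, esd_mm = esd_mm, psd_mm = psd_mm),
            class = "lens_shape")
}

#' @export
print.lens_shape <- function(x, ...) {
  cat(sprintf(paste0("lens_shape: ACR %.2f, PCR %.2f, LT %.2f, ",
                     "ASD %.2f, ESD %s, PSD %.2f (mm)\n"),
              x$acr_mm, x$pcr_mm, x$lt_mm, x$asd_mm,
              if (is.na(x$esd_mm)) "NA" else sprintf("%.2f", x$esd_mm),
              x$psd_mm))
  invisible(x)
}

#' Derive the lens shape from the two fitted surface circles
#'
#' The anterior surface depth is the anterior circle's vertex
#' (`center_depth - radius`), the posterior surface depth the posterior
#' circle's vertex (`center_depth + radius`); lens thickness is their
#' difference and the equatorial depth is obtained from
#' [equatorial_depth()].
#'
#' @param anterior,posterior `axis_circle` objects for the anterior and
#'   posterior lens surfaces.
#' @return A `lens_shape` with all six fields filled.
#' @examples
#' ant <- axis_circle(13.00, 10.21)
#' post <- axis_circle(1.26, 6.01)
#' lens_shape_from_circles(ant, post)
#' @export
lens_shape_from_circles <- function(anterior, posterior) {
  stopifnot(inherits(anterior, "axis_circle"), inherits(posterior, "axis_circle"))
  asd <- anterior$center_depth - anterior$radius
  psd <- posterior$center_depth + posterior$radius
  lt <- psd - asd
  if (lt <= 0) stop("inverted lens geometry: posterior vertex is anterior to the anterior vertex")
  # the equator exists only when the two circles genuinely cross; a
  # vertex-valid but non-intersecting pair keeps ESD undefined (NA)
  esd <- tryCatch(equatorial_depth(anterior, posterior),
                  error = function(e) NA_real_)
  lens_shape(acr_mm = anterior$radius, pcr_mm = posterior$radius,
             lt_mm = lt, asd_mm = asd, esd_mm = esd)
}

#' Equatorial-plane depth of the crystalline lens
#'
#' Depth of the plane through the two points where the anterior and
#' posterior surface circles intersect in the meridional section. For
#' circles with on-axis centers at depths \eqn{z_a, z_p} and radii
#' \eqn{R_a, R_p}, equating the two circle equations gives the closed form
#' \deqn{z^* = \frac{z_a^2 - z_p^2 - R_a^2 + R_p^2}{2 (z_a - z_p)},}
#' the radical plane of the two circles restricted to the intersecting
#' case. The construction presumes a real intersection: if the circles do
#' not cross, this is an error, not a silent fallback.
#'
#' @param anterior,posterior `axis_circle` objects (anterior surface circle
#'   opens toward the retina, posterior toward the cornea).
#' @return Equatorial surface depth, mm. Always strictly between the
#'   anterior and posterior vertex depths for a valid lens.
#' @examples
#' equatorial_depth(axis_circle(13.00, 10.21), axis_circle(1.26, 6.01))
#' @export
equatorial_depth <- function(anterior, posterior) {
  stopifnot(inherits(anterior, "axis_circle"), inherits(posterior, "axis_circle"))
  za <- anterior$center_depth;  ra <- anterior$radius
  zp <- posterior$center_depth; rp <- posterior$radius
  if (za == zp)
    stop("concentric-depth circles, equator undefined")
  zstar <- (za^2 - zp^2 - ra^2 + rp^2) / (2 * (za - zp))
  # height^2 of the intersection points on the anterior circle
  h2 <- ra^2 - (zstar - za)^2
  if (!is.finite(h2) || h2 <= 0)
    stop("lens circles do not intersect")
  zstar
}
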