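# Independent oracles used by the unit and property tests. Each one solves
# the same problem as a package operation by a different route, so the two
# can disagree when either is wrong.

# Exact circle through three points (perpendicular-bisector solve).
circle_through_3 <- function(p1, p2, p3) {
  A <- rbind(2 * (p2 - p1), 2 * (p3 - p1))
  b <- c(sum(p2^2) - sum(p1^2), sum(p3^2) - sum(p1^2))
  ctr <- solve(A, b)
  list(center = ctr, radius = sqrt(sum((p1 - ctr)^2)))
}

# Off-axis crossing depth of two on-axis circles, found numerically by
# root-finding the difference of the two surface height profiles over the
# depth interval where both circles have real height.
esd_crossing_oracle <- function(anterior, posterior, tol = 1e-12) {
  za <- anterior$center_depth;  ra <- anterior$radius
  zp <- posterior$center_depth; rp <- posterior$radius
  f <- function(z) sqrt(pmax(ra^2 - (z - za)^2, 0)) -
    sqrt(pmax(rp^2 - (z - zp)^2, 0))
  lo <- max(za - ra, zp - rp); hi <- min(za + ra, zp + rp)
  grid <- seq(lo + 1e-9, hi - 1e-9, length.out = 2048)
  fg <- f(grid)
  idx <- which(diff(sign(fg)) != 0)
  if (length(idx) == 0) return(NA_real_)
  stats::uniroot(f, c(grid[idx[1]], grid[idx[1] + 1]), tol = tol)$root
}

# Partial correlation via residuals of x ~ z and y ~ z.
partial_corr_residual <- function(x, y, z) {
  stats::cor(stats::resid(stats::lm(x ~ z)), stats::resid(stats::lm(y ~ z)))
}

# OLS coefficients by explicit normal equations.
ols_normal_equations <- function(y, X) {
  Xd <- cbind(1, as.matrix(X))
  drop(solve(t(Xd) %*% Xd, t(Xd) %*% y))
}

# Random intersecting lens-like circle pair (anterior opens posteriorly,
# posterior opens anteriorly), drawn until the geometry is valid.
random_lens_circle_pair <- function() {
  repeat {
    asd <- stats::runif(1, 1.5, 4.0)
    lt  <- stats::runif(1, 3.0, 5.5)
    acr <- stats::runif(1, 7, 14)
    pcr <- stats::runif(1, 4.5, 8)
    ant <- axis_circle(asd + acr, acr)
    post <- axis_circle(asd + lt - pcr, pcr)
    z <- tryCatch(equatorial_depth(ant, post), error = function(e) NULL)
    if (!is.null(z) && z > asd && z < asd + lt)
      return(list(anterior = ant, posterior = post, asd = asd, psd = asd + lt))
  }
}

# Small deterministic cohort for pipeline tests.
tiny_cohort <- function(n = 40, seed = 99) generate_cohort(cohort_params(n = n, seed = seed))
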