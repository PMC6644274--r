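# Cohort statistical surface: summaries, Pearson correlations with
# Bonferroni correction, age-controlled partial correlations, and multiple
# regression with standardized coefficients.

#' Summarize a biometric variable
#'
#' @param x Numeric vector, length >= 2.
#' @return Named list: `mean`, `sd` (n-1 denominator), `min`, `max`.
#' @export
biometry_summary <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("insufficient data: need at least 2 values")
  list(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x))
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the exact t
#' distribution on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors, n >= 3, each with nonzero variance.
#' @param x_name,y_name Labels carried into the result.
#' @return A one-row data frame (a correlation entry) with columns
#'   `x_name`, `y_name`, `n`, `r`, `r_squared`, `p_raw`.
#' @export
pearson_corr <- function(x, y, x_name = deparse(substitute(x)),
                         y_name = deparse(substitute(y))) {
  force(x_name); force(y_name)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate variable: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  data.frame(x_name = x_name, y_name = y_name, n = length(x),
             r = r, r_squared = r^2, p_raw = ct$p.value,
             stringsAsFactors = FALSE)
}

#' Bonferroni correction within a hypothesis family
#'
#' Multiplies each raw p-value by the family size and caps at 1, the
#' display convention used for correlation tables (non-significant entries
#' print as 1.000).
#'
#' @param p_raw Numeric vector of raw p-values.
#' @param family_size Number of tests in the family (>= 1).
#' @return Corrected p-values, `pmin(1, family_size * p_raw)`.
#' @export
bonferroni_adjust <- function(p_raw, family_size) {
  if (family_size < 1L) stop("family_size must be >= 1")
  pmin(1, family_size * p_raw)
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of a
#' single control variable `z`:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#' Equivalent to correlating the residuals of `x ~ z` with those of
#' `y ~ z` (the residual route is kept as an independent test oracle).
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @param control The single control variable (e.g. age).
#' @return Partial correlation coefficient (scalar).
#' @export
partial_corr <- function(x, y, control) {
  ok <- is.finite(x) & is.finite(y) & is.finite(control)
  x <- x[ok]; y <- y[ok]; z <- control[ok]
  if (length(x) < 4L) stop("need at least 4 complete triples")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("control collinear with variable")
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Multiple linear regression with standardized coefficients
#'
#' Ordinary least squares of `response` on the given predictor columns,
#' reporting raw partial regression coefficients, standard partial
#' regression coefficients (raw coefficient times sd(x)/sd(y)) and the
#' multiple coefficient of determination R^2.
#'
#' @param data Data frame containing the response and predictors.
#' @param response Name of the response column.
#' @param terms Character vector of predictor column names.
#' @return An object of class `regression_fit`: list with `response`,
#'   `terms` (data frame: name, coefficient, standardized_coefficient),
#'   `intercept`, `r_squared_multiple`, and the underlying `lm` fit.
#' @export
multiple_regression <- function(data, response, terms) {
  stopifnot(response %in% names(data), all(terms %in% names(data)))
  df <- data[, c(response, terms)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) <= length(terms) + 1L)
    stop("insufficient data: need n > number of terms + 1")
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (fit$rank < length(terms) + 1L) stop("collinear predictors")
  coefs <- stats::coef(fit)
  y <- df[[response]]
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  sdy <- stats::sd(df[[response]])
  std <- vapply(terms, function(v) unname(coefs[v]) * stats::sd(df[[v]]) / sdy,
                numeric(1))
  structure(list(
    response = response,
    terms = data.frame(name = terms,
                       coefficient = unname(coefs[terms]),
                       standardized_coefficient = unname(std),
                       stringsAsFactors = FALSE),
    intercept = unname(coefs[["(Intercept)"]]),
    r_squared_multiple = r2,
    fit = fit), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("Multiple regression: %s ~ %s\n", x$response,
              paste(x$terms$name, collapse = " + ")))
  print(cbind(x$terms[1L],
              round(x$terms[c("coefficient", "standardized_coefficient")], 3)),
        row.names = FALSE)
  cat(sprintf("Intercept %.3f, multiple R^2 = %.3f\n",
              x$intercept, x$r_squared_multiple))
  invisible(x)
}

#' Per-eye differences between measured depths and the SRK/T predicted ACD
#'
#' Subtracts the SRK/T predicted postoperative ACD from each supplied depth
#' column (each depth minus the prediction), producing the difference
#' variables whose correlation with the refractive prediction error is of
#' clinical interest.
#'
#' @param depths Data frame of per-eye depth columns (mm), e.g.
#'   `anterior_iol_mm`, `asd_mm`, `esd_mm`, `psd_mm`.
#' @param srkt_acd Per-eye SRK/T predicted ACD, mm; length must match.
#' @return Data frame of the same shape; column names gain a `_minus_srkt`
#'   suffix.
#' @export
difference_vs_srkt <- function(depths, srkt_acd) {
  depths <- as.data.frame(depths)
  if (nrow(depths) != length(srkt_acd)) stop("unaligned cohort")
  out <- as.data.frame(lapply(depths, function(col) col - srkt_acd))
  names(out) <- paste0(names(depths), "_minus_srkt")
  out
}
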