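# Report surface: derived per-eye quantities and the four cohort tables,
# plus per-figure scatter data. All computation happens through the
# geometry/formula/statistics operations; the writers only format.

cohort_required_columns <- function() {
  c("eye_id", "age_years", "al_mm", "mean_k_d", "acr_mm", "pcr_mm",
    "lt_mm", "asd_mm", "esd_mm", "psd_mm", "iol_power_d",
    "iol_thickness_mm", "anterior_iol_mm", "postop_se_d")
}

#' Validate a cohort table against the shared column dictionary
#'
#' @param cohort Data frame to check.
#' @return The cohort, invisibly, if valid; otherwise an error naming the
#'   first missing column.
#' @export
validate_cohort <- function(cohort) {
  miss <- setdiff(cohort_required_columns(), names(cohort))
  if (length(miss))
    stop("cohort schema error: missing column '", miss[1L], "'")
  invisible(cohort)
}

#' Derive the analysis quantities for every eye
#'
#' Fills in, per eye: the central/posterior IOL surface depths, the
#' effective C constant and the C-constant predicted central IOL position
#' (using the cohort mean C, as the constant is a lens-model property, not
#' a per-eye one), the SRK/T predicted postoperative ACD, and the
#' predicted refraction and refractive prediction error after the A
#' constant has been optimized to zero the cohort mean error.
#'
#' @param cohort Validated cohort data frame (see [validate_cohort()]).
#' @param optimize_a If `TRUE` (default), the A constant is re-optimized on
#'   this cohort; otherwise the `a_constant` column (or `a_constant`
#'   argument value) is used as-is.
#' @param a_constant Optional fixed A constant when `optimize_a = FALSE`.
#' @return The cohort with derived columns `central_iol_mm`,
#'   `posterior_iol_mm`, `c_constant`, `pred_iol_c_mm`, `srkt_acd_mm`,
#'   `predicted_refraction_d`, `prediction_error_d`, and attributes
#'   `a_constant_optimized` and `mean_c_constant`.
#' @export
augment_cohort <- function(cohort, optimize_a = TRUE, a_constant = NULL) {
  validate_cohort(cohort)
  pos <- iol_positions(cohort$anterior_iol_mm, cohort$iol_thickness_mm)
  cohort$central_iol_mm <- pos$central_mm
  cohort$posterior_iol_mm <- pos$posterior_mm
  cohort$c_constant <- effective_c_constant(cohort$asd_mm, cohort$lt_mm,
                                            cohort$anterior_iol_mm,
                                            cohort$iol_thickness_mm)
  c_mean <- mean(cohort$c_constant)
  cohort$pred_iol_c_mm <- predict_iol_center(cohort$asd_mm, cohort$lt_mm, c_mean)
  a_opt <- if (optimize_a) {
    optimize_a_constant(cohort)
  } else if (!is.null(a_constant)) {
    a_constant
  } else if ("a_constant" %in% names(cohort)) {
    cohort$a_constant[1L]
  } else stop("no A constant available: supply one or set optimize_a = TRUE")
  cohort$srkt_acd_mm <- srkt_predicted_acd(cohort$al_mm, cohort$mean_k_d, a_opt)
  cohort$predicted_refraction_d <- srkt_predicted_refraction(
    cohort$al_mm, cohort$mean_k_d, a_opt, cohort$iol_power_d)
  cohort$prediction_error_d <- refractive_prediction_error(
    cohort$postop_se_d, cohort$predicted_refraction_d)
  attr(cohort, "a_constant_optimized") <- a_opt
  attr(cohort, "mean_c_constant") <- c_mean
  cohort
}

table1_variables <- function() {
  c(age_years = "Age (years)",
    iol_power_d = "IOL power (D)",
    al_mm = "Axial length (mm)",
    predicted_refraction_d = "Predictive refraction by SRK/T (D)",
    postop_se_d = "Spherical equivalent of postoperative refraction (D)",
    prediction_error_d = "Prediction error (D)",
    srkt_acd_mm = "Predicted postoperative ACD of SRK/T formula (mm)",
    c_constant = "C constant",
    pred_iol_c_mm = "Predicted IOL position using C constant (mm)",
    acr_mm = "Anterior curvature radius (mm)",
    pcr_mm = "Posterior curvature radius (mm)",
    lt_mm = "Lens thickness (mm)",
    asd_mm = "Anterior surface depth (mm)",
    esd_mm = "Equatorial surface depth (mm)",
    psd_mm = "Posterior surface depth (mm)",
    anterior_iol_mm = "Anterior IOL surface position (mm)",
    central_iol_mm = "Central IOL thickness position (mm)",
    posterior_iol_mm = "Posterior IOL surface position (mm)")
}

#' Cohort summary table (demographics and biometry)
#'
#' @param aug Augmented cohort from [augment_cohort()].
#' @return Data frame with one row per parameter: `variable`, `label`,
#'   `mean`, `sd`, `min`, `max`.
#' @export
report_table1 <- function(aug) {
  vars <- table1_variables()
  vars <- vars[names(vars) %in% names(aug)]
  rows <- lapply(names(vars), function(v) {
    s <- biometry_summary(aug[[v]])
    data.frame(variable = v, label = vars[[v]], mean = s$mean, sd = s$sd,
               min = s$min, max = s$max, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Default Bonferroni families: each analytic block of the correlation table
# is corrected for its own number of tests.
default_family_map <- function() {
  c(lt = 9L, pred_iol_c = 3L, anterior_iol = 3L, prediction_error = 4L)
}

#' Correlation table: LT, predicted positions, achieved position, error
#'
#' Four analytic blocks: correlates of lens thickness (with age-controlled
#' partial correlations), correlates of the C-constant predicted position,
#' correlates of the achieved anterior IOL surface position, and
#' correlates of the refractive prediction error with the per-eye gaps
#' between each depth and the SRK/T predicted ACD. Bonferroni correction is
#' applied within each block; the family sizes are configurable.
#'
#' @param aug Augmented cohort from [augment_cohort()].
#' @param family_map Named integer vector of Bonferroni family sizes per
#'   block (`lt`, `pred_iol_c`, `anterior_iol`, `prediction_error`);
#'   defaults to the number of tests in each block.
#' @return Data frame with columns `block`, `x_name`, `y_name`, `n`, `r`,
#'   `r_squared`, `partial_r_given_age`, `p_raw`, `p_bonferroni`.
#' @export
report_table2 <- function(aug, family_map = default_family_map()) {
  fam <- default_family_map()
  fam[names(family_map)] <- family_map
  ent <- function(block, xv, yv, partial = FALSE) {
    e <- pearson_corr(aug[[xv]], aug[[yv]], xv, yv)
    e$block <- block
    e$partial_r_given_age <- if (partial)
      partial_corr(aug[[xv]], aug[[yv]], aug$age_years) else NA_real_
    e
  }
  lt_vars <- c("age_years", "acr_mm", "pcr_mm", "asd_mm", "esd_mm", "psd_mm",
               "central_iol_mm", "c_constant", "pred_iol_c_mm")
  rows <- lapply(lt_vars, function(v)
    ent("lt", "lt_mm", v, partial = v != "age_years"))
  depth_vars <- c("asd_mm", "esd_mm", "psd_mm")
  rows <- c(rows,
            lapply(depth_vars, function(v) ent("pred_iol_c", "pred_iol_c_mm", v)),
            lapply(depth_vars, function(v) ent("anterior_iol", "anterior_iol_mm", v)))
  diffs <- difference_vs_srkt(
    aug[c("anterior_iol_mm", "asd_mm", "esd_mm", "psd_mm")], aug$srkt_acd_mm)
  err_rows <- lapply(names(diffs), function(v) {
    e <- pearson_corr(aug$prediction_error_d, diffs[[v]],
                      "prediction_error_d", v)
    e$block <- "prediction_error"
    e$partial_r_given_age <- NA_real_
    e
  })
  out <- do.call(rbind, c(rows, err_rows))
  out$p_bonferroni <- bonferroni_adjust(out$p_raw, 1)
  for (b in unique(out$block)) {
    idx <- out$block == b
    out$p_bonferroni[idx] <- bonferroni_adjust(out$p_raw[idx], fam[[b]])
  }
  out[c("block", "x_name", "y_name", "n", "r", "r_squared",
        "partial_r_given_age", "p_raw", "p_bonferroni")]
}

#' Intercorrelations among the three lens surface depths
#'
#' @param aug Augmented cohort from [augment_cohort()].
#' @return Data frame of the three pairwise correlations (upper triangle)
#'   among ASD, ESD and PSD with raw p-values.
#' @export
report_table3 <- function(aug) {
  vars <- c("asd_mm", "esd_mm", "psd_mm")
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr)
    pearson_corr(aug[[pr[1L]]], aug[[pr[2L]]], pr[1L], pr[2L])))
}

#' Multiple regression of the anterior IOL position on the lens depths
#'
#' @param aug Augmented cohort from [augment_cohort()].
#' @return A `regression_fit` (see [multiple_regression()]) with an extra
#'   `simple_r` column in `$terms`: the simple correlation of each depth
#'   with the anterior IOL surface position.
#' @export
report_table4 <- function(aug) {
  fit <- multiple_regression(aug, "anterior_iol_mm",
                             c("asd_mm", "esd_mm", "psd_mm"))
  fit$terms$simple_r <- vapply(fit$terms$name, function(v)
    stats::cor(aug[[v]], aug$anterior_iol_mm), numeric(1))
  fit
}

#' Per-figure scatter data
#'
#' One data frame per figure with the plotted series, point coordinates and
#' the least-squares line for each series.
#'
#' @param aug Augmented cohort from [augment_cohort()].
#' @return Named list of data frames with columns `series`, `x`, `y`,
#'   `slope`, `intercept`.
#' @export
figure_scatter_data <- function(aug) {
  diffs <- difference_vs_srkt(
    aug[c("anterior_iol_mm", "asd_mm", "esd_mm", "psd_mm")], aug$srkt_acd_mm)
  series_df <- function(xv, yv, x, y) {
    cf <- stats::coef(stats::lm(y ~ x))
    data.frame(series = paste(yv, "vs", xv), x = x, y = y,
               slope = unname(cf[2L]), intercept = unname(cf[1L]),
               stringsAsFactors = FALSE)
  }
  fig <- function(pairs) do.call(rbind, lapply(pairs, function(p)
    series_df(p[[1L]], p[[2L]], p[[3L]], p[[4L]])))
  lt <- aug$lt_mm
  list(
    fig2_lt_vs_curvature = fig(list(
      list("lt_mm", "acr_mm", lt, aug$acr_mm),
      list("lt_mm", "pcr_mm", lt, aug$pcr_mm))),
    fig3_lt_vs_depths = fig(list(
      list("lt_mm", "asd_mm", lt, aug$asd_mm),
      list("lt_mm", "esd_mm", lt, aug$esd_mm),
      list("lt_mm", "psd_mm", lt, aug$psd_mm))),
    fig4_lt_vs_iol_position = fig(list(
      list("lt_mm", "central_iol_mm", lt, aug$central_iol_mm),
      list("lt_mm", "pred_iol_c_mm", lt, aug$pred_iol_c_mm))),
    fig5_depths_vs_pred_iol_c = fig(list(
      list("asd_mm", "pred_iol_c_mm", aug$asd_mm, aug$pred_iol_c_mm),
      list("esd_mm", "pred_iol_c_mm", aug$esd_mm, aug$pred_iol_c_mm),
      list("psd_mm", "pred_iol_c_mm", aug$psd_mm, aug$pred_iol_c_mm))),
    fig6_depths_vs_anterior_iol = fig(list(
      list("asd_mm", "anterior_iol_mm", aug$asd_mm, aug$anterior_iol_mm),
      list("esd_mm", "anterior_iol_mm", aug$esd_mm, aug$anterior_iol_mm),
      list("psd_mm", "anterior_iol_mm", aug$psd_mm, aug$anterior_iol_mm))),
    fig7_error_vs_iol_gap = fig(list(
      list("anterior_iol_mm_minus_srkt", "prediction_error_d",
           diffs$anterior_iol_mm_minus_srkt, aug$prediction_error_d))),
    fig8_error_vs_depth_gaps = fig(list(
      list("asd_mm_minus_srkt", "prediction_error_d",
           diffs$asd_mm_minus_srkt, aug$prediction_error_d),
      list("esd_mm_minus_srkt", "prediction_error_d",
           diffs$esd_mm_minus_srkt, aug$prediction_error_d),
      list("psd_mm_minus_srkt", "prediction_error_d",
           diffs$psd_mm_minus_srkt, aug$prediction_error_d)))
  )
}

# Printed-dialect p-value: 3 dp, capped at 1.000, "<0.001" below threshold.
format_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", pmin(p, 1)))

# Markdown renderers use the table dialect: depths and diopters at 2 dp,
# correlations at 2 dp, p at 3 dp.
render_markdown_reports <- function(tables) {
  t1 <- tables$table1
  md1 <- c("# Cohort summary", "",
           "| Parameter | Mean | SD | Min | Max |", "|---|---|---|---|---|",
           sprintf("| %s | %.2f | %.2f | %.2f | %.2f |",
                   t1$label, t1$mean, t1$sd, t1$min, t1$max))
  t2 <- tables$table2
  md2 <- c("# Correlations", "",
           "| Block | x | y | r | R2 | partial r (age) | p (Bonferroni) |",
           "|---|---|---|---|---|---|---|",
           sprintf("| %s | %s | %s | %.2f | %.2f | %s | %s |",
                   t2$block, t2$x_name, t2$y_name, t2$r, t2$r_squared,
                   ifelse(is.na(t2$partial_r_given_age), "",
                          sprintf("%.2f", t2$partial_r_given_age)),
                   format_p(t2$p_bonferroni)))
  t3 <- tables$table3
  md3 <- c("# Lens depth intercorrelations", "",
           "| x | y | r | p |", "|---|---|---|---|",
           sprintf("| %s | %s | %.2f | %s |",
                   t3$x_name, t3$y_name, t3$r, format_p(t3$p_raw)))
  t4 <- tables$table4
  md4 <- c("# Multiple regression: anterior IOL surface position", "",
           "| Variable | Coefficient | Standardized | Simple r |",
           "|---|---|---|---|",
           sprintf("| %s | %.2f | %.2f | %.2f |",
                   t4$terms$name, t4$terms$coefficient,
                   t4$terms$standardized_coefficient, t4$terms$simple_r),
           sprintf("| Constant | %.2f | | |", t4$intercept), "",
           sprintf("Multiple R^2 = %.2f", t4$r_squared_multiple))
  list(table1 = md1, table2 = md2, table3 = md3, table4 = md4)
}
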