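# Pipeline orchestration: simulate -> analyze -> report, plus small
# one-shot calculators. All file I/O is plain text (UTF-8, comma CSV,
# period decimals, header row); intermediate computation stays at full
# precision and rounding happens only in the markdown renderers.

#' Write / read a cohort CSV
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `read_cohort_csv` returns the validated cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}

#' Simulate a cohort and write it with a provenance sidecar
#'
#' @param n Number of eyes (>= 4).
#' @param seed Master seed.
#' @param out Output CSV path; the provenance sidecar is written next to it
#'   as `<out>.provenance.yaml` (parameters, seed, package version,
#'   rejection count, calibrated position-noise sd).
#' @param params_file Optional YAML/JSON file of [cohort_params()]
#'   overrides (e.g. `lt: {mean: 5.0, sd: 0.37, range: [3.6, 6.4]}`).
#' @return The cohort, invisibly.
#' @export
run_simulate <- function(n, seed, out, params_file = NULL) {
  if (n < 4) stop("usage error: n must be at least 4")
  overrides <- if (!is.null(params_file)) yaml::read_yaml(params_file) else list()
  params <- do.call(cohort_params, c(list(n = n, seed = seed), overrides))
  cohort <- generate_cohort(params)
  write_cohort_csv(cohort, out)
  prov <- list(
    package = "lenspos",
    version = as.character(utils::packageVersion("lenspos")),
    seed = seed, n = n,
    rejected_draws = attr(cohort, "rejected"),
    position_noise_sd_mm = attr(cohort, "position_noise_sd"),
    params = unclass(params))
  yaml::write_yaml(prov, paste0(out, ".provenance.yaml"))
  invisible(cohort)
}

#' Analyze a cohort and write the report bundle
#'
#' Derives all per-eye quantities (C constant, predicted positions, SRK/T
#' ACD with A-constant optimisation, prediction error), then writes
#' `table1_summary`, `table2_correlations`, `table3_intercorrelations` and
#' `table4_regression` as TSV and markdown, plus one scatter CSV per
#' figure.
#'
#' @param input Cohort CSV path or cohort data frame.
#' @param outdir Output directory (created if needed).
#' @param family_map Optional named Bonferroni family sizes, see
#'   [report_table2()].
#' @return Invisibly, a list with the augmented cohort and all tables.
#' @export
run_analyze <- function(input, outdir, family_map = default_family_map()) {
  cohort <- if (is.character(input)) read_cohort_csv(input) else
    validate_cohort(input)
  if (nrow(cohort) < 4L)
    stop("statistical precondition: need at least 4 eyes")
  aug <- augment_cohort(cohort)
  tables <- list(table1 = report_table1(aug),
                 table2 = report_table2(aug, family_map),
                 table3 = report_table3(aug),
                 table4 = report_table4(aug))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(outdir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  tsv(tables$table1, "table1_summary")
  tsv(tables$table2, "table2_correlations")
  tsv(tables$table3, "table3_intercorrelations")
  t4 <- tables$table4
  tsv(rbind(cbind(t4$terms,
                  intercept = t4$intercept,
                  r_squared_multiple = t4$r_squared_multiple)),
      "table4_regression")
  md <- render_markdown_reports(tables)
  for (nm in names(md))
    writeLines(md[[nm]], file.path(outdir, paste0(switch(nm,
      table1 = "table1_summary", table2 = "table2_correlations",
      table3 = "table3_intercorrelations", table4 = "table4_regression"),
      ".md")))
  figs <- figure_scatter_data(aug)
  for (nm in names(figs))
    utils::write.csv(figs[[nm]], file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  invisible(c(list(cohort = aug,
                   a_constant = attr(aug, "a_constant_optimized")), tables))
}

#' Equatorial depth from the four printed lens parameters
#'
#' Convenience wrapper: builds the anterior circle (vertex at ASD, radius
#' ACR) and posterior circle (vertex at ASD + LT, radius PCR) and returns
#' the equatorial-plane depth.
#'
#' @param acr,pcr Curvature radii, mm.
#' @param asd Anterior surface depth, mm.
#' @param lt Lens thickness, mm.
#' @return ESD, mm.
#' @examples
#' esd_from_biometry(10.21, 6.01, 2.79, 4.48)  # about 4.23 mm
#' @export
esd_from_biometry <- function(acr, pcr, asd, lt) {
  if (any(c(acr, pcr, asd, lt) <= 0)) stop("all lens parameters must be positive")
  anterior <- axis_circle(asd + acr, acr)
  posterior <- axis_circle(asd + lt - pcr, pcr)
  equatorial_depth(anterior, posterior)
}

# ---- command-line dispatcher -------------------------------------------
# Exit codes: 0 success, 2 usage/schema, 3 statistical precondition,
# 4 geometry failure. The installed wrapper script is
# system.file("cli", "lenspos.R", package = "lenspos").

parse_cli_args <- function(argv) {
  opts <- list(); positional <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(argv) || startsWith(argv[[i + 1L]], "--"))
        stop("usage error: option --", key, " needs a value")
      opts[[gsub("-", "_", key)]] <- argv[[i + 1L]]
      i <- i + 2L
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(opts = opts, positional = positional)
}

cli_usage <- function() {
  paste(
    "usage: lenspos.R <command> [options]",
    "  simulate --n N --seed S --out FILE [--params FILE]",
    "  analyze  --in FILE --out DIR [--family-map FILE]",
    "  esd      --acr MM --pcr MM --asd MM --lt MM",
    "  srkt     --al MM --k D --a-const A [--power D]",
    sep = "\n")
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `analyze`, `esd` and `srkt` subcommands; see
#' the wrapper script in `inst/cli/lenspos.R`. Returns an exit status
#' instead of calling `quit()` so it can be tested in-process.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status: 0 success, 2 usage/schema error,
#'   3 statistical precondition, 4 geometry failure.
#' @export
cli_main <- function(argv) {
  if (length(argv) == 0L) { message(cli_usage()); return(2L) }
  cmd <- argv[[1L]]
  parsed <- tryCatch(parse_cli_args(argv[-1L]), error = function(e) e)
  if (inherits(parsed, "error")) { message(conditionMessage(parsed)); return(2L) }
  o <- parsed$opts
  num <- function(x) suppressWarnings(as.numeric(x))
  res <- tryCatch(switch(cmd,
    simulate = {
      if (is.null(o$n) || is.null(o$seed) || is.null(o$out))
        stop("usage error: simulate needs --n, --seed, --out")
      run_simulate(as.integer(num(o$n)), as.integer(num(o$seed)), o$out,
                   params_file = o$params)
      message("wrote ", o$out)
      0L
    },
    analyze = {
      if (is.null(o$`in`) || is.null(o$out))
        stop("usage error: analyze needs --in and --out")
      fam <- if (!is.null(o$family_map))
        unlist(yaml::read_yaml(o$family_map)) else default_family_map()
      run_analyze(o$`in`, o$out, family_map = fam)
      message("reports written to ", o$out)
      0L
    },
    esd = {
      if (any(vapply(list(o$acr, o$pcr, o$asd, o$lt), is.null, logical(1))))
        stop("usage error: esd needs --acr, --pcr, --asd, --lt")
      val <- esd_from_biometry(num(o$acr), num(o$pcr), num(o$asd), num(o$lt))
      cat(sprintf("ESD = %.2f mm (circles intersect: yes)\n", val))
      0L
    },
    srkt = {
      if (any(vapply(list(o$al, o$k, o$a_const), is.null, logical(1))))
        stop("usage error: srkt needs --al, --k, --a-const")
      acd <- srkt_predicted_acd(num(o$al), num(o$k), num(o$a_const))
      cat(sprintf("SRK/T predicted postoperative ACD = %.2f mm\n", acd))
      if (!is.null(o$power)) {
        ref <- srkt_predicted_refraction(num(o$al), num(o$k), num(o$a_const),
                                         num(o$power))
        cat(sprintf("Predicted refraction at %.1f D: %.2f D\n",
                    num(o$power), ref))
      }
      0L
    },
    { message("unknown command: ", cmd, "\n", cli_usage()); 2L }
  ), error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    if (grepl("usage error|schema error|not found|unknown cohort parameter",
              msg)) 2L
    else if (grepl("statistical precondition|insufficient data|at least",
                   msg)) 3L
    else if (grepl("intersect|concentric|geometry|degenerate|tilt|positive",
                   msg)) 4L
    else 1L
  })
  res
}
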