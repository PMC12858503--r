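#' Write the EIM report bundle
#'
#' Writes, under `dir`: `model_comparison.csv` (one row per model:
#' variances, log-likelihood, AIC, VPC%, PCV%), one
#' `stratum_predictions_<model>.csv` per model (ranked predicted means
#' with 95% intervals), `interaction_flags_<model>.csv` for the
#' main-effects models, `coefficients_<model>.csv` (estimate, 95% CI,
#' significance stars) and `summary.json`.  Data CSVs carry full
#' precision; display rounding is confined to the JSON percentages.
#'
#' @param seq_result An `eimm_sequence` from [run_model_sequence()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(seq_result, dir) {
  stopifnot(inherits(seq_result, "eimm_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(seq_result$comparison, "model_comparison.csv")
  for (lab in names(seq_result$models)) {
    m <- seq_result$models[[lab]]
    wr(m$predictions, sprintf("stratum_predictions_%s.csv", lab))
    wr(coef_table(m$fit), sprintf("coefficients_%s.csv", lab))
    if (!is.null(m$fit$model$effects))
      wr(m$summary$significant, sprintf("interaction_flags_%s.csv", lab))
  }
  summ <- lapply(seq_result$models, function(m)
    list(vpc_pct = m$summary$vpc_pct,
         pcv_pct = m$summary$pcv_pct,
         sigma2_u = m$fit$sigma2_u, sigma2_e = m$fit$sigma2_e,
         aic = m$fit$aic, loglik = m$fit$loglik,
         n_areas = m$fit$n_areas, n_strata = m$fit$n_strata_occupied,
         n_significant = nrow(m$summary$significant)))
  pj <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, pj, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  paths <- c(paths, pj)
  invisible(paths)
}

# Coefficient table mirroring the usual published layout:
# estimate, CI bracket, stars at 0.05 / 0.01 / 0.001.
coef_table <- function(fit) {
  stars <- cut(fit$p_beta, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  data.frame(term = names(fit$beta),
             estimate = unname(fit$beta),
             se = unname(fit$se_beta),
             ci_lower = unname(fit$ci95_beta[, "lower"]),
             ci_upper = unname(fit$ci95_beta[, "upper"]),
             p = unname(fit$p_beta),
             stars = as.character(stars),
             stringsAsFactors = FALSE)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic area table and its truth
#' record), `build-strata` (area -> stratum code CSVs), `fit` (single
#' model), `report` / `run-all` (full model sequence and report bundle).
#' Designed to be called from an `Rscript` wrapper (see
#' `inst/cli/eimm`); returns the exit status instead of quitting so it
#' is testable in-process.
#'
#' Common options: `--seed <int>`, `--out <dir>`, `--input <csv>`,
#' `--preset study-like`, `--n-areas <int>`, `--no-model3`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status: 0 success, 2 configuration/data error,
#'   3 fit error.
#' @export
eimm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    cli_dispatch(args)
    0L
  },
  eimm_fit_error = function(e) { cli_log("ERROR", conditionMessage(e)); 3L },
  eimm_config_error = function(e) { cli_log("ERROR", conditionMessage(e)); 2L },
  eimm_data_error = function(e) { cli_log("ERROR", conditionMessage(e)); 2L })
  status
}

cli_log <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

parse_opts <- function(args, flags = c("no-model3", "quiet")) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop_config(sprintf("unexpected argument '%s'", a))
    key <- sub("^--", "", a)
    if (key %in% flags) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args))
        stop_config(sprintf("option --%s requires a value", key))
      opts[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  known <- c(flags, "seed", "out", "input", "preset", "n-areas",
             "sigma2-u", "sigma2-e", "outcome-col", "id-col")
  unknown <- setdiff(names(opts), known)
  if (length(unknown))
    stop_config(paste0("unknown option(s): ",
                       paste0("--", unknown, collapse = ", ")))
  opts
}

cli_config <- function(opts) {
  n <- as.integer(opts[["n-areas"]] %||% 33755L)
  cfg <- preset_study_like(
    n_areas = n,
    seed = as.integer(opts$seed %||% 1L))
  if (!is.null(opts[["sigma2-u"]])) cfg$sigma2_u <- as.numeric(opts[["sigma2-u"]])
  if (!is.null(opts[["sigma2-e"]])) cfg$sigma2_e <- as.numeric(opts[["sigma2-e"]])
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_input_table <- function(opts) {
  columns <- NULL
  if (!is.null(opts[["outcome-col"]]))
    columns <- c(columns, outcome = opts[["outcome-col"]])
  if (!is.null(opts[["id-col"]]))
    columns <- c(columns, area_id = opts[["id-col"]])
  if (!is.null(opts$input)) {
    cli_log("INFO", "reading ", opts$input)
    read_area_table(opts$input, columns = columns)
  } else {
    preset <- opts$preset %||% "study-like"
    if (!identical(preset, "study-like"))
      stop_config(sprintf("unknown preset '%s'", preset))
    cfg <- cli_config(opts)
    cli_log("INFO", sprintf("simulating %d areas (seed %d)",
                            cfg$n_areas, cfg$seed))
    simulate_areas(cfg)$table
  }
}

cli_dispatch <- function(args) {
  if (length(args) == 0L)
    stop_config("usage: eimm <simulate|build-strata|fit|report|run-all> [options]")
  cmd <- args[[1L]]
  opts <- parse_opts(args[-1L])
  out <- opts$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  switch(cmd,
    simulate = {
      cfg <- cli_config(opts)
      sim <- simulate_areas(cfg)
      utils::write.csv(sim$table, file.path(out, "areas.csv"), row.names = FALSE)
      truth <- sim$truth
      truth$config <- NULL  # scheme objects are not JSON-friendly
      jsonlite::write_json(truth, file.path(out, "truth.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      cli_log("INFO", "wrote areas.csv and truth.json to ", out)
    },
    `build-strata` = {
      tab <- cli_input_table(opts)
      strata <- categorize(tab, default_scheme(TRUE))
      write_strata(strata, file.path(out, "area_strata.csv"),
                   file.path(out, "stratum_registry.csv"))
      cli_log("INFO", sprintf("assigned %d areas to %d occupied strata",
                              nrow(strata$assignment), nrow(strata$registry)))
    },
    fit = {
      tab <- cli_input_table(opts)
      strata <- categorize(tab, default_scheme(TRUE))
      vars <- names(strata$scheme$rules)
      fit <- fit_eim(tab, strata, model_spec(vars, label = "2b"))
      cli_log("INFO", sprintf(
        "model 2b converged in %d iterations: sigma2_u=%.4f sigma2_e=%.4f loglik=%.4f",
        fit$convergence$iterations, fit$sigma2_u, fit$sigma2_e, fit$loglik))
      utils::write.csv(coef_table(fit), file.path(out, "coefficients_2b.csv"),
                       row.names = FALSE)
    },
    report = ,
    `run-all` = {
      tab <- cli_input_table(opts)
      interaction <- if (isTRUE(opts[["no-model3"]])) NULL else c("pct_minority", "urban")
      seq_result <- run_model_sequence(tab, interaction = interaction)
      for (lab in names(seq_result$models)) {
        f <- seq_result$models[[lab]]$fit
        cli_log("INFO", sprintf(
          "model %s: %s after %d iterations; sigma2_u=%.4f sigma2_e=%.4f",
          lab, f$convergence$message, f$convergence$iterations,
          f$sigma2_u, f$sigma2_e))
      }
      write_report_bundle(seq_result, out)
      cli_log("INFO", "report bundle written to ", out)
    },
    stop_config(sprintf("unknown subcommand '%s'", cmd)))
  invisible(NULL)
}
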