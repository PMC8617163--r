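# Reporting glue: one benchmark run -> a deterministic bundle of files.

#' Write a benchmark report bundle
#'
#' Writes, into `out_dir`: the accumulated prediction records
#' (`records.csv`), the formula-by-stratum metrics (`metrics.csv` and
#' `metrics.json`), the statistical test battery (`tests.csv`), the run
#' configuration (`config.json`) and a plain-text summary (`summary.txt`).
#' Re-running with the same cohort and seed reproduces the bundle
#' byte-identically.
#'
#' @param cv An `"iol_cv"` object from [mc_crossval()].
#' @param out_dir Output directory (created if missing).
#' @param tests Run the statistical battery (set `FALSE` to skip).
#' @return Invisibly, the vector of files written.
#' @export
run_report <- function(cv, out_dir, tests = TRUE) {
  stopifnot(inherits(cv, "iol_cv"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory '", out_dir, "'",
                  call. = FALSE)
  }
  files <- character(0)
  f <- file.path(out_dir, "records.csv")
  utils::write.csv(cv$records, f, row.names = FALSE)
  files <- c(files, f)

  metrics <- compute_metrics(cv$records)
  f <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, f, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  files <- c(files, f)

  if (tests) {
    battery <- run_test_battery(cv$records)
    f <- file.path(out_dir, "tests.csv")
    utils::write.csv(battery, f, row.names = FALSE)
    files <- c(files, f)
  }

  f <- file.path(out_dir, "config.json")
  jsonlite::write_json(
    list(k = cv$k, test_fraction = cv$test_fraction, seed = cv$seed,
         n = cv$n, lens_model = cv$lens_model, formulae = cv$formulae,
         failed_folds = length(cv$failures)),
    f, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f)

  f <- file.path(out_dir, "summary.txt")
  con <- file(f, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("Monte-Carlo cross-validation: %d repetitions, %.0f%% held out, seed %d",
            cv$k, 100 * cv$test_fraction, cv$seed),
    sprintf("Lens model %s, cohort n = %d, accumulated records = %d",
            cv$lens_model, cv$n, nrow(cv$records)),
    if (length(cv$failures)) sprintf("Failed folds: %d", length(cv$failures))
    else "All folds completed",
    "",
    "Formula x stratum cells reported (empty strata are absent):",
    sprintf("  %-10s %-12s n=%-6d MAE=%.3f  %%<=1.0D=%.1f",
            metrics$formula_id, metrics$stratum, metrics$n, metrics$mae,
            metrics$pct_within_1.0)), con)
  files <- c(files, f)
  invisible(files)
}
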