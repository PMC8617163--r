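# Cohort data frames: one row per eye (one eye per patient).
# Canonical columns: id, lens_model, age, sex, al_mm, k1_d, k2_d, acd_mm,
# iol_power_d, postop_se_d.

cohort_columns <- c("id", "lens_model", "age", "sex", "al_mm", "k1_d",
                    "k2_d", "acd_mm", "iol_power_d", "postop_se_d")

# per-row plausibility ranges (open intervals)
cohort_ranges <- list(
  al_mm       = c(15, 40),
  k1_d        = c(30, 60),
  k2_d        = c(30, 60),
  acd_mm      = c(1.5, 6),
  iol_power_d = c(-10, 40),
  postop_se_d = c(-10, 10)
)

#' Validate a cohort data frame
#'
#' Checks that the canonical per-eye columns are present and that each row's
#' biometry and outcome values fall inside plausible clinical ranges.
#'
#' @param cohort Data frame with one row per eye.
#' @param require_outcome Require the implanted power / achieved refraction
#'   columns (set to `FALSE` for pre-operative biometry-only tables).
#' @return A data frame of row-level issues (zero rows when clean) with
#'   columns `row`, `column`, `value`, `problem`.
#' @export
validate_cohort <- function(cohort, require_outcome = TRUE) {
  need <- c("id", "lens_model", "al_mm", "k1_d", "k2_d", "acd_mm")
  if (require_outcome) need <- c(need, "iol_power_d", "postop_se_d")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cohort$id)) {
    stop("duplicate eye id(s): ",
         paste(utils::head(cohort$id[duplicated(cohort$id)], 3),
               collapse = ", "), call. = FALSE)
  }
  issues <- list()
  for (col in intersect(names(cohort_ranges), need)) {
    v <- cohort[[col]]
    bad <- !is.finite(v) | v <= cohort_ranges[[col]][1] |
      v >= cohort_ranges[[col]][2]
    if (any(bad)) {
      issues[[col]] <- data.frame(
        row = which(bad), column = col, value = v[bad],
        problem = sprintf("outside (%s, %s)",
                          cohort_ranges[[col]][1], cohort_ranges[[col]][2]))
    }
  }
  if (length(issues)) do.call(rbind, unname(issues)) else
    data.frame(row = integer(), column = character(),
               value = numeric(), problem = character())
}

#' Read a cohort CSV
#'
#' Expects the canonical header `id, lens_model, age, sex, al_mm, k1_d,
#' k2_d, acd_mm, iol_power_d, postop_se_d`; extra columns are preserved.
#' Rows failing the plausibility checks are dropped with a warning; the
#' dropped rows (with their file line numbers) are attached as the
#' `"issues"` attribute.
#'
#' @param path Path to a CSV file.
#' @return Validated cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols)) {
    stop("cohort CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in names(cohort_ranges)) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(df[[col]] <- as.numeric(df[[col]]))
    }
  }
  issues <- validate_cohort(df)
  if (nrow(issues)) {
    issues$line <- issues$row + 1L  # header occupies line 1
    warning(nrow(issues), " row-level validation failure(s); ",
            "offending rows dropped (see attr(., 'issues'))", call. = FALSE)
    df <- df[-unique(issues$row), , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "issues") <- issues
  df
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort[, c(cohort_columns,
                              setdiff(names(cohort), cohort_columns))],
                   path, row.names = FALSE)
  invisible(path)
}

# cheap deterministic content hash (djb2 over the formatted numeric columns),
# used only for provenance stamps on optimized constant sets
cohort_hash <- function(cohort) {
  s <- paste(
    paste(cohort$id, collapse = ","),
    paste(format(cohort$al_mm, digits = 10), collapse = ","),
    paste(format(cohort$iol_power_d, digits = 10), collapse = ","),
    sep = "|")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 268435456
  sprintf("%07x", h)
}
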