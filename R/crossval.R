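# Monte-Carlo cross-validation benchmark: repeated random train/test splits,
# within each repetition the classical IOL constants are re-optimized and
# the MM ensemble is re-fitted on the same training split, then every
# formula predicts the held-out eyes.  Errors accumulate over repetitions.

all_formulae <- c("SRKT", "HOFFERQ", "HOLLADAY1", "HAIGIS", "MM")

#' Axial-length stratum of each eye
#'
#' Short eyes: AL < 22 mm; medium: 22 <= AL <= 24.5; long-medium:
#' 24.5 < AL <= 26; long: AL > 26 (closed upper bounds).
#'
#' @param al Axial length(s), mm.
#' @return Factor with levels `short`, `medium`, `long_medium`, `long`.
#' @export
#' @examples
#' stratify_axial_length(c(21.9, 22, 24.5, 26, 26.01))
stratify_axial_length <- function(al) {
  out <- ifelse(al < 22, "short",
         ifelse(al <= 24.5, "medium",
         ifelse(al <= 26, "long_medium", "long")))
  factor(out, levels = c("short", "medium", "long_medium", "long"))
}

#' Monte-Carlo cross-validation of the five formulae
#'
#' For each of `k` repetitions a random `test_fraction` of the cohort is
#' held out; all classical constants are optimized and the MM ensemble is
#' fitted on the remaining training split; every formula then predicts the
#' held-out eyes.  Per-eye prediction records are accumulated across
#' repetitions (each eye can appear in several repetitions but at most once
#' per repetition).
#'
#' @param cohort Cohort data frame (single lens model).
#' @param k Number of Monte-Carlo repetitions.
#' @param test_fraction Held-out proportion per repetition (0, 0.5).
#' @param seed Integer seed controlling the splits and the ensemble fits.
#' @param formulae Subset of `c("SRKT","HOFFERQ","HOLLADAY1","HAIGIS","MM")`.
#' @param control [mm_control()] for the MM fits.
#' @param constants [optical_constants()] for the MM optics.
#' @param haigis_mode Passed to [optimize_constants()].
#' @param accumulate If `FALSE`, keep only the last repetition's records.
#' @return An object of class `"iol_cv"`; `$records` is a data frame with
#'   one row per (eye, formula, repetition).
#' @export
mc_crossval <- function(cohort, k = 100, test_fraction = 0.2, seed = 1L,
                        formulae = all_formulae, control = mm_control(),
                        constants = optical_constants(),
                        haigis_mode = "regression", accumulate = TRUE) {
  stopifnot(k >= 1, test_fraction > 0, test_fraction < 0.5)
  formulae <- match.arg(formulae, all_formulae, several.ok = TRUE)
  stopifnot(nrow(validate_cohort(cohort)) == 0)
  n <- nrow(cohort)
  n_test <- max(1L, floor(n * test_fraction))
  set.seed(as.integer(seed))
  fold_seeds <- sample.int(.Machine$integer.max - 1L, k)
  records <- vector("list", k)
  failures <- character(0)
  for (rep_i in seq_len(k)) {
    set.seed(fold_seeds[rep_i])
    test_idx <- sample.int(n, n_test)
    train <- cohort[-test_idx, , drop = FALSE]
    test <- cohort[test_idx, , drop = FALSE]
    fold <- tryCatch({
      preds <- list()
      for (f in setdiff(formulae, "MM")) {
        cst <- suppressWarnings(
          optimize_constants(train, f, haigis_mode = haigis_mode))
        preds[[f]] <- suppressWarnings(
          predict_refraction_classical(f, test, cst, test$iol_power_d))
      }
      if ("MM" %in% formulae) {
        fit <- fit_mm(train, control = control, seed = fold_seeds[rep_i],
                      constants = constants)
        preds[["MM"]] <- predict(fit, test, type = "refraction")
      }
      do.call(rbind, lapply(names(preds), function(f) {
        data.frame(eye_id = test$id, formula_id = f, fold = rep_i,
                   al_mm = test$al_mm, predicted_rx = preds[[f]],
                   achieved_rx = test$postop_se_d,
                   pe = prediction_error(test$postop_se_d, preds[[f]]))
      }))
    }, error = function(e) conditionMessage(e))
    if (is.character(fold)) {
      failures <- c(failures, sprintf("fold %d: %s", rep_i, fold))
    } else {
      records[[rep_i]] <- fold
    }
  }
  if (length(failures) > 0.1 * k) {
    stop("more than 10% of cross-validation folds failed:\n  ",
         paste(utils::head(failures, 5), collapse = "\n  "), call. = FALSE)
  }
  kept <- if (accumulate) records else records[length(records)]
  out <- structure(list(
    records = do.call(rbind, kept),
    k = k, test_fraction = test_fraction, seed = as.integer(seed),
    n = n, formulae = formulae, failures = failures,
    lens_model = cohort$lens_model[1]), class = "iol_cv")
  out
}

#' @export
print.iol_cv <- function(x, ...) {
  cat("Monte-Carlo cross-validation (", x$k, "repetitions, ",
      100 * x$test_fraction, "% held out, seed", x$seed, ")\n")
  cat("  lens model:", x$lens_model, "  cohort n =", x$n, "\n")
  cat("  accumulated records:", nrow(x$records), "over",
      length(x$formulae), "formulae\n")
  if (length(x$failures)) cat("  failed folds:", length(x$failures), "\n")
  invisible(x)
}

#' Prediction-error metrics by formula and axial-length stratum
#'
#' Computes, for every (formula, stratum) cell with at least one record:
#' the mean/median/SD/range of the prediction error, the mean/median
#' absolute error, and the percentage of eyes with |PE| within closed bands
#' of 0.5, 1.0 and 1.5 D.
#'
#' @param records Prediction-record data frame (from [mc_crossval()], or
#'   its `$records`).
#' @param bands Accuracy bands (D).
#' @return Data frame with one row per (formula, stratum); strata include
#'   `"all"`.  Empty cells are absent, not zero.
#' @export
compute_metrics <- function(records, bands = c(0.5, 1.0, 1.5)) {
  if (inherits(records, "iol_cv")) records <- records$records
  stopifnot(all(c("formula_id", "al_mm", "pe") %in% names(records)))
  records$stratum <- stratify_axial_length(records$al_mm)
  cells <- expand.grid(
    formula_id = unique(records$formula_id),
    stratum = c(levels(records$stratum), "all"),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- records$formula_id == cells$formula_id[i]
    if (cells$stratum[i] != "all") {
      sel <- sel & records$stratum == cells$stratum[i]
    }
    pe <- records$pe[sel]
    if (!length(pe)) return(NULL)
    ae <- abs(pe)
    row <- data.frame(
      formula_id = cells$formula_id[i], stratum = cells$stratum[i],
      n = length(pe), mpe = mean(pe),
      sd = if (length(pe) > 1) stats::sd(pe) else 0,
      medpe = stats::median(pe), pe_min = min(pe), pe_max = max(pe),
      mae = mean(ae), mae_sd = if (length(ae) > 1) stats::sd(ae) else 0,
      medae = stats::median(ae))
    for (b in bands) {
      row[[sprintf("pct_within_%.1f", b)]] <- 100 * mean(ae <= b)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
summary.iol_cv <- function(object, ...) {
  out <- compute_metrics(object$records, ...)
  class(out) <- c("summary.iol_cv", class(out))
  out
}

#' @export
print.summary.iol_cv <- function(x, digits = 3, ...) {
  cat("Prediction-error metrics by formula and axial-length stratum\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.iol_cv <- function(x, band = 1.0, ...) {
  m <- compute_metrics(x$records)
  m <- m[m$stratum == "all", ]
  graphics::barplot(m[[sprintf("pct_within_%.1f", band)]],
                    names.arg = m$formula_id,
                    ylab = sprintf("%% eyes with |PE| <= %.1f D", band),
                    ylim = c(0, 100), ...)
  graphics::abline(h = 85, lty = 2)
  invisible(x)
}
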