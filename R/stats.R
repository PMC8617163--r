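# Non-parametric comparison battery over accumulated prediction records:
# Shapiro-Wilk screening, one-sample Wilcoxon against a zero median,
# Friedman + paired Wilcoxon for absolute errors, Cochran's Q + McNemar for
# within-band accuracy.  Significance level 0.05 throughout.

test_report <- function(test_name, statistic, p_value, n, method_detail,
                        groups = NA_character_, alpha = 0.05) {
  data.frame(test = test_name, groups = groups,
             statistic = as.numeric(statistic),
             p_value = as.numeric(p_value), n = n, alpha = alpha,
             verdict = ifelse(p_value < alpha, "significant",
                              "not_significant"),
             method = method_detail, stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality screen
#'
#' Used to justify the non-parametric battery: prediction errors from
#' clinical cohorts are routinely non-normal.
#'
#' @param values Numeric sample, 3 <= n <= 5000.
#' @return A one-row test-report data frame.
#' @export
normality_screen <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("degenerate sample: all values identical", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  test_report("shapiro_wilk", sw$statistic, sw$p.value, n, "exact")
}

# one-sample / paired signed-rank with explicit zero- and tie-handling:
# exact distribution when n <= 25 and no tied magnitudes, otherwise normal
# approximation with tie correction (wilcox.test's default machinery)
signed_rank <- function(x, label) {
  x <- x[is.finite(x)]
  nz <- x[x != 0]
  if (!length(x)) stop("empty sample", call. = FALSE)
  if (!length(nz)) {
    return(test_report(label, 0, 1, length(x), "degenerate (all zeros)"))
  }
  exact_ok <- length(nz) <= 25 && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0, exact = exact_ok))
  test_report(label, wt$statistic, wt$p.value, length(nz),
              if (exact_ok) "exact" else "asymptotic")
}

#' One-sample Wilcoxon signed-rank test for a zero median
#'
#' Two-sided test of whether the median prediction error (or absolute
#' prediction error) equals zero.  Exact zeros are dropped before ranking.
#'
#' @param pe_values Numeric vector of prediction errors.
#' @return A one-row test-report data frame.
#' @export
median_zero_test <- function(pe_values) {
  pe_values <- pe_values[is.finite(pe_values)]
  if (length(pe_values) < 4) {
    stop("median_zero_test requires at least 4 values", call. = FALSE)
  }
  if (all(pe_values == 0)) {
    stop("degenerate sample: all prediction errors are exactly zero",
         call. = FALSE)
  }
  signed_rank(pe_values, "wilcoxon_signed_rank_1s")
}

# Friedman test that reports (0, 1) in the fully tied degenerate case
# instead of stats::friedman.test's NaN
friedman_safe <- function(mat) {
  if (all(apply(mat, 1, function(r) length(unique(r)) == 1))) {
    return(test_report("friedman", 0, 1, nrow(mat),
                       "degenerate (all rows tied)"))
  }
  ft <- stats::friedman.test(mat)
  test_report("friedman", ft$statistic, ft$p.value, nrow(mat), "asymptotic")
}

#' Compare absolute prediction errors across the five formulae
#'
#' Friedman test across all columns; pairwise Wilcoxon signed-rank tests of
#' the reference formula (default `"MM"`) against every other column.
#' P-values are unadjusted by default; Holm adjustment is available.
#'
#' @param abs_pe Matrix or data frame of absolute prediction errors, one
#'   column per formula, rows paired by eye.
#' @param reference Column name of the reference formula.
#' @param adjust `"none"` or `"holm"` for the pairwise p-values.
#' @return List with elements `friedman` (one-row report) and `pairwise`
#'   (one row per comparison).
#' @export
compare_absolute_errors <- function(abs_pe, reference = "MM",
                                    adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  mat <- as.matrix(abs_pe)
  if (is.null(colnames(mat)) || !reference %in% colnames(mat)) {
    stop("columns must be named and include the reference '", reference,
         "'", call. = FALSE)
  }
  if (anyNA(mat)) stop("misaligned columns: NA in paired data",
                       call. = FALSE)
  fr <- friedman_safe(mat)
  others <- setdiff(colnames(mat), reference)
  pw <- do.call(rbind, lapply(others, function(f) {
    rep_ <- signed_rank(mat[, reference] - mat[, f], "wilcoxon_paired")
    rep_$groups <- paste(reference, "vs", f)
    rep_
  }))
  if (adjust == "holm") {
    pw$p_value <- stats::p.adjust(pw$p_value, "holm")
    pw$verdict <- ifelse(pw$p_value < pw$alpha, "significant",
                         "not_significant")
  }
  list(friedman = fr, pairwise = pw)
}

#' Cochran's Q test for paired binary outcomes
#'
#' Tests whether the success proportion differs across k paired binary
#' columns (here: whether an eye's |PE| falls within an accuracy band under
#' each formula).  Degenerate inputs (no between-column variation) report
#' Q = 0, p = 1.
#'
#' @param x Matrix or data frame of 0/1 indicators, rows paired by eye.
#' @return A one-row test-report data frame.
#' @export
cochran_q <- function(x) {
  mat <- as.matrix(x)
  if (!all(mat %in% c(0, 1))) {
    stop("Cochran's Q requires binary (0/1) indicators", call. = FALSE)
  }
  k <- ncol(mat)
  cj <- colSums(mat)
  ri <- rowSums(mat)
  tt <- sum(mat)
  denom <- k * tt - sum(ri^2)
  if (denom == 0) {
    return(test_report("cochran_q", 0, 1, nrow(mat),
                       "degenerate (no discordance)"))
  }
  q <- k * (k - 1) * sum((cj - tt / k)^2) / denom
  test_report("cochran_q", q, stats::pchisq(q, k - 1, lower.tail = FALSE),
              nrow(mat), "asymptotic chi-square")
}

#' McNemar test for one pair of binary columns
#'
#' Exact binomial version when there are fewer than `exact_below`
#' discordant pairs, otherwise the chi-square approximation with continuity
#' correction.
#'
#' @param x,y Paired 0/1 vectors.
#' @param exact_below Use the exact test when discordant pairs
#'   `b + c < exact_below`.
#' @return A one-row test-report data frame with the discordant counts in
#'   attributes `"b"` (x only) and `"c"` (y only).
#' @export
mcnemar_pair <- function(x, y, exact_below = 25) {
  if (!all(c(x, y) %in% c(0, 1))) {
    stop("McNemar requires binary (0/1) indicators", call. = FALSE)
  }
  if (length(x) != length(y)) stop("pairing error: unequal lengths",
                                   call. = FALSE)
  b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1)
  nd <- b + cc
  if (nd == 0) {
    rep_ <- test_report("mcnemar", 0, 1, length(x),
                        "degenerate (no discordant pairs)")
  } else if (nd < exact_below) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), nd, 0.5))
    rep_ <- test_report("mcnemar", min(b, cc), p, length(x),
                        "exact binomial")
  } else {
    stat <- (abs(b - cc) - 1)^2 / nd
    rep_ <- test_report("mcnemar", stat,
                        stats::pchisq(stat, 1, lower.tail = FALSE),
                        length(x), "chi-square with continuity correction")
  }
  attr(rep_, "b") <- b
  attr(rep_, "c") <- cc
  rep_
}

#' Compare within-band prediction accuracy across formulae
#'
#' Cochran's Q across all formulae; McNemar for the reference formula
#' against each other column, with the pairwise verdict classified as
#' `no_difference`, `<ref>_outperformed` or `<ref>_underperformed` by the
#' sign of the discordance.
#'
#' @param indicators Matrix or data frame of 0/1 within-band indicators,
#'   one column per formula, rows paired by eye.
#' @param reference Column name of the reference formula.
#' @param band Accuracy band the indicators refer to (annotation only).
#' @return List with elements `cochran_q` (one-row report) and `pairwise`
#'   (one row per comparison, with a `direction` column).
#' @export
compare_accuracy <- function(indicators, reference = "MM", band = NA_real_) {
  mat <- as.matrix(indicators)
  if (is.null(colnames(mat)) || !reference %in% colnames(mat)) {
    stop("columns must be named and include the reference '", reference,
         "'", call. = FALSE)
  }
  cq <- cochran_q(mat)
  others <- setdiff(colnames(mat), reference)
  pw <- do.call(rbind, lapply(others, function(f) {
    rep_ <- mcnemar_pair(mat[, reference], mat[, f])
    b <- attr(rep_, "b"); cc <- attr(rep_, "c")
    rep_$groups <- paste(reference, "vs", f)
    rep_$band <- band
    rep_$direction <- if (rep_$p_value >= rep_$alpha) "no_difference"
      else if (b > cc) paste0(reference, "_outperformed")
      else paste0(reference, "_underperformed")
    rep_
  }))
  list(cochran_q = cq, pairwise = pw)
}

#' Full statistical battery over accumulated prediction records
#'
#' Runs, for each axial-length stratum with enough records: the Friedman +
#' pairwise Wilcoxon comparison of absolute errors, and Cochran's Q +
#' pairwise McNemar of the within-band accuracy for each band.
#'
#' @param records Prediction records (from [mc_crossval()]).
#' @param bands Accuracy bands (D).
#' @param reference Reference formula.
#' @param min_n Minimum records per formula in a stratum for it to be
#'   tested.
#' @return Data frame of test reports (`stratum`, `test`, `groups`,
#'   `statistic`, `p_value`, ...).
#' @export
run_test_battery <- function(records, bands = c(0.5, 1.0, 1.5),
                             reference = "MM", min_n = 20) {
  if (inherits(records, "iol_cv")) records <- records$records
  records$stratum <- as.character(stratify_axial_length(records$al_mm))
  out <- list()
  for (st in c(unique(records$stratum), "all")) {
    sub <- if (st == "all") records else records[records$stratum == st, ]
    wide <- pe_matrix(sub)
    if (is.null(wide) || nrow(wide) < min_n) next
    abs_pe <- abs(wide)
    ae <- compare_absolute_errors(abs_pe, reference)
    block <- rbind(ae$friedman, ae$pairwise)
    for (b in bands) {
      acc <- compare_accuracy(1 * (abs_pe <= b), reference, band = b)
      blk <- rbind(acc$cochran_q, acc$pairwise[names(acc$cochran_q)])
      blk$band <- b
      dirs <- c(NA_character_, acc$pairwise$direction)
      blk$direction <- dirs
      block <- merge_report(block, blk)
    }
    block$stratum <- st
    out[[st]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# bind report blocks that may differ in annotation columns
merge_report <- function(a, b) {
  for (col in setdiff(names(b), names(a))) a[[col]] <- NA
  for (col in setdiff(names(a), names(b))) b[[col]] <- NA
  rbind(a, b[names(a)])
}

# records (long) -> eyes x formulae PE matrix, pairing rows by (eye, fold)
pe_matrix <- function(records) {
  formulae <- unique(records$formula_id)
  if (length(formulae) < 2) return(NULL)
  key <- paste(records$eye_id, records$fold, sep = "#")
  wide <- stats::reshape(
    data.frame(key = key, formula_id = records$formula_id,
               pe = records$pe),
    idvar = "key", timevar = "formula_id", direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^pe\\.", "", colnames(mat))
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  mat
}
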