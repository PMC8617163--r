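# Synthetic cataract-surgery cohorts with known ground truth.
#
# Biometry is drawn from a truncated multivariate normal calibrated to the
# published per-lens summary statistics (sample sizes, means, SDs, observed
# ranges) of three real cohorts; outcomes are produced by pushing a known
# ground-truth ELP through the vergence optics, with clinically quantized
# implant powers and manifest refractions.

# per-variable rows: mean, sd, median, min, max
.profiles <- list(
  "SN60WF" = list(
    lens_model = "SN60WF", n = 265, pct_female = 0.52,
    age = c(66, 10, 67, 36, 90),
    al  = c(23.80, 1.53, 23.49, 20.50, 29.63),
    k1  = c(43.06, 1.83, 43.19, 35.56, 47.20),
    k2  = c(43.84, 1.94, 43.83, 36.06, 48.70),
    acd = c(3.24, 0.41, 3.00, 2.17, 4.80)),
  "Softec HDO" = list(
    lens_model = "Softec HDO", n = 256, pct_female = 0.50,
    age = c(71, 10, 73, 45, 94),
    al  = c(23.59, 1.42, 23.46, 20.06, 29.37),
    k1  = c(43.25, 1.65, 43.38, 35.70, 46.88),
    k2  = c(44.03, 1.69, 44.12, 36.20, 48.49),
    acd = c(3.21, 0.39, 3.00, 2.33, 4.22)),
  "AT LISA tri839 MP" = list(
    lens_model = "AT LISA tri839 MP", n = 160, pct_female = 0.60,
    age = c(58, 7, 58, 44, 92),
    al  = c(23.55, 1.32, 23.42, 20.48, 27.85),
    k1  = c(42.86, 1.50, 42.72, 38.38, 47.34),
    k2  = c(43.50, 1.54, 43.47, 38.96, 47.77),
    acd = c(3.22, 0.35, 3.00, 2.37, 4.22))
)

# biometry correlation over (AL, K1, K2, ACD); flat/steep keratometry are
# near-collinear (their gap is the corneal astigmatism, ~0.8 +/- 0.5 D),
# longer eyes run slightly flatter and have deeper chambers
default_biometry_correlation <- function() {
  m <- diag(4)
  dimnames(m) <- list(c("al", "k1", "k2", "acd"), c("al", "k1", "k2", "acd"))
  m["al", "acd"] <- m["acd", "al"] <- 0.45
  m["k1", "k2"] <- m["k2", "k1"] <- 0.96
  m["al", "k1"] <- m["k1", "al"] <- -0.30
  m["al", "k2"] <- m["k2", "al"] <- -0.30
  m
}

#' Calibration profile of a study cohort
#'
#' Returns the per-lens calibration (sample size, and mean / SD / median /
#' range of age, AL, K1, K2, ACD) of one of the three study cohorts, plus
#' the default biometry correlation structure.
#'
#' @param lens_model One of `"SN60WF"`, `"Softec HDO"`,
#'   `"AT LISA tri839 MP"`.
#' @return A list of class `"cohort_profile"`.
#' @export
#' @examples
#' cohort_profile("SN60WF")$al
cohort_profile <- function(lens_model) {
  if (!lens_model %in% names(.profiles)) {
    stop("unknown lens_model '", lens_model, "'; known profiles: ",
         paste(names(.profiles), collapse = ", "), call. = FALSE)
  }
  p <- .profiles[[lens_model]]
  p$correlation <- default_biometry_correlation()
  for (v in c("age", "al", "k1", "k2", "acd")) {
    names(p[[v]]) <- c("mean", "sd", "median", "min", "max")
  }
  structure(p, class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("Cohort profile:", x$lens_model, " (n =", x$n, ")\n")
  for (v in c("age", "al", "k1", "k2", "acd")) {
    cat(sprintf("  %-4s %6.2f +/- %5.2f  median %6.2f  range [%.2f, %.2f]\n",
                v, x[[v]]["mean"], x[[v]]["sd"], x[[v]]["median"],
                x[[v]]["min"], x[[v]]["max"]))
  }
  invisible(x)
}

# Truncating to the profile's observed ranges and re-ordering the flat/steep
# pair both shift sample means away from the targets; this fixed-point
# correction adjusts the pre-truncation means (analytic univariate
# truncation shift + analytic swap transfer between K1 and K2) so the
# generated cohort reproduces the published marginal means.
calibrate_sampling_means <- function(target, sd, sigma, lo, hi,
                                     iterations = 6) {
  adj <- target
  sd_diff <- sqrt(sigma[2, 2] + sigma[3, 3] - 2 * sigma[2, 3])
  for (it in seq_len(iterations)) {
    a <- (lo - adj) / sd
    b <- (hi - adj) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    shift <- sd * (stats::dnorm(a) - stats::dnorm(b)) / z
    mu_d <- adj[2] - adj[3]
    swap <- mu_d * stats::pnorm(mu_d / sd_diff) +
      sd_diff * stats::dnorm(mu_d / sd_diff)
    post <- adj + shift
    post[2] <- post[2] - swap
    post[3] <- post[3] + swap
    adj <- adj - (post - target)
  }
  adj
}

#' Sample pre-operative biometry from a cohort profile
#'
#' Draws `(AL, K1, K2, ACD)` from a multivariate normal with the profile's
#' means, SDs and correlations, rejecting draws outside the profile's
#' observed ranges.  Sampled pairs with flat > steep keratometry are swapped
#' so the column roles stay honest.  Age and sex are sampled for
#' completeness (they are never predictors).
#'
#' @param profile A [cohort_profile()].
#' @param n Number of eyes.
#' @param seed Integer seed.
#' @return Biometry data frame (`lens_model`, `age`, `sex`, `al_mm`, `k1_d`,
#'   `k2_d`, `acd_mm`).
#' @export
sample_biometry <- function(profile, n = profile$n, seed = 1L) {
  stopifnot(inherits(profile, "cohort_profile"), n >= 1)
  set.seed(as.integer(seed))
  mu <- c(profile$al["mean"], profile$k1["mean"], profile$k2["mean"],
          profile$acd["mean"])
  sd <- c(profile$al["sd"], profile$k1["sd"], profile$k2["sd"],
          profile$acd["sd"])
  sigma <- diag(sd) %*% profile$correlation %*% diag(sd)
  ch <- chol(sigma)
  lo <- c(profile$al["min"], profile$k1["min"], profile$k2["min"],
          profile$acd["min"])
  hi <- c(profile$al["max"], profile$k1["max"], profile$k2["max"],
          profile$acd["max"])
  mu <- calibrate_sampling_means(mu, sd, sigma, lo, hi)
  acc <- matrix(numeric(0), ncol = 4)
  tried <- 0L
  while (nrow(acc) < n) {
    m <- max(2L * n, 100L)
    z <- matrix(stats::rnorm(4 * m), m, 4) %*% ch
    x <- sweep(z, 2, mu, "+")
    # enforce the flat/steep roles before range checks
    swap <- x[, 2] > x[, 3]
    tmp <- x[swap, 2]; x[swap, 2] <- x[swap, 3]; x[swap, 3] <- tmp
    ok <- rep(TRUE, m)
    for (j in 1:4) ok <- ok & x[, j] >= lo[j] & x[, j] <= hi[j]
    acc <- rbind(acc, x[ok, , drop = FALSE])
    tried <- tried + m
    if (tried >= 100L * n && nrow(acc) < 0.01 * tried) {
      stop("infeasible profile: truncation acceptance below 1%",
           call. = FALSE)
    }
  }
  acc <- acc[seq_len(n), , drop = FALSE]
  age <- round(stats::rnorm(n, profile$age["mean"], profile$age["sd"]))
  age <- pmin(pmax(age, profile$age["min"]), profile$age["max"])
  sex <- ifelse(stats::runif(n) < profile$pct_female, "F", "M")
  data.frame(lens_model = profile$lens_model, age = age, sex = sex,
             al_mm = acc[, 1], k1_d = acc[, 2], k2_d = acc[, 3],
             acd_mm = acc[, 4])
}

#' Ground-truth effective-lens-position process
#'
#' The linear kind mirrors a Haigis-style lens:
#' `d = 0.9 + 0.40 ACD + 0.08 AL`.  The nonlinear kind adds a saturating
#' axial-length bend `0.25 tanh((AL - 23.5) / 1.5)` and a mild
#' keratometry-by-length interaction `0.01 (K - 43.5)(AL - 23.5)`, the
#' regime in which a flexible ELP predictor has something to gain over the
#' linear one.
#'
#' @param kind `"nonlinear"` or `"linear"`.
#' @param coefficients Named numeric overrides of `intercept`, `acd`, `al`
#'   (the linear part).
#' @param elp_noise_sd SD of the per-eye ELP perturbation (mm).
#' @return A list of class `"ground_truth_elp"`.
#' @export
ground_truth_elp <- function(kind = c("nonlinear", "linear"),
                             coefficients = NULL, elp_noise_sd = 0.15) {
  kind <- match.arg(kind)
  coefs <- c(intercept = 0.9, acd = 0.40, al = 0.08)
  if (!is.null(coefficients)) coefs[names(coefficients)] <- coefficients
  stopifnot(elp_noise_sd >= 0)
  structure(list(kind = kind, coefficients = coefs,
                 elp_noise_sd = elp_noise_sd),
            class = "ground_truth_elp")
}

# deterministic part of the ground-truth ELP for a biometry table
eval_ground_truth <- function(gt, biometry) {
  d <- gt$coefficients["intercept"] +
    gt$coefficients["acd"] * biometry$acd_mm +
    gt$coefficients["al"] * biometry$al_mm
  if (gt$kind == "nonlinear") {
    k <- (biometry$k1_d + biometry$k2_d) / 2
    d <- d + 0.25 * tanh((biometry$al_mm - 23.5) / 1.5) +
      0.01 * (k - 43.5) * (biometry$al_mm - 23.5)
  }
  as.numeric(d)
}

#' Observation noise model for simulated surgery
#'
#' Manifest refraction is clinically quantized (0.125 D steps) and measured
#' with error; implant powers come in manufacturing steps.  The default
#' refraction noise SD of 0.35 D is calibrated so that all-eyes prediction
#' error SDs land near 0.5 D, the scale reported for real cohorts.
#'
#' @param refraction_noise_sd SD of the refraction measurement noise (D).
#' @param refraction_step Quantization step of the manifest refraction (D);
#'   0 disables quantization.
#' @param power_step Manufacturing step of implant powers (D); 0 disables
#'   rounding.
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(refraction_noise_sd = 0.35, refraction_step = 0.125,
                        power_step = 0.5) {
  stopifnot(refraction_noise_sd >= 0, refraction_step >= 0, power_step >= 0)
  structure(list(refraction_noise_sd = refraction_noise_sd,
                 refraction_step = refraction_step,
                 power_step = power_step),
            class = "noise_model")
}

round_step <- function(x, step) if (step > 0) round(x / step) * step else x

#' Simulate surgical outcomes for a biometry table
#'
#' For each eye the true ELP is the ground-truth value plus ELP noise; the
#' implanted power is the vergence solution for the target refraction at
#' that true ELP, rounded to the manufacturing step; the achieved SE
#' refraction is the vergence prediction at the implanted power plus
#' measurement noise, quantized to the refraction step.
#'
#' @param biometry Biometry data frame from [sample_biometry()].
#' @param gt A [ground_truth_elp()].
#' @param noise A [noise_model()].
#' @param target_rx Surgical target refraction (D).
#' @param seed Integer seed.
#' @param constants An [optical_constants()] object.
#' @param pc_transform Corneal power convention of the forward optics:
#'   `"mean_k"` uses the mean keratometry directly (the MM / thin-lens
#'   convention); `"haigis"` rescales it by the Haigis corneal index so a
#'   Haigis-generated cohort is exactly self-consistent.
#' @return Cohort data frame with `id`, implanted powers and achieved
#'   refractions; true ELP values in the `"elp_true"` attribute and skipped
#'   eyes in the `"audit"` attribute.
#' @export
simulate_outcomes <- function(biometry, gt = ground_truth_elp(),
                              noise = noise_model(), target_rx = 0,
                              seed = 1L, constants = optical_constants(),
                              pc_transform = c("mean_k", "haigis")) {
  pc_transform <- match.arg(pc_transform)
  stopifnot(inherits(gt, "ground_truth_elp"), inherits(noise, "noise_model"))
  set.seed(as.integer(seed))
  n <- nrow(biometry)
  d_true <- eval_ground_truth(gt, biometry) +
    stats::rnorm(n, 0, gt$elp_noise_sd)
  if (any(d_true <= 1.5 | d_true >= 8.0)) {
    stop("ground truth produced ELP outside the plausible (1.5, 8) mm ",
         "window", call. = FALSE)
  }
  k <- mean_corneal_power(biometry$k1_d, biometry$k2_d)
  pc <- if (pc_transform == "haigis") haigis_corneal_power(k) else k
  ok <- rep(TRUE, n)
  p_impl <- ach <- rep(NA_real_, n)
  res <- tryCatch({
    p_raw <- iol_power_for_refraction(biometry$al_mm, d_true, pc, target_rx,
                                      constants)
    p_impl <- round_step(p_raw, noise$power_step)
    ach <- predict_refraction(biometry$al_mm, d_true, pc, p_impl, constants)
    TRUE
  }, error = function(e) FALSE)
  if (!res) {
    # fall back to per-eye evaluation so singular eyes can be skipped
    for (i in seq_len(n)) {
      ok[i] <- tryCatch({
        p_raw <- iol_power_for_refraction(biometry$al_mm[i], d_true[i],
                                          pc[i], target_rx, constants)
        p_impl[i] <- round_step(p_raw, noise$power_step)
        ach[i] <- predict_refraction(biometry$al_mm[i], d_true[i], pc[i],
                                     p_impl[i], constants)
        TRUE
      }, error = function(e) FALSE)
    }
    if (sum(!ok) > 0.01 * n) {
      stop("more than 1% of simulated eyes hit optical singularities",
           call. = FALSE)
    }
  }
  ach <- ach + stats::rnorm(n, 0, noise$refraction_noise_sd)
  ach <- round_step(ach, noise$refraction_step)
  out <- cbind(data.frame(id = sprintf("eye%04d", seq_len(n))), biometry,
               iol_power_d = p_impl, postop_se_d = ach)
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "elp_true") <- d_true[ok]
  attr(out, "audit") <- list(n_skipped = sum(!ok))
  out
}

#' Generate a complete synthetic cohort
#'
#' One-call composition of [cohort_profile()], [sample_biometry()] and
#' [simulate_outcomes()] with the default ground truth and noise model.
#'
#' @param lens_model Profile name (see [cohort_profile()]).
#' @param n Number of eyes; defaults to the profile's sample size.
#' @param gt_kind `"nonlinear"` or `"linear"` ground-truth ELP.
#' @param seed Integer seed.
#' @param gt,noise,target_rx,constants,pc_transform Overrides passed to
#'   [simulate_outcomes()].
#' @return Cohort data frame (see [simulate_outcomes()]).
#' @export
#' @examples
#' cohort <- generate_cohort("SN60WF", n = 50, seed = 7)
#' head(cohort)
generate_cohort <- function(lens_model = "SN60WF", n = NULL,
                            gt_kind = c("nonlinear", "linear"), seed = 1L,
                            gt = NULL, noise = noise_model(), target_rx = 0,
                            constants = optical_constants(),
                            pc_transform = "mean_k") {
  gt_kind <- match.arg(gt_kind)
  profile <- cohort_profile(lens_model)
  if (is.null(n)) n <- profile$n
  if (is.null(gt)) gt <- ground_truth_elp(gt_kind)
  biometry <- sample_biometry(profile, n, seed = seed)
  simulate_outcomes(biometry, gt = gt, noise = noise, target_rx = target_rx,
                    seed = as.integer(seed) + 1L, constants = constants,
                    pc_transform = pc_transform)
}
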