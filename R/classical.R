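# The four classical third-generation IOL power formulae, each as an ELP
# estimator plus its own published vergence variant:
#   SRK/T      Retzlaff et al. 1990 (+ erratum)
#   Hoffer Q   Hoffer 1993 (+ errata)
#   Holladay I Holladay et al. 1988
#   Haigis     Haigis et al. 2000
# They differ only in how the effective lens position d is estimated and in
# their internal corneal/ocular indices.

#' @rdname optimize_constants
#' @export
classical_formulae <- c("SRKT", "HOFFERQ", "HOLLADAY1", "HAIGIS")

#' Lens constant set for a classical formula
#'
#' Holds the per-lens personalization constant(s) of one formula: `pacd` for
#' Hoffer Q, `sf` for Holladay I, `a_constant` for SRK/T, `(a0, a1, a2)` for
#' Haigis.
#'
#' @param formula_id One of `"SRKT"`, `"HOFFERQ"`, `"HOLLADAY1"`, `"HAIGIS"`.
#' @param pacd Personalized anterior chamber depth, mm (Hoffer Q).
#' @param sf Surgeon factor, mm (Holladay I).
#' @param a_constant A-constant, dimensionless (SRK/T).
#' @param a0,a1,a2 Haigis regression constants (a0 mm, a1 and a2
#'   dimensionless).
#' @param lens_model Optional lens model label the constants belong to.
#' @return An object of class `"lens_constants"`.
#' @export
#' @examples
#' lens_constants("SRKT", a_constant = 118.4)
lens_constants <- function(formula_id, pacd = NULL, sf = NULL,
                           a_constant = NULL, a0 = NULL, a1 = NULL,
                           a2 = NULL, lens_model = NA_character_) {
  formula_id <- match.arg(formula_id, classical_formulae)
  need <- switch(formula_id,
                 SRKT = !is.null(a_constant),
                 HOFFERQ = !is.null(pacd),
                 HOLLADAY1 = !is.null(sf),
                 HAIGIS = !is.null(a0) && !is.null(a1) && !is.null(a2))
  if (!need) {
    stop("constants required by ", formula_id, " are not populated",
         call. = FALSE)
  }
  structure(list(formula_id = formula_id, pacd = pacd, sf = sf,
                 a_constant = a_constant, a0 = a0, a1 = a1, a2 = a2,
                 lens_model = lens_model, provenance = NULL),
            class = "lens_constants")
}

#' @export
print.lens_constants <- function(x, ...) {
  vals <- switch(x$formula_id,
    SRKT = sprintf("A = %.4f", x$a_constant),
    HOFFERQ = sprintf("pACD = %.4f mm", x$pacd),
    HOLLADAY1 = sprintf("SF = %.4f mm", x$sf),
    HAIGIS = sprintf("a0 = %.4f, a1 = %.4f, a2 = %.4f",
                     x$a0, x$a1, x$a2))
  cat(x$formula_id, "constants:", vals, "\n")
  if (!is.null(x$provenance)) {
    cat("  optimized on n =", x$provenance$n_train,
        " [", x$provenance$hash, "] ", x$provenance$date, "\n")
  }
  invisible(x)
}

# ---- per-formula ELP estimators (vectorized over eyes) ----

elp_haigis <- function(acd, al, a0, a1, a2) a0 + a1 * acd + a2 * al

elp_hofferq <- function(al, k, pacd) {
  al_c <- pmin(pmax(al, 18.5), 31)
  if (any(al_c != al)) {
    warning("Hoffer Q: axial length clamped to [18.5, 31] mm for ",
            sum(al_c != al), " eye(s)", call. = FALSE)
  }
  m <- ifelse(al_c <= 23, 1, -1)
  g <- ifelse(al_c <= 23, 28, 23.5)
  tand <- function(deg) tan(deg * pi / 180)
  acd <- pacd + 0.3 * (al_c - 23.5) + tand(k)^2 +
    0.1 * m * (23.5 - al_c)^2 * tand(0.1 * (g - al_c)^2) - 0.99166
  pmin(pmax(acd, 2.5), 6.5)
}

elp_holladay1 <- function(al, k, sf) {
  r <- 337.5 / k
  ag <- pmin(al * 12.5 / 23.45, 13.5)
  disc <- pmax(r^2 - ag^2 / 4, 0)
  aacd <- 0.56 + r - sqrt(disc)
  aacd + sf
}

elp_srkt <- function(al, k, a_constant) {
  r <- 337.5 / k
  lcor <- ifelse(al <= 24.2, al, -3.446 + 1.715 * al - 0.0237 * al^2)
  cw <- -5.41 + 0.58412 * lcor + 0.098 * k
  disc <- pmax(r^2 - cw^2 / 4, 0)
  h <- r - sqrt(disc)
  acd_const <- 0.62467 * a_constant - 68.747
  h + (acd_const - 3.336)
}

#' Effective lens position under a classical formula
#'
#' @param formula_id One of `"SRKT"`, `"HOFFERQ"`, `"HOLLADAY1"`, `"HAIGIS"`.
#' @param cohort Cohort data frame (columns `al_mm`, `k1_d`, `k2_d`, and
#'   `acd_mm` for Haigis).
#' @param constants A [lens_constants()] object for `formula_id`.
#' @return Estimated ELP in mm, one value per eye.
#' @export
estimate_elp <- function(formula_id, cohort, constants) {
  formula_id <- match.arg(formula_id, classical_formulae)
  stopifnot(inherits(constants, "lens_constants"),
            constants$formula_id == formula_id)
  k <- mean_corneal_power(cohort$k1_d, cohort$k2_d)
  al <- cohort$al_mm
  switch(formula_id,
    HAIGIS = {
      if (is.null(cohort$acd_mm) || anyNA(cohort$acd_mm)) {
        stop("Haigis requires the pre-operative ACD ('acd_mm') on every eye",
             call. = FALSE)
      }
      elp_haigis(cohort$acd_mm, al, constants$a0, constants$a1, constants$a2)
    },
    HOFFERQ = elp_hofferq(al, k, constants$pacd),
    HOLLADAY1 = elp_holladay1(al, k, constants$sf),
    SRKT = elp_srkt(al, k, constants$a_constant))
}

# shared corneal-radius vergence chain used by SRK/T and Holladay I
# (na, ncm1 are the formula's internal indices; v = vertex in mm; lengths mm)
radius_vergence_refraction <- function(power, l, c, r, na, ncm1, v = 12) {
  num <- 1000 * na * (na * r - ncm1 * l) -
    power * (l - c) * (na * r - ncm1 * c)
  den <- na * (v * (na * r - ncm1 * l) + l * r) -
    0.001 * power * (l - c) * (v * (na * r - ncm1 * c) + c * r)
  num / den
}

radius_vergence_power <- function(ref, l, c, r, na, ncm1, v = 12) {
  num <- 1000 * na *
    (na * r - ncm1 * l - 0.001 * ref * (v * (na * r - ncm1 * l) + l * r))
  den <- (l - c) *
    (na * r - ncm1 * c - 0.001 * ref * (v * (na * r - ncm1 * c) + c * r))
  num / den
}

# Haigis converts keratometer readings (337.5 convention) back to a radius
# and applies its own corneal index 1.3315
haigis_corneal_power <- function(k) k * 331.5 / 337.5

#' Predicted refraction under a classical formula
#'
#' Each formula combines its own ELP estimate with its own published
#' vergence variant and internal indices; the result is the spectacle-plane
#' predicted spherical-equivalent refraction for an implanted power.
#'
#' @inheritParams estimate_elp
#' @param power Implanted IOL power (D), recycled over eyes.
#' @return Predicted SE refraction (D), one value per eye.
#' @export
predict_refraction_classical <- function(formula_id, cohort, constants,
                                         power) {
  formula_id <- match.arg(formula_id, classical_formulae)
  elp <- estimate_elp(formula_id, cohort, constants)
  k <- mean_corneal_power(cohort$k1_d, cohort$k2_d)
  al <- cohort$al_mm
  switch(formula_id,
    SRKT = {
      l <- al + (0.65696 - 0.02029 * al)
      radius_vergence_refraction(power, l, elp, 337.5 / k,
                                 na = 1.336, ncm1 = 0.333)
    },
    HOLLADAY1 = {
      radius_vergence_refraction(power, al + 0.2, elp, 337.5 / k,
                                 na = 1.336, ncm1 = 1 / 3)
    },
    HOFFERQ = predict_refraction(al, elp + 0.05, k, power),
    HAIGIS = predict_refraction(al, elp, haigis_corneal_power(k), power))
}

#' Recommended IOL power under a classical formula
#'
#' @inheritParams predict_refraction_classical
#' @param target_rx Desired post-operative refraction (D).
#' @return Exact (unrounded) IOL power (D), one value per eye.
#' @export
recommend_power_classical <- function(formula_id, cohort, constants,
                                      target_rx = 0) {
  formula_id <- match.arg(formula_id, classical_formulae)
  elp <- estimate_elp(formula_id, cohort, constants)
  k <- mean_corneal_power(cohort$k1_d, cohort$k2_d)
  al <- cohort$al_mm
  switch(formula_id,
    SRKT = {
      l <- al + (0.65696 - 0.02029 * al)
      radius_vergence_power(target_rx, l, elp, 337.5 / k,
                            na = 1.336, ncm1 = 0.333)
    },
    HOLLADAY1 = radius_vergence_power(target_rx, al + 0.2, elp, 337.5 / k,
                                      na = 1.336, ncm1 = 1 / 3),
    HOFFERQ = iol_power_for_refraction(al, elp + 0.05, k, target_rx),
    HAIGIS = iol_power_for_refraction(al, elp, haigis_corneal_power(k),
                                      target_rx))
}

#' Optimize the IOL constant(s) of a classical formula on a training cohort
#'
#' Single-constant formulae (SRK/T, Hoffer Q, Holladay I) are personalized
#' by root-finding the constant at which the training-set mean prediction
#' error is zero.  Haigis is personalized by ordinary least squares of the
#' back-calculated ELP (under Haigis's own internal optics) on
#' `(1, ACD, AL)`; an `a0`-only mode keeps the manufacturer defaults
#' `a1 = 0.4, a2 = 0.1` and shifts only the intercept.
#'
#' @param cohort Training cohort data frame with implanted powers and
#'   achieved refractions.
#' @param formula_id One of `"SRKT"`, `"HOFFERQ"`, `"HOLLADAY1"`, `"HAIGIS"`.
#' @param haigis_mode `"regression"` (full 3-parameter OLS) or `"a0_only"`.
#' @param floor Minimum training-cohort size.
#' @param interval Search interval for the single constant; defaults to the
#'   published lens-constant range of the formula.
#' @return A [lens_constants()] object with provenance.
#' @export
optimize_constants <- function(cohort, formula_id,
                               haigis_mode = c("regression", "a0_only"),
                               floor = 30, interval = NULL) {
  formula_id <- match.arg(formula_id, classical_formulae)
  haigis_mode <- match.arg(haigis_mode)
  stopifnot(nrow(validate_cohort(cohort)) == 0)
  if (nrow(cohort) < floor) {
    stop("training cohort of ", nrow(cohort), " eyes is below the floor of ",
         floor, call. = FALSE)
  }
  if (length(unique(cohort$lens_model)) != 1) {
    stop("all training records must share one lens_model", call. = FALSE)
  }
  lens <- cohort$lens_model[1]

  if (formula_id == "HAIGIS") {
    k <- mean_corneal_power(cohort$k1_d, cohort$k2_d)
    d <- back_calculate_elp(cohort$al_mm, haigis_corneal_power(k),
                            cohort$iol_power_d, cohort$postop_se_d,
                            on_failure = "na")
    keep <- !is.na(d)
    if (sum(keep) < floor) {
      stop("too many back-calculation failures for Haigis optimization",
           call. = FALSE)
    }
    if (haigis_mode == "a0_only") {
      a1 <- 0.4; a2 <- 0.1
      a0 <- mean(d[keep] - a1 * cohort$acd_mm[keep] - a2 * cohort$al_mm[keep])
    } else {
      X <- cbind(1, cohort$acd_mm[keep], cohort$al_mm[keep])
      if (qr(X)$rank < 3) {
        stop("rank-deficient design for Haigis regression", call. = FALSE)
      }
      fit <- stats::lm.fit(X, d[keep])
      a0 <- fit$coefficients[1]
      a1 <- fit$coefficients[2]
      a2 <- fit$coefficients[3]
    }
    out <- lens_constants("HAIGIS", a0 = unname(a0), a1 = unname(a1),
                          a2 = unname(a2), lens_model = lens)
  } else {
    if (is.null(interval)) {
      interval <- switch(formula_id, SRKT = c(110, 125),
                         HOFFERQ = c(2, 8), HOLLADAY1 = c(-2, 4))
    }
    objective <- function(const) {
      cst <- switch(formula_id,
        SRKT = lens_constants("SRKT", a_constant = const, lens_model = lens),
        HOFFERQ = lens_constants("HOFFERQ", pacd = const, lens_model = lens),
        HOLLADAY1 = lens_constants("HOLLADAY1", sf = const,
                                   lens_model = lens))
      pred <- suppressWarnings(
        predict_refraction_classical(formula_id, cohort, cst,
                                     cohort$iol_power_d))
      mean(prediction_error(cohort$postop_se_d, pred))
    }
    flo <- objective(interval[1]); fhi <- objective(interval[2])
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
      stop("mean-PE root not bracketed in [", interval[1], ", ",
           interval[2], "] for ", formula_id, call. = FALSE)
    }
    root <- stats::uniroot(objective, interval, tol = 1e-10)$root
    out <- switch(formula_id,
      SRKT = lens_constants("SRKT", a_constant = root, lens_model = lens),
      HOFFERQ = lens_constants("HOFFERQ", pacd = root, lens_model = lens),
      HOLLADAY1 = lens_constants("HOLLADAY1", sf = root, lens_model = lens))
  }
  out$provenance <- list(n_train = nrow(cohort), hash = cohort_hash(cohort),
                         date = format(Sys.Date()))
  out
}

#' Serialize / deserialize lens constant sets
#'
#' Constant sets are stored as a JSON document keyed by
#' `lens_model:formula_id`, with provenance metadata.
#'
#' @param constants A list of [lens_constants()] objects (or a single one).
#' @param path Output / input path.
#' @return `path` (write) or a named list of `lens_constants` (read).
#' @export
write_lens_constants <- function(constants, path) {
  if (inherits(constants, "lens_constants")) constants <- list(constants)
  entries <- lapply(constants, function(x) {
    x[!vapply(x, is.null, logical(1))]
  })
  names(entries) <- vapply(constants, function(x)
    paste(x$lens_model, x$formula_id, sep = ":"), character(1))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_lens_constants
#' @export
read_lens_constants <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(entries, function(e) {
    out <- lens_constants(e$formula_id, pacd = e$pacd, sf = e$sf,
                          a_constant = e$a_constant, a0 = e$a0, a1 = e$a1,
                          a2 = e$a2, lens_model = e$lens_model)
    out$provenance <- e$provenance
    out
  })
}
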