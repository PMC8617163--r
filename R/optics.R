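# Thin-lens vergence optics for the pseudophakic eye.
#
# All axial distances are in millimetres; every vergence term therefore uses
# 1000 * refractive index so that powers come out in diopters (D = 1/m).
# The vertex distance is stored in metres because it multiplies diopters
# directly in the spectacle-plane transform S = Rx / (1 - b * Rx).

#' Optical constants for the vergence model
#'
#' Bundles the refractive indices and the spectacle vertex distance shared by
#' all vergence computations.  The default `n_aq = n_vit = 1.336` is the
#' standard convention for the aqueous and vitreous humour of a pseudophakic
#' eye; the default vertex distance is 12 mm.
#'
#' @param n_aq Refractive index of the aqueous humour (dimensionless).
#' @param n_vit Refractive index of the vitreous humour (dimensionless).
#' @param vertex_distance Spectacle vertex distance in metres.
#' @return An object of class `"optical_constants"`.
#' @export
#' @examples
#' optical_constants()
optical_constants <- function(n_aq = 1.336, n_vit = 1.336,
                              vertex_distance = 0.012) {
  check_range(n_aq, 1.2, 1.5, "n_aq")
  check_range(n_vit, 1.2, 1.5, "n_vit")
  check_range(vertex_distance, 0, 0.02, "vertex_distance")
  structure(list(n_aq = n_aq, n_vit = n_vit,
                 vertex_distance = vertex_distance),
            class = "optical_constants")
}

#' @export
print.optical_constants <- function(x, ...) {
  cat("Optical constants: n_aq =", x$n_aq, " n_vit =", x$n_vit,
      " vertex =", x$vertex_distance * 1000, "mm\n")
  invisible(x)
}

# validation helper: open-interval range check that names the failing field
check_range <- function(x, lo, hi, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("'", name, "' must be finite numeric", call. = FALSE)
  }
  if (any(x <= lo | x >= hi)) {
    stop("'", name, "' out of range (", lo, ", ", hi, "): ",
         paste(utils::head(signif(x[x <= lo | x >= hi], 5), 3), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean corneal power from the two keratometry readings
#'
#' @param k_flat Flat keratometry reading K1 (D).
#' @param k_steep Steep keratometry reading K2 (D).
#' @return Arithmetic mean keratometry K = (K1 + K2) / 2 in diopters.
#' @export
#' @examples
#' mean_corneal_power(43.06, 43.84)
mean_corneal_power <- function(k_flat, k_steep) {
  check_range(k_flat, 30, 60, "k_flat")
  check_range(k_steep, 30, 60, "k_steep")
  (k_flat + k_steep) / 2
}

# spectacle-plane refraction Rx -> corneal-plane refraction S
corneal_plane_refraction <- function(rx, vertex_distance) {
  denom <- 1 - vertex_distance * rx
  if (any(abs(denom) < 1e-9)) {
    stop("vertex singularity: 1 - b*Rx ~ 0", call. = FALSE)
  }
  rx / denom
}

# core two-vergence chain; pc_eff is the effective corneal power in D
vergence_power <- function(al, elp, pc_eff, n_aq, n_vit) {
  if (any(elp >= al)) {
    stop("singular geometry: 'elp' must be smaller than 'al'", call. = FALSE)
  }
  d1 <- al - elp
  d2 <- 1000 * n_aq / pc_eff - elp
  if (any(abs(d1) < 1e-9) || any(abs(d2) < 1e-9)) {
    stop("singular geometry: degenerate vergence denominator", call. = FALSE)
  }
  1000 * n_vit / d1 - 1000 * n_aq / d2
}

#' IOL power for emmetropia
#'
#' Thin-lens vergence solution for the intraocular lens power that brings an
#' aphakic eye of axial length `al` to emmetropia, given the effective lens
#' position and the corneal power.
#'
#' @param al Axial length (mm).
#' @param elp Effective lens position d (mm), measured from the corneal apex.
#' @param pc Corneal power (D).
#' @param constants An [optical_constants()] object.
#' @return Required IOL power in diopters.
#' @export
#' @examples
#' emmetropic_iol_power(24, 5, 43)
emmetropic_iol_power <- function(al, elp, pc, constants = optical_constants()) {
  check_range(al, 15, 40, "al")
  check_range(pc, 10, 70, "pc")
  check_range(elp, 0, 12, "elp")
  vergence_power(al, elp, pc, constants$n_aq, constants$n_vit)
}

#' IOL power for a target refraction
#'
#' As [emmetropic_iol_power()], but targeting a desired post-operative
#' spherical-equivalent refraction `rx` at the spectacle plane.  The
#' spectacle-plane target is first moved to the corneal plane,
#' S = Rx / (1 - b Rx), and added to the corneal power.
#'
#' @inheritParams emmetropic_iol_power
#' @param rx Desired post-operative refraction (D) at the spectacle plane.
#' @return Required IOL power in diopters.
#' @export
iol_power_for_refraction <- function(al, elp, pc, rx = 0,
                                     constants = optical_constants()) {
  check_range(al, 15, 40, "al")
  check_range(pc, 10, 70, "pc")
  check_range(elp, 0, 12, "elp")
  s <- corneal_plane_refraction(rx, constants$vertex_distance)
  vergence_power(al, elp, pc + s, constants$n_aq, constants$n_vit)
}

#' Predicted refraction for an implanted IOL power
#'
#' Closed-form inversion of the vergence equation for the spectacle-plane
#' refraction, given the implanted power `power` and an effective lens
#' position.  Exact round trip with [iol_power_for_refraction()].
#'
#' @inheritParams emmetropic_iol_power
#' @param power Implanted (or candidate) IOL power (D).
#' @return Predicted spherical-equivalent refraction (D) at the spectacle
#'   plane.
#' @export
predict_refraction <- function(al, elp, pc, power,
                               constants = optical_constants()) {
  check_range(al, 15, 40, "al")
  check_range(pc, 10, 70, "pc")
  check_range(elp, 0, 12, "elp")
  n_aq <- 1000 * constants$n_aq
  n_vit <- 1000 * constants$n_vit
  z <- n_vit / (al - elp) - power
  if (any(abs(z) < 1e-9)) {
    stop("singular geometry: IOL cancels the axial vergence (z ~ 0)",
         call. = FALSE)
  }
  q <- n_aq / z + elp
  if (any(q <= 0)) {
    stop("non-physical intermediate: negative corneal focal distance",
         call. = FALSE)
  }
  s <- n_aq / q - pc
  b <- constants$vertex_distance
  if (any(abs(1 + b * s) < 1e-9)) {
    stop("vertex singularity while mapping back to the spectacle plane",
         call. = FALSE)
  }
  s / (1 + b * s)
}

#' Back-calculate the effective lens position from an observed outcome
#'
#' Solves the vergence equation for the lens position d, given the implanted
#' power and the achieved post-operative refraction.  The equation is a
#' quadratic in d; the anatomically plausible root inside `window` is
#' returned.  If both roots fall inside the window the one closer to 5.0 mm
#' is returned and the element is flagged in the `"ambiguous"` attribute.
#'
#' @inheritParams emmetropic_iol_power
#' @param power Implanted IOL power (D); must be nonzero.
#' @param rx_achieved Achieved post-operative spherical-equivalent refraction
#'   (D) at the spectacle plane.
#' @param window Plausible pseudophakic ELP range (mm).
#' @param on_failure `"error"` to stop on eyes with no admissible root,
#'   `"na"` to return `NA` for those eyes (with the count in the
#'   `"n_failed"` attribute).
#' @return Numeric vector of back-calculated ELP values (mm) with attributes
#'   `"ambiguous"` (logical) and `"n_failed"` (integer).
#' @export
back_calculate_elp <- function(al, pc, power, rx_achieved,
                               constants = optical_constants(),
                               window = c(1.5, 8.0),
                               on_failure = c("error", "na")) {
  on_failure <- match.arg(on_failure)
  check_range(al, 15, 40, "al")
  check_range(pc, 10, 70, "pc")
  if (any(power == 0)) {
    stop("'power' must be nonzero (linear degenerate case rejected)",
         call. = FALSE)
  }
  n_aq <- 1000 * constants$n_aq
  n_vit <- 1000 * constants$n_vit
  s <- corneal_plane_refraction(rx_achieved, constants$vertex_distance)
  q <- n_aq / (pc + s)
  # P*d^2 + [n_vit' - n_aq' - P*(AL+q)]*d + [P*AL*q - n_vit'*q + n_aq'*AL] = 0
  a <- power
  b <- n_vit - n_aq - power * (al + q)
  cc <- power * al * q - n_vit * q + n_aq * al
  disc <- b^2 - 4 * a * cc
  m <- max(length(al), length(pc), length(power), length(rx_achieved))
  out <- rep(NA_real_, m)
  ambiguous <- rep(FALSE, m)
  ok <- disc >= 0
  sq <- sqrt(pmax(disc, 0))
  r1 <- (-b - sq) / (2 * a)
  r2 <- (-b + sq) / (2 * a)
  in1 <- ok & r1 > window[1] & r1 < window[2]
  in2 <- ok & r2 > window[1] & r2 < window[2]
  out[in1] <- r1[in1]
  out[in2 & !in1] <- r2[in2 & !in1]
  both <- in1 & in2
  if (any(both)) {
    pick2 <- both & (abs(r2 - 5.0) < abs(r1 - 5.0))
    out[pick2] <- r2[pick2]
    ambiguous[both] <- TRUE
  }
  failed <- is.na(out)
  if (any(failed) && on_failure == "error") {
    stop(sum(failed), " eye(s) with no admissible ELP root in (",
         window[1], ", ", window[2], ") mm", call. = FALSE)
  }
  structure(out, ambiguous = ambiguous, n_failed = sum(failed))
}

#' Prediction error of a refraction forecast
#'
#' The prediction error (PE) is the achieved post-operative
#' spherical-equivalent refraction minus the formula-predicted refraction;
#' positive values are hyperopic surprises.
#'
#' @param achieved_se Achieved post-operative SE refraction (D).
#' @param predicted_rx Predicted SE refraction (D).
#' @return achieved - predicted, in diopters.
#' @export
prediction_error <- function(achieved_se, predicted_rx) {
  achieved_se - predicted_rx
}
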