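# The MM formula: thin-lens vergence optics coupled to an ensemble
# regression of the effective lens position on the four pre-operative
# predictors (K1, K2, ACD, AL).  Training targets are the per-eye ELP values
# back-calculated from the implanted power and the achieved refraction, so
# the ensemble learns the lens-position behaviour of one lens model on one
# surgeon's retrospective data.

mm_features <- c("k1_d", "k2_d", "acd_mm", "al_mm")

#' Ensemble hyperparameters for the MM formula
#'
#' The default family is a bootstrap-aggregated ensemble of penalized
#' additive spline regressions (shrinkage smooths in each of the four
#' predictors, REML-selected smoothness).  Each member shrinks towards a
#' linear fit when the data carry no nonlinear signal, so the ensemble is
#' never less efficient than a Haigis-style linear predictor, and bends
#' where the data demand it.  Gradient-boosted trees (`"gbt"`: 300 trees of
#' depth 3, learning rate 0.05, row subsampling 0.8) and bagged random
#' forests (`"bagging"`) are available behind the same interface.
#'
#' @param family `"spline"` (bagged additive spline regressions, default),
#'   `"gbt"` (gradient-boosted trees) or `"bagging"` (bootstrap-aggregated
#'   trees).
#' @param n_models Number of bootstrap members of the spline ensemble.
#' @param n_trees Number of trees (tree families).
#' @param max_depth Maximum tree depth (gbt only).
#' @param learning_rate Shrinkage per boosting round (gbt only).
#' @param subsample Row subsampling fraction per round (gbt only).
#' @return A list of class `"mm_control"`.
#' @export
mm_control <- function(family = c("spline", "gbt", "bagging"),
                       n_models = 20, n_trees = 300, max_depth = 3,
                       learning_rate = 0.05, subsample = 0.8) {
  family <- match.arg(family)
  stopifnot(n_models >= 1, n_trees >= 1, max_depth >= 1,
            learning_rate > 0, learning_rate <= 1,
            subsample > 0, subsample <= 1)
  structure(list(family = family, n_models = n_models, n_trees = n_trees,
                 max_depth = max_depth, learning_rate = learning_rate,
                 subsample = subsample),
            class = "mm_control")
}

# one member of the spline ensemble: penalized additive regression with
# shrinkage smooths; falls back to ordinary least squares when the response
# is (near-)exactly linear in the predictors or the smoother fails
fit_spline_member <- function(data) {
  ols <- stats::lm(d ~ k1_d + k2_d + acd_mm + al_mm, data = data)
  if (stats::sd(stats::residuals(ols)) < 1e-6) {
    return(ols)
  }
  member <- tryCatch(
    suppressWarnings(mgcv::gam(
      d ~ s(al_mm, k = 6, bs = "ts") + s(acd_mm, k = 5, bs = "ts") +
        s(k1_d, k = 5, bs = "ts") + s(k2_d, k = 5, bs = "ts"),
      data = data, method = "REML", select = TRUE)),
    error = function(e) NULL)
  if (is.null(member)) ols else member
}

#' Build the ELP training table from post-operative records
#'
#' One row per eye: the four predictors plus the back-calculated ELP target.
#' Eyes whose back-calculation has no admissible root are dropped and
#' counted in the returned audit.
#'
#' @param cohort Cohort data frame with implanted powers and achieved
#'   refractions.
#' @param constants An [optical_constants()] object.
#' @param max_failure_rate Error if more than this fraction of eyes fails
#'   back-calculation.
#' @return A list with `features` (data frame), `targets` (numeric, mm) and
#'   `audit` (list with `n_input`, `n_dropped`).
#' @export
build_training_table <- function(cohort, constants = optical_constants(),
                                 max_failure_rate = 0.2) {
  stopifnot(nrow(validate_cohort(cohort)) == 0)
  pc <- mean_corneal_power(cohort$k1_d, cohort$k2_d)
  d <- back_calculate_elp(cohort$al_mm, pc, cohort$iol_power_d,
                          cohort$postop_se_d, constants = constants,
                          on_failure = "na")
  keep <- !is.na(d)
  n_dropped <- sum(!keep)
  if (n_dropped > max_failure_rate * nrow(cohort)) {
    stop("back-calculation failed for ", n_dropped, "/", nrow(cohort),
         " eyes (> ", 100 * max_failure_rate, "%): check data quality",
         call. = FALSE)
  }
  list(features = cohort[keep, mm_features],
       targets = as.numeric(d[keep]),
       audit = list(n_input = nrow(cohort), n_dropped = n_dropped))
}

#' Fit the MM effective-lens-position ensemble
#'
#' Fits one per-lens-model ensemble mapping `(K1, K2, ACD, AL)` to the
#' back-calculated ELP.  Training is deterministic given
#' `(control, seed, data)`; predictions outside the plausible pseudophakic
#' window are clamped.
#'
#' @param cohort Training cohort data frame (single lens model) with
#'   implanted powers and achieved refractions.
#' @param control An [mm_control()] object.
#' @param seed Integer seed for the ensemble's internal randomness.
#' @param constants An [optical_constants()] object used both for the ELP
#'   back-calculation and later refraction predictions.
#' @param floor Minimum number of usable training rows.
#' @param window Plausible ELP window (mm) used for target validation and
#'   prediction clamping.
#' @return An object of class `"mm_model"`.
#' @export
#' @examples
#' cohort <- generate_cohort("SN60WF", n = 120, seed = 42)
#' fit <- fit_mm(cohort, control = mm_control(n_trees = 50), seed = 1)
#' fit
fit_mm <- function(cohort, control = mm_control(), seed = 1L,
                   constants = optical_constants(), floor = 50,
                   window = c(1.5, 8.0)) {
  stopifnot(inherits(control, "mm_control"))
  tab <- build_training_table(cohort, constants)
  n <- length(tab$targets)
  if (n < floor) {
    stop("only ", n, " usable training rows (< ", floor, "); ",
         "consider a Haigis-style linear ELP model for small cohorts",
         call. = FALSE)
  }
  if (any(tab$targets <= window[1] | tab$targets >= window[2])) {
    stop("back-calculated ELP targets outside the plausible window",
         call. = FALSE)
  }
  x <- as.matrix(tab$features)
  y <- tab$targets
  if (control$family == "spline") {
    data <- tab$features
    data$d <- y
    set.seed(as.integer(seed))
    members <- lapply(seq_len(control$n_models), function(b) {
      fit_spline_member(data[sample.int(nrow(data), replace = TRUE), ])
    })
    state <- members
    fitted_raw <- rowMeans(vapply(members, function(m)
      as.numeric(predict(m, newdata = tab$features)), numeric(n)))
  } else if (control$family == "gbt") {
    booster <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    max_depth = control$max_depth,
                    eta = control$learning_rate,
                    subsample = control$subsample,
                    nthread = 1, seed = as.integer(seed)),
      data = xgboost::xgb.DMatrix(x, label = y),
      nrounds = control$n_trees, verbose = 0)
    state <- xgboost::xgb.save.raw(booster)
    fitted_raw <- predict(booster, x)
  } else {
    set.seed(as.integer(seed))
    rf <- randomForest::randomForest(x, y, ntree = control$n_trees)
    state <- rf
    fitted_raw <- as.numeric(predict(rf, x))
  }
  model <- structure(list(
    family = control$family,
    ensemble_state = state,
    hyperparams = control,
    train_seed = as.integer(seed),
    lens_model = if (!is.null(cohort$lens_model)) cohort$lens_model[1]
                 else NA_character_,
    constants = constants,
    window = window,
    training = list(n = n, target_mean = mean(y), target_sd = stats::sd(y),
                    dropped = tab$audit$n_dropped,
                    targets = y, fitted = pmin(pmax(fitted_raw, window[1]),
                                               window[2]),
                    features = tab$features),
    version = "iolpower-mm-1"), class = "mm_model")
  model
}

# rebuild the live booster from the serialized state
mm_booster <- function(model) {
  if (model$family == "gbt") xgboost::xgb.load.raw(model$ensemble_state)
  else model$ensemble_state
}

#' Predict from a fitted MM model
#'
#' @param object A fitted `"mm_model"`.
#' @param newdata Data frame with columns `k1_d`, `k2_d`, `acd_mm`, `al_mm`
#'   (plus `iol_power_d` when `type = "refraction"` and `power` is omitted).
#' @param type `"elp"` for the predicted lens position (mm), `"refraction"`
#'   for the predicted spectacle-plane SE refraction given an implanted
#'   power, `"power"` for the recommended IOL power at a target refraction.
#' @param power Implanted power (D) for `type = "refraction"`.
#' @param target_rx Target refraction (D) for `type = "power"`.
#' @param step Manufacturing step (D) the recommended power is rounded to;
#'   the pre-rounding value is kept in the `"raw"` attribute.
#' @param ... Unused.
#' @return Numeric vector; ELP predictions carry a `"clamped"` attribute
#'   marking eyes clamped to the plausible window.
#' @export
predict.mm_model <- function(object, newdata,
                             type = c("elp", "refraction", "power"),
                             power = NULL, target_rx = 0, step = 0.5, ...) {
  type <- match.arg(type)
  if (!all(mm_features %in% names(newdata))) {
    stop("newdata must contain columns: ",
         paste(mm_features, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(newdata[, mm_features])
  raw <- if (object$family == "spline") {
    member_preds <- vapply(object$ensemble_state, function(m)
      as.numeric(predict(m, newdata = newdata[, mm_features])),
      numeric(nrow(newdata)))
    if (is.null(dim(member_preds))) mean(member_preds)
    else rowMeans(member_preds)
  } else if (object$family == "gbt") {
    predict(mm_booster(object), x)
  } else {
    as.numeric(predict(object$ensemble_state, x))
  }
  elp <- pmin(pmax(raw, object$window[1]), object$window[2])
  clamped <- raw != elp
  if (type == "elp") {
    return(structure(as.numeric(elp), clamped = clamped))
  }
  pc <- mean_corneal_power(newdata$k1_d, newdata$k2_d)
  if (type == "refraction") {
    if (is.null(power)) power <- newdata$iol_power_d
    if (is.null(power)) {
      stop("'power' (or an 'iol_power_d' column) is required", call. = FALSE)
    }
    return(predict_refraction(newdata$al_mm, elp, pc, power,
                              object$constants))
  }
  p_raw <- iol_power_for_refraction(newdata$al_mm, elp, pc, target_rx,
                                    object$constants)
  p <- if (step > 0) round(p_raw / step) * step else p_raw
  structure(p, raw = p_raw)
}

#' @export
print.mm_model <- function(x, ...) {
  cat("MM effective-lens-position ensemble (", x$family, ")\n", sep = "")
  cat("  lens model:", x$lens_model, "\n")
  cat("  trained on", x$training$n, "eyes (", x$training$dropped,
      "dropped in back-calculation )\n")
  cat(sprintf("  ELP target: %.3f +/- %.3f mm\n",
              x$training$target_mean, x$training$target_sd))
  invisible(x)
}

#' @export
summary.mm_model <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(lens_model = object$lens_model,
              family = object$family,
              hyperparams = object$hyperparams,
              n = object$training$n,
              dropped = object$training$dropped,
              target_mean = object$training$target_mean,
              target_sd = object$training$target_sd,
              train_mae = mean(abs(res)),
              train_rmse = sqrt(mean(res^2)))
  class(out) <- "summary.mm_model"
  out
}

#' @export
print.summary.mm_model <- function(x, ...) {
  cat("MM ensemble summary (", x$family, ", lens ", x$lens_model, ")\n",
      sep = "")
  cat("  n =", x$n, "  dropped =", x$dropped, "\n")
  cat(sprintf("  ELP target %.3f +/- %.3f mm\n", x$target_mean, x$target_sd))
  cat(sprintf("  training ELP MAE %.4f mm, RMSE %.4f mm\n",
              x$train_mae, x$train_rmse))
  invisible(x)
}

#' @export
residuals.mm_model <- function(object, ...) {
  object$training$targets - object$training$fitted
}

#' @export
plot.mm_model <- function(x, ...) {
  feats <- x$training$features
  graphics::plot(feats$al_mm, x$training$targets,
                 xlab = "Axial length (mm)",
                 ylab = "Back-calculated ELP (mm)",
                 main = "MM ensemble: ELP vs axial length", ...)
  al_grid <- seq(min(feats$al_mm), max(feats$al_mm), length.out = 100)
  grid <- data.frame(k1_d = stats::median(feats$k1_d),
                     k2_d = stats::median(feats$k2_d),
                     acd_mm = stats::median(feats$acd_mm),
                     al_mm = al_grid)
  graphics::lines(al_grid, predict(x, grid, type = "elp"), col = 2, lwd = 2)
  invisible(x)
}

#' Save / load a fitted MM model
#'
#' Versioned persistence; loading refuses a payload written by an
#' incompatible version.  Predictions after a save/load round trip are
#' identical.
#'
#' @param model A fitted `"mm_model"`.
#' @param path File path.
#' @return `path` (save) or the restored `"mm_model"` (load).
#' @export
save_mm_model <- function(model, path) {
  stopifnot(inherits(model, "mm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_mm_model
#' @export
load_mm_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mm_model") ||
      !identical(model$version, "iolpower-mm-1")) {
    stop("incompatible or corrupt MM model payload", call. = FALSE)
  }
  model
}
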