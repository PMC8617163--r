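# The MM ensemble: training-table construction, determinism, persistence,
# clamping, closure of the optics pipeline, and the nonlinear-recovery
# property.

test_that("training table recovers the generator's true ELP when clean", {
  cohort <- clean_cohort(n = 120, seed = 3)
  tab <- build_training_table(cohort)
  expect_equal(tab$targets, as.numeric(attr(cohort, "elp_true")),
               tolerance = 1e-9)
  expect_identical(tab$audit$n_dropped, 0L)

  # a record with no admissible back-calculation is dropped and audited
  broken <- cohort
  broken$iol_power_d[1] <- 39
  broken$postop_se_d[1] <- 0
  tab2 <- build_training_table(broken)
  expect_identical(tab2$audit$n_dropped, 1L)
  expect_identical(nrow(tab2$features), nrow(cohort) - 1L)

  # a mostly-broken cohort is a data-quality error
  bad <- cohort
  bad$iol_power_d[1:40] <- 39
  bad$postop_se_d[1:40] <- 0
  expect_error(build_training_table(bad), "data quality")
})

test_that("Haigis-generated targets are linear in (ACD, AL)", {
  gt <- ground_truth_elp("linear", elp_noise_sd = 0)
  cohort <- clean_cohort(n = 100, seed = 11, gt = gt)
  tab <- build_training_table(cohort)
  fit <- stats::lm(tab$targets ~ tab$features$acd_mm + tab$features$al_mm)
  expect_gt(summary(fit)$r.squared, 1 - 1e-9)
})

test_that("ensemble fits are deterministic, persistent and clamped", {
  cohort <- shared_cohort
  f1 <- fit_mm(cohort, seed = 9)
  f2 <- fit_mm(cohort, seed = 9)
  expect_identical(predict(f1, cohort, type = "elp"),
                   predict(f2, cohort, type = "elp"))

  path <- tempfile(fileext = ".rds")
  save_mm_model(f1, path)
  f3 <- load_mm_model(path)
  expect_equal(predict(f3, cohort, type = "elp"),
               predict(f1, cohort, type = "elp"), tolerance = 1e-12)

  # predictions always land inside the plausible pseudophakic window,
  # even under far extrapolation
  extreme <- data.frame(k1_d = c(31, 59), k2_d = c(32, 59.5),
                        acd_mm = c(1.6, 5.9), al_mm = c(15.5, 39.5))
  e <- predict(f1, extreme, type = "elp")
  expect_true(all(e >= 1.5 & e <= 8))
  expect_true(is.logical(attr(e, "clamped")))

  expect_error(fit_mm(cohort[1:10, ]), "training rows")
})

test_that("constant ELP targets are recovered exactly", {
  gt <- ground_truth_elp("linear",
                         coefficients = c(intercept = 5, acd = 0, al = 0),
                         elp_noise_sd = 0)
  cohort <- clean_cohort(n = 80, seed = 21, gt = gt)
  fit <- fit_mm(cohort, seed = 1)
  expect_equal(as.numeric(predict(fit, cohort, type = "elp")),
               rep(5, nrow(cohort)), tolerance = 1e-6)
})

test_that("noiseless linear truth is learned to high precision", {
  gt <- ground_truth_elp("linear", elp_noise_sd = 0)
  cohort <- clean_cohort(n = 400, seed = 31, gt = gt)
  test_idx <- 321:400
  fit <- fit_mm(cohort[-test_idx, ], seed = 1)
  elp_hat <- predict(fit, cohort[test_idx, ], type = "elp")
  elp_true <- attr(cohort, "elp_true")[test_idx]
  expect_lt(mean(abs(elp_hat - elp_true)), 0.05)
})

test_that("the ensemble beats a linear ELP model on bent ground truth", {
  # nonlinear truth with modest observation noise: the ensemble should
  # capture the axial-length bend the linear model cannot
  wins <- 0
  for (s in 1:10) {
    cohort <- generate_cohort(
      "SN60WF", n = 400, seed = 400 + s,
      gt = ground_truth_elp("nonlinear", elp_noise_sd = 0.05),
      noise = noise_model(0.1, 0, 0))
    elp_true <- attr(cohort, "elp_true")
    test_idx <- 321:400
    train <- cohort[-test_idx, ]
    fit <- fit_mm(train, seed = s)
    mae_mm <- mean(abs(predict(fit, cohort[test_idx, ], type = "elp") -
                         elp_true[test_idx]))
    tab <- build_training_table(train)
    lin <- stats::lm(d ~ acd_mm + al_mm,
                     data = cbind(tab$features, d = tab$targets))
    mae_lin <- mean(abs(stats::predict(lin, cohort[test_idx, ]) -
                          elp_true[test_idx]))
    wins <- wins + (mae_mm < mae_lin)
  }
  expect_gte(wins, 8)
})

test_that("the optics pipeline closes end to end through the model", {
  # noise-free linear truth: the ensemble's exact-fit fallback makes the
  # whole back-calculate -> fit -> predict chain an identity
  cohort <- clean_cohort(n = 150, seed = 41)
  fit <- fit_mm(cohort, seed = 1)
  pred <- predict(fit, cohort, type = "refraction")
  pe <- prediction_error(cohort$postop_se_d, pred)
  expect_lt(max(abs(pe)), 1e-6)

  # recommended powers are rounded to the manufacturing step, with the
  # exact value retained
  p <- predict(fit, cohort[1:10, ], type = "power", target_rx = -0.5,
               step = 0.5)
  expect_true(all(abs(p / 0.5 - round(p / 0.5)) < 1e-12))
  expect_equal(length(attr(p, "raw")), 10L)
  expect_lt(max(abs(p - attr(p, "raw"))), 0.25 + 1e-12)

  # emmetropic target reproduces the emmetropic vergence solution at the
  # predicted ELP
  elp_hat <- predict(fit, cohort[1:10, ], type = "elp")
  k <- mean_corneal_power(cohort$k1_d[1:10], cohort$k2_d[1:10])
  expect_equal(as.numeric(attr(predict(fit, cohort[1:10, ], type = "power",
                                       target_rx = 0), "raw")),
               emmetropic_iol_power(cohort$al_mm[1:10], as.numeric(elp_hat),
                                    k),
               tolerance = 1e-9)
})

test_that("model persistence refuses incompatible payloads", {
  path <- tempfile(fileext = ".rds")
  saveRDS(list(version = "other"), path)
  expect_error(load_mm_model(path), "incompatible")
})
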