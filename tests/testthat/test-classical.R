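# Classical formulae: ELP chains against frozen oracle values, vergence
# self-consistency, and constant optimization.

test_that("ELP estimators reproduce the published calculation chains", {
  eye <- data.frame(al_mm = 23.8, k1_d = 43.45, k2_d = 43.45, acd_mm = 3.2)

  h <- lens_constants("HAIGIS", a0 = 0.4, a1 = 0.1, a2 = 0.1)
  expect_equal(estimate_elp("HAIGIS", eye, h), 0.4 + 0.1 * 3.2 + 0.1 * 23.8)
  h0 <- lens_constants("HAIGIS", a0 = 4.2, a1 = 0, a2 = 0)
  many <- shared_cohort[1:20, ]
  expect_equal(estimate_elp("HAIGIS", many, h0), rep(4.2, 20))

  # frozen from an independent evaluation of the SRK/T chain
  s <- lens_constants("SRKT", a_constant = 118.4)
  expect_equal(estimate_elp("SRKT", eye, s), 5.207775191567734,
               tolerance = 1e-9)

  # frozen from an independent evaluation of the Hoffer Q chain
  eye_q <- data.frame(al_mm = 23.5, k1_d = 43.5, k2_d = 43.5, acd_mm = 3.2)
  q <- lens_constants("HOFFERQ", pacd = 5.2)
  expect_equal(estimate_elp("HOFFERQ", eye_q, q), 5.1088737488803595,
               tolerance = 1e-9)

  # frozen from an independent evaluation of the Holladay I chain
  ho <- lens_constants("HOLLADAY1", sf = 1.2)
  expect_equal(estimate_elp("HOLLADAY1", eye, ho), 3.8445176313510476 + 1.2,
               tolerance = 1e-9)

  expect_warning(
    estimate_elp("HOFFERQ", data.frame(al_mm = 32, k1_d = 43, k2_d = 43,
                                       acd_mm = 3.2), q),
    "clamped")
  expect_error(
    estimate_elp("HAIGIS", data.frame(al_mm = 23.8, k1_d = 43, k2_d = 43,
                                      acd_mm = NA_real_), h),
    "ACD")
  expect_error(lens_constants("SRKT", pacd = 5), "not populated")
})

test_that("refraction predictions match oracles and are self-consistent", {
  # frozen from a root-finding oracle on Hoffer Q's vergence form
  eye_q <- data.frame(al_mm = 23.5, k1_d = 43.5, k2_d = 43.5, acd_mm = 3.2)
  q <- lens_constants("HOFFERQ", pacd = 5.2)
  expect_equal(predict_refraction_classical("HOFFERQ", eye_q, q, 20.5),
               0.041404247745830375, tolerance = 1e-8)

  # frozen from an independent evaluation of the SRK/T refraction formula
  eye <- data.frame(al_mm = 23.8, k1_d = 43.45, k2_d = 43.45, acd_mm = 3.2)
  s <- lens_constants("SRKT", a_constant = 118.4)
  expect_equal(predict_refraction_classical("SRKT", eye, s, 21),
               -0.9018315933778244, tolerance = 1e-8)

  # self-consistency: the power each formula picks for emmetropia predicts
  # zero refraction under that same formula
  eyes <- shared_cohort[1:25, ]
  sets <- list(
    SRKT = lens_constants("SRKT", a_constant = 118.9),
    HOFFERQ = lens_constants("HOFFERQ", pacd = 5.3),
    HOLLADAY1 = lens_constants("HOLLADAY1", sf = 1.45),
    HAIGIS = lens_constants("HAIGIS", a0 = 1.1, a1 = 0.35, a2 = 0.09))
  for (f in classical_formulae) {
    p0 <- recommend_power_classical(f, eyes, sets[[f]], target_rx = 0)
    expect_equal(predict_refraction_classical(f, eyes, sets[[f]], p0),
                 rep(0, nrow(eyes)), tolerance = 1e-9)
  }
})

test_that("classical ELPs ignore the pre-operative ACD except Haigis", {
  base <- data.frame(al_mm = 23.8, k1_d = 43.2, k2_d = 43.9, acd_mm = 2.6)
  deep <- transform(base, acd_mm = 4.2)
  sets <- list(
    SRKT = lens_constants("SRKT", a_constant = 118.9),
    HOFFERQ = lens_constants("HOFFERQ", pacd = 5.3),
    HOLLADAY1 = lens_constants("HOLLADAY1", sf = 1.45),
    HAIGIS = lens_constants("HAIGIS", a0 = 1.1, a1 = 0.35, a2 = 0.09))
  for (f in c("SRKT", "HOFFERQ", "HOLLADAY1")) {
    expect_identical(estimate_elp(f, base, sets[[f]]),
                     estimate_elp(f, deep, sets[[f]]))
  }
  expect_false(estimate_elp("HAIGIS", base, sets$HAIGIS) ==
                 estimate_elp("HAIGIS", deep, sets$HAIGIS))
})

test_that("single-constant optimization zeroes the training mean error", {
  cohort <- shared_cohort[1:150, ]
  for (f in c("SRKT", "HOFFERQ", "HOLLADAY1")) {
    cst <- suppressWarnings(optimize_constants(cohort, f))
    pred <- suppressWarnings(
      predict_refraction_classical(f, cohort, cst, cohort$iol_power_d))
    expect_lt(abs(mean(prediction_error(cohort$postop_se_d, pred))), 1e-6)
    expect_false(is.null(cst$provenance))
  }
})

test_that("Haigis regression recovers the generating constants", {
  gt <- ground_truth_elp("linear",
                         coefficients = c(intercept = 1.1, acd = 0.35,
                                          al = 0.09),
                         elp_noise_sd = 0)
  cohort <- clean_cohort(n = 120, seed = 5, gt = gt,
                         pc_transform = "haigis")
  cst <- optimize_constants(cohort, "HAIGIS")
  expect_equal(cst$a0, 1.1, tolerance = 1e-6)
  expect_equal(cst$a1, 0.35, tolerance = 1e-6)
  expect_equal(cst$a2, 0.09, tolerance = 1e-6)

  # by construction the generating formula predicts with zero error
  pred <- predict_refraction_classical("HAIGIS", cohort, cst,
                                       cohort$iol_power_d)
  expect_equal(prediction_error(cohort$postop_se_d, pred),
               rep(0, nrow(cohort)), tolerance = 1e-7)

  # a0-only fallback pins the published slopes
  cst0 <- optimize_constants(cohort, "HAIGIS", haigis_mode = "a0_only")
  expect_identical(cst0$a1, 0.4)
  expect_identical(cst0$a2, 0.1)

  # noisy recovery stays close to the generating ELP surface
  for (s in 1:5) {
    noisy_s <- generate_cohort("SN60WF", n = 250, seed = 100 + s, gt = gt,
                               noise = noise_model(0.25, 0, 0),
                               pc_transform = "haigis")
    cstn <- optimize_constants(noisy_s, "HAIGIS")
    expect_lt(abs(cstn$a1 - 0.35), 0.15)
    expect_lt(abs(cstn$a2 - 0.09), 0.15)
    # the intercept trades off against the slopes far from the data, so the
    # recovered surface (not a0 alone) is compared to the generating one
    d_hat <- estimate_elp("HAIGIS", noisy_s, cstn)
    d_true <- 1.1 + 0.35 * noisy_s$acd_mm + 0.09 * noisy_s$al_mm
    expect_lt(mean(abs(d_hat - d_true)), 0.1)
  }
})

test_that("optimization guards: floor, mixed lenses, serialization", {
  expect_error(optimize_constants(shared_cohort[1:10, ], "SRKT"), "floor")
  mixed <- shared_cohort[1:60, ]
  mixed$lens_model[1:30] <- "other"
  expect_error(optimize_constants(mixed, "SRKT"), "lens_model")

  cst <- suppressWarnings(optimize_constants(shared_cohort[1:80, ], "SRKT"))
  path <- tempfile(fileext = ".json")
  write_lens_constants(list(cst), path)
  back <- read_lens_constants(path)[[1]]
  expect_equal(back$a_constant, cst$a_constant, tolerance = 1e-12)
  expect_identical(back$formula_id, "SRKT")
})
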