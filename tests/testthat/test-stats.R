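# Non-parametric battery: exact signed-rank values, Friedman / Cochran
# degenerate handling, exact McNemar against the binomial oracle.

test_that("one-sample signed-rank test handles the canonical cases", {
  # perfectly symmetric sample: no evidence against a zero median
  expect_equal(median_zero_test(c(-2, -1, 1, 2))$p_value, 1)

  # all-positive n = 6: exact two-sided p = 2/2^6
  rep_ <- median_zero_test(c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0))
  expect_equal(rep_$p_value, 2 / 64, tolerance = 1e-12)
  expect_identical(rep_$method, "exact")
  expect_identical(rep_$verdict, "significant")

  expect_error(median_zero_test(numeric(0)), "at least 4")
  expect_error(median_zero_test(rep(0, 10)), "degenerate")
})

test_that("normality screen separates normal from skewed samples", {
  p_norm <- vapply(1:100, function(s) {
    set.seed(s)
    normality_screen(stats::rnorm(100))$p_value
  }, numeric(1))
  expect_gte(sum(p_norm > 0.05), 90)

  p_exp <- vapply(1:100, function(s) {
    set.seed(s)
    normality_screen(stats::rexp(100))$p_value
  }, numeric(1))
  expect_gte(sum(p_exp < 0.001), 95)

  expect_error(normality_screen(c(1, 2)), "n")
  expect_error(normality_screen(rep(3, 50)), "degenerate")
})

test_that("Friedman comparison of absolute errors behaves at the edges", {
  set.seed(5)
  base <- abs(stats::rnorm(40, 0, 0.5))
  same <- matrix(rep(base, 5), ncol = 5,
                 dimnames = list(NULL, c("MM", "A", "B", "C", "D")))
  res <- compare_absolute_errors(same)
  expect_equal(res$friedman$statistic, 0)
  expect_equal(res$friedman$p_value, 1)
  # pairwise against an identical column is a perfect tie
  expect_true(all(res$pairwise$p_value == 1))

  # constant per-formula shifts are detected
  shifted <- same + matrix(rep(c(0, 0.15, 0.3, 0.45, 0.6), each = 40),
                           ncol = 5)
  colnames(shifted) <- colnames(same)
  res2 <- compare_absolute_errors(shifted)
  expect_lt(res2$friedman$p_value, 0.05)
  expect_true(all(res2$pairwise$p_value < 0.05))

  # Holm adjustment never decreases a p-value
  res3 <- compare_absolute_errors(shifted, adjust = "holm")
  expect_true(all(res3$pairwise$p_value >= res2$pairwise$p_value - 1e-15))

  expect_error(compare_absolute_errors(unname(same)), "named")
})

test_that("Cochran's Q and McNemar match their oracles", {
  set.seed(9)
  v <- stats::rbinom(25, 1, 0.7)
  same <- matrix(rep(v, 5), ncol = 5,
                 dimnames = list(NULL, c("MM", "A", "B", "C", "D")))
  res <- compare_accuracy(same)
  expect_equal(res$cochran_q$statistic, 0)
  expect_equal(res$cochran_q$p_value, 1)
  expect_true(all(res$pairwise$p_value == 1))
  expect_true(all(res$pairwise$direction == "no_difference"))

  # exact binomial oracle: b = 5, c = 15 discordant pairs
  x <- c(rep(1, 5), rep(0, 15), rep(1, 30))
  y <- c(rep(0, 5), rep(1, 15), rep(1, 30))
  rep_ <- mcnemar_pair(x, y)
  expect_equal(rep_$p_value, 2 * stats::pbinom(5, 20, 0.5),
               tolerance = 1e-12)
  expect_identical(rep_$method, "exact binomial")

  # symmetric discordance is a perfect tie
  xb <- c(rep(1, 7), rep(0, 7), rep(1, 20))
  yb <- c(rep(0, 7), rep(1, 7), rep(1, 20))
  expect_equal(mcnemar_pair(xb, yb)$p_value, 1)

  expect_error(cochran_q(matrix(c(0, 2), 1, 2)), "binary")
  expect_error(mcnemar_pair(c(1, 0), c(1, 0, 1)), "pairing")
})

test_that("exact and asymptotic McNemar agree for large discordance", {
  for (nd in c(30, 50, 80)) {
    for (b in seq(2, floor(nd / 2) - 1, by = 3)) {
      p_exact <- min(1, 2 * stats::pbinom(b, nd, 0.5))
      stat <- (abs(nd - 2 * b) - 1)^2 / nd
      p_chi <- stats::pchisq(stat, 1, lower.tail = FALSE)
      expect_lt(abs(p_exact - p_chi), 0.02)
    }
  }
  # the implementation switches to chi-square at >= 25 discordant pairs
  x <- c(rep(1, 10), rep(0, 20))
  y <- c(rep(0, 10), rep(1, 20))
  expect_match(mcnemar_pair(x, y)$method, "chi-square")
})

test_that("direction labels follow the sign of the discordance", {
  # reference clearly better within band
  mm <- c(rep(1, 30), rep(1, 15), rep(0, 3))
  other <- c(rep(1, 30), rep(0, 15), rep(1, 3))
  mat <- cbind(MM = mm, OTHER = other)
  res <- compare_accuracy(mat)
  expect_identical(res$pairwise$direction, "MM_outperformed")
  res2 <- compare_accuracy(cbind(MM = other, OTHER = mm))
  expect_identical(res2$pairwise$direction, "MM_underperformed")
})

test_that("the full battery runs over accumulated records", {
  cohort <- shared_cohort[1:120, ]
  cv <- mc_crossval(cohort, k = 2, seed = 6,
                    formulae = c("HAIGIS", "HOFFERQ", "MM"))
  battery <- run_test_battery(cv)
  expect_true(all(battery$p_value >= 0 & battery$p_value <= 1))
  expect_true(all(c("friedman", "wilcoxon_paired", "cochran_q", "mcnemar")
                  %in% battery$test))
  expect_true("all" %in% battery$stratum)
  mc <- battery[battery$test == "mcnemar", ]
  expect_true(all(mc$direction %in%
                    c("no_difference", "MM_outperformed",
                      "MM_underperformed")))
})
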