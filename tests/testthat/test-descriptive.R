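test_that("prevalence reproduces the screening-sample interval", {
  pr <- prevalence(168, 1156)
  expect_equal(pr$p_hat, 168 / 1156)
  expect_equal(round(100 * pr$p_hat, 1), 14.5)
  expect_equal(round(100 * pr$ci_low, 1), 12.5)
  expect_equal(round(100 * pr$ci_high, 1), 16.6)
})

test_that("prevalence handles edge cases and matches closed-form Wald", {
  p0 <- prevalence(0, 100)
  expect_equal(p0$p_hat, 0)
  expect_equal(p0$ci_low, 0)

  p5 <- prevalence(50, 100)
  expect_equal(p5$ci_low, 0.5 - qnorm(0.975) * sqrt(0.25 / 100))
  expect_equal(round(p5$ci_low, 3), 0.402)
  expect_equal(round(p5$ci_high, 3), 0.598)

  expect_error(prevalence(1, 0), "positive")
  expect_error(prevalence(5, 3))
})

test_that("interval width shrinks as 1/sqrt(n) for fixed proportion", {
  w1 <- with(prevalence(50, 100), ci_high - ci_low)
  w4 <- with(prevalence(200, 400), ci_high - ci_low)
  expect_equal(w4, w1 / 2, tolerance = 1e-12)
})

test_that("sex chi-squared (no continuity correction) matches the printed test", {
  ## affected counts reconstructed from printed per-sex prevalences:
  ## round(0.131 * 426) = 56 males, round(0.153 * 730) = 112 females
  tab <- matrix(c(56, 426 - 56, 112, 730 - 112), 2, byrow = TRUE)
  ct <- sex_chi2(tab)
  expect_equal(round(ct$chi2, 2), 1.05)
  expect_equal(round(ct$p_value, 3), 0.307)
  expect_equal(ct$df, 1)
})

test_that("chi-squared equals the direct formula and is swap-invariant", {
  tab <- matrix(c(10, 90, 20, 80), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(sex_chi2(tab)$chi2, sum((tab - E)^2 / E))

  expect_equal(sex_chi2(tab)$chi2, sex_chi2(tab[2:1, ])$chi2)
  expect_equal(sex_chi2(tab)$chi2, sex_chi2(tab[, 2:1])$chi2)

  same <- matrix(c(30, 70, 60, 140), 2, byrow = TRUE)
  expect_equal(sex_chi2(same)$chi2, 0)
  expect_equal(sex_chi2(same)$p_value, 1)

  expect_error(sex_chi2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("grading proportions reproduce the published distribution", {
  clean <- data.frame(
    diagnosis = rep(c("affected", "unaffected"), c(168, 988)),
    grade = c(rep(c("mild", "moderate", "severe", "none"),
                  c(146, 4, 1, 17)), rep("none", 988)))
  g <- grading_summary(clean)
  expect_equal(unname(round(g$pct_among_affected, 1)),
               c(86.9, 2.4, 0.6, 10.1))
  expect_equal(unname(round(g$pct_among_graded, 1)), c(96.7, 2.6, 0.7))
  expect_equal(sum(g$pct_among_affected), 100)

  none <- grading_summary(data.frame(diagnosis = "unaffected",
                                     grade = "none"))
  expect_null(none$pct_among_affected)

  all_mild <- grading_summary(data.frame(diagnosis = "affected",
                                         grade = rep("mild", 5)))
  expect_equal(unname(all_mild$pct_among_affected["mild"]), 100)
})

test_that("screening coverage percentages match registry arithmetic", {
  expect_equal(coverage(1156, 5422)$pct_rounded, 21.3)
  expect_equal(coverage(857, 1756)$pct_rounded, 48.8)
  expect_equal(coverage(0, 100)$pct_rounded, 0)
  expect_error(coverage(10, 0), "positive")
})
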