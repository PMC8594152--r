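test_that("normal ordinate at the threshold is exact", {
  expect_equal(z_ordinate(0.5), dnorm(0))
  expect_equal(z_ordinate(0.145), 0.2279, tolerance = 1e-4)
  z_tiny <- z_ordinate(1e-9)
  expect_true(is.finite(z_tiny) && z_tiny > 0)
  expect_error(z_ordinate(0), "in \\(0, 1\\)")
  expect_error(z_ordinate(1.2), "in \\(0, 1\\)")
})

test_that("liability-scale conversion reproduces the published table", {
  c1 <- dempster_lerner(0.276, 0.050, p = 0.145, z_override = 0.227)
  expect_equal(round(c1$h2_liab, 3), 0.664)
  expect_equal(round(c1$se_liab, 3), 0.120)

  c3 <- dempster_lerner(0.280, 0.051, p = 0.145, z_override = 0.227)
  expect_equal(round(c3$h2_liab, 3), 0.674)

  c0 <- dempster_lerner(0, 0.02, p = 0.145)
  expect_equal(c0$h2_liab, 0)

  expect_error(dempster_lerner(0.3, 0.05, p = 0.145, z_override = -1),
               "positive")
  expect_error(dempster_lerner(-0.1, 0.05, p = 0.145), "non-negative")
  expect_warning(dempster_lerner(0.9, 0.05, p = 0.01), "exceeds 1")
})

test_that("conversion is symmetric in p and minimized at p = 0.5", {
  for (p in c(0.1, 0.25, 0.4)) {
    expect_equal(dempster_lerner(0.3, p = p)$h2_liab,
                 dempster_lerner(0.3, p = 1 - p)$h2_liab)
  }
  grid <- seq(0.02, 0.98, by = 0.02)
  ## extreme p legitimately warns when the converted value exceeds 1
  vals <- suppressWarnings(
    vapply(grid, function(p) dempster_lerner(0.3, p = p)$h2_liab,
           numeric(1)))
  expect_equal(grid[which.min(vals)], 0.5)
})

test_that("EBV comparisons behave as correlations should", {
  set.seed(3)
  e1 <- setNames(rnorm(50), paste0("a", 1:50))
  id <- compare_ebv(e1, e1)
  expect_equal(id$pearson, 1)
  expect_equal(id$spearman, 1)

  neg <- compare_ebv(e1, -e1)
  expect_equal(neg$pearson, -1)
  expect_equal(neg$spearman, -1)

  mono <- compare_ebv(e1, setNames(exp(2 * e1), names(e1)))
  expect_equal(mono$spearman, 1)
  expect_lt(mono$pearson, 1)

  ## common affine rescaling leaves Pearson unchanged
  sh <- compare_ebv(setNames(3 * e1 + 2, names(e1)),
                    setNames(3 * exp(2 * e1) + 2, names(e1)))
  expect_equal(sh$pearson, mono$pearson)

  expect_error(compare_ebv(e1[1:2], e1[1:2]), "at least 3")
  expect_warning(z <- compare_ebv(setNames(rep(1, 10), paste0("a", 1:10)),
                                  e1[1:10]), "zero variance")
  expect_true(is.na(z$pearson))
})

test_that("exact threshold-model conversion brackets and extends Dempster-Lerner", {
  ## exact pair-implied observed h2 exceeds the linearized value, and
  ## approaches it as the pair relationship weakens
  p <- 0.145; h2l <- 0.65
  dl <- h2l * z_ordinate(p)^2 / (p * (1 - p))
  ex50 <- observed_h2_exact(h2l, p, r = 0.5)
  ex12 <- observed_h2_exact(h2l, p, r = 0.125)
  expect_gt(ex50, dl)
  expect_gt(ex50, ex12)
  expect_lt(abs(ex12 - dl) / dl, 0.06)

  ## round trip
  h2b <- liability_h2_for_observed(ex50, p, r = 0.5)
  expect_equal(h2b, h2l, tolerance = 1e-6)

  expect_equal(observed_h2_exact(0, p), 0)
  expect_error(observed_h2_exact(1.2, p), "h2_liab")
  expect_error(liability_h2_for_observed(0, p), "positive")
})
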