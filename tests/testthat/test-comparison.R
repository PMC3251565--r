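test_that("percent and fold arithmetic", {
  expect_equal(round(percentHigher(8.32, 5.98)), 39)
  expect_equal(round(percentHigher(10.03, 6.50)), 54)
  expect_equal(percentHigher(3, 3), 0)
  expect_error(percentHigher(1, 0), "positive")

  expect_equal(round(percentLower(0.75, 0.53)), 29)
  expect_equal(round(percentLower(0.50, 0.43)), 14)
  expect_equal(round(percentLower(0.85, 0.61)), 28)
  expect_equal(percentLower(2, 2), 0)
  expect_error(percentLower(0, 1), "positive")

  expect_equal(foldRatio(0.11, 1.04), 9.5, tolerance = 0.05 / 9.5)
  expect_equal(foldRatio(0.19, 0.98), 5.16, tolerance = 0.01)
  expect_equal(foldRatio(4, 4), 1.0)
  expect_error(foldRatio(-1, 2), "positive")
})

test_that("percent-higher and percent-lower describe the same pair", {
  set.seed(12)
  for (i in 1:20) {
    a <- runif(1, 0.1, 10)
    b <- runif(1, 0.1, 10)
    ph <- percentHigher(a, b)
    expect_equal(percentLower(a, b), 100 * ph / (100 + ph), tolerance = 1e-10)
    expect_equal(foldRatio(a, b), foldRatio(b, a))
    expect_gte(foldRatio(a, b), 1)
  }
})

test_that("internal correlation times fall into flexibility bands", {
  expect_identical(classifyTauE(1.04e-9), "slow")
  expect_identical(classifyTauE(0.11e-9), "intermediate")
  expect_identical(classifyTauE(50e-12), "fast")    # boundary belongs below
  expect_identical(classifyTauE(500e-12), "intermediate")
  expect_identical(classifyTauE(0), "fast")
  expect_error(classifyTauE(-1e-12), "non-negative")
})

test_that("composite amide shift difference", {
  expect_equal(compositeShiftDifference(0, 0), 0)
  expect_equal(compositeShiftDifference(0.3, 0), 0.3)
  expect_equal(compositeShiftDifference(0.2, 1.0), 0.282842712474619,
               tolerance = 1e-12)
  flagged <- flagShiftPerturbations(
    data.frame(residue = 1:2, dH_ppm = c(0.5, 0.05), dN_ppm = c(1, 0.2)))
  expect_identical(flagged$flagged, c(TRUE, FALSE))
})

test_that("comparison table: identical inputs, published figures, missing data", {
  a <- data.frame(residue = c(49, 50, 51), S2 = c(0.75, 0.50, 0.85),
                  te_ns = c(0.11, 0.84, 0.19), R2 = c(8.32, 5.09, 10.03))
  same <- buildComparisonTable(a, a)
  expect_true(all(abs(same$pct_higher_a_over_b) < 1e-12))
  expect_true(all(abs(same$fold_ratio - 1) < 1e-12))

  b <- data.frame(residue = c(49, 50, 51), S2 = c(0.53, 0.43, 0.61),
                  te_ns = c(1.04, 0.93, 0.98), R2 = c(5.98, 4.90, 6.50))
  cmp <- buildComparisonTable(a, b, "WT", "P48A")
  r2 <- cmp[cmp$quantity == "R2", ]
  expect_equal(round(r2$pct_higher_a_over_b[r2$residue == 49]), 39)
  expect_equal(round(r2$pct_higher_a_over_b[r2$residue == 51]), 54)
  s2 <- cmp[cmp$quantity == "S2", ]
  expect_equal(round(s2$pct_lower_b_under_a), c(29, 14, 28))
  te <- cmp[cmp$quantity == "te_ns", ]
  expect_equal(te$fold_ratio[te$residue == 49], 9.5, tolerance = 0.05 / 9.5)
  expect_equal(te$fold_ratio[te$residue == 51], 5.16, tolerance = 0.1)

  # one side missing a residue (e.g. a proline): flagged, not an error
  b_gap <- b[b$residue != 50, ]
  cmp_gap <- buildComparisonTable(a, b_gap)
  expect_true(all(cmp_gap$missing[cmp_gap$residue == 50]))
  expect_false(any(cmp_gap$missing[cmp_gap$residue != 50]))

  expect_error(buildComparisonTable(a, data.frame(residue = 9, S2 = 1)),
               "no shared residues")
})

test_that("report rendering is a pure function of its inputs", {
  a <- data.frame(residue = 49:51, S2 = c(0.75, 0.50, 0.85))
  b <- data.frame(residue = 49:51, S2 = c(0.53, 0.43, 0.61))
  r1 <- renderComparisonReport(buildComparisonTable(a, b, "WT", "P48A"))
  r2 <- renderComparisonReport(buildComparisonTable(a, b, "WT", "P48A"))
  expect_identical(r1, r2)
  expect_match(r1[1], "WT.*P48A")
})
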