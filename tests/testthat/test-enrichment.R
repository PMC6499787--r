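test_that("contingency tables compute expected counts from marginals", {
  ct <- contingency_table(rbind(c(10, 20), c(30, 40)))
  expect_equal(ct$n, 100)
  expect_equal(ct$row_marginal, c(30, 70), ignore_attr = TRUE)
  expect_equal(ct$col_marginal, c(40, 60), ignore_attr = TRUE)
  expect_equal(ct$E[1, 1], 12)
  expect_error(contingency_table(rbind(c(-1, 2), c(3, 4))), "non-negative")
  expect_error(contingency_table(matrix(0, 2, 2)), "zero")
})

test_that("adjusted residuals reproduce the hand-evaluated formula", {
  ct <- contingency_table(rbind(c(10, 20), c(30, 40)))
  r <- adjusted_residuals(ct)
  expect_equal(r[1, 1], -2 / sqrt(12 * 0.7 * 0.6), tolerance = 1e-12)
  expect_equal(r[1, 1], -0.8909, tolerance = 1e-4)
  # 2x2 identity: all four |residuals| equal, signs alternate
  expect_equal(abs(r[1, 1]), abs(r[1, 2]))
  expect_equal(abs(r[1, 1]), abs(r[2, 1]))
  expect_equal(abs(r[1, 1]), abs(r[2, 2]))
  expect_equal(sign(r), rbind(c(-1, 1), c(1, -1)), ignore_attr = TRUE)
  # O = E exactly: all residuals zero
  expect_equal(adjusted_residuals(contingency_table(matrix(10, 2, 2))),
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(adjusted_residuals(contingency_table(rbind(c(0, 0), c(1, 2)))),
               "zero marginal")
})

test_that("chi-squared statistic matches hand summation", {
  ct <- contingency_table(rbind(c(10, 20), c(30, 40)))
  ht <- chi2_test(ct)
  expect_equal(ht$statistic, 4 / 12 + 4 / 18 + 4 / 28 + 4 / 42,
               tolerance = 1e-12)
  expect_equal(ht$statistic, 0.7937, tolerance = 1e-4)
  expect_equal(ht$df, 1)
  flat <- chi2_test(contingency_table(matrix(10, 2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
  expect_error(chi2_test(contingency_table(matrix(c(1, 2), 1, 2))),
               "2x2")
})

test_that("squared adjusted residual equals chi-squared for any 2x2 table", {
  set.seed(37)
  for (rep in 1:200) {
    O <- matrix(sample(1:200, 4, replace = TRUE), 2, 2)
    ct <- contingency_table(O)
    r <- adjusted_residuals(ct)
    ht <- suppressWarnings(chi2_test(ct))
    expect_equal(r[1, 1]^2, ht$statistic, tolerance = 1e-9)
    # cross-check against the standard implementation of the residuals
    std <- suppressWarnings(stats::chisq.test(O, correct = FALSE))$stdres
    expect_equal(r, std, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("residual matrix properties hold on random r x c tables", {
  set.seed(38)
  for (rep in 1:25) {
    O <- matrix(sample(1:60, 12, replace = TRUE), 3, 4)
    ct <- contingency_table(O)
    # row deviations sum to zero
    expect_equal(rowSums(ct$O - ct$E), rep(0, 3), ignore_attr = TRUE)
    # residuals of the transpose are the transposed residuals
    expect_equal(adjusted_residuals(contingency_table(t(O))),
                 t(adjusted_residuals(ct)), ignore_attr = TRUE)
  }
})

test_that("family contingency counts genes inside and outside PULs", {
  sim <- simulate_dataset(sim_config(n_genomes = 30, seed = 43,
                                     p_outside_cazyme_run = 3))
  sorted <- sort_dataset(sim)
  annotated <- annotate_in_pul(sim, sorted)
  expect_true(all(annotated$category %in% DEGRADATIVE_CATEGORIES))
  f <- names(sort(table(annotated$feature), decreasing = TRUE))[1]
  tab <- family_contingency(annotated, f)
  expect_equal(sum(tab$O), nrow(annotated))
  expect_equal(tab$O[1, 1] + tab$O[1, 2], sum(annotated$feature == f))
  expect_error(family_contingency(annotated, "GH99999"), "absent")
  scan <- family_enrichment(annotated)
  expect_true(all(scan$q.value >= scan$p.value - 1e-12))
  expect_true(all(abs(scan$residual^2 - scan$chi2) < 1e-9))
})

test_that("genus enrichment of tandem loci is detected directionally", {
  cfg <- sim_config(n_genomes = 120, seed = 47, trsuscd_fraction = 0.05,
                    genus_enrichment = list(genus = "Bacteroides",
                                            multiplier = 8))
  sim <- simulate_dataset(cfg)
  sorted <- sort_dataset(sim)
  gt <- suppressWarnings(genus_trsuscd_test(sorted, sim$meta,
                                            focal_genus = "Bacteroides"))
  res <- gt$residuals["Bacteroides", "trsusCD"]
  expect_gt(res, 2)  # clearly over-represented
  expect_lt(gt$chi2$p.value, 0.01)
  # single genus: test undefined
  meta1 <- sim$meta; meta1$genus <- "Bacteroides"
  expect_error(genus_trsuscd_test(sorted, meta1), "two genera")
})

test_that("null tandem rates give calibrated chi-squared p-values", {
  set.seed(53)
  p_values <- replicate(400, {
    genus <- sample(c("A", "B"), 300, replace = TRUE)
    tandem <- stats::rbinom(300, 1, 0.25)
    O <- table(genus, tandem)
    suppressWarnings(chi2_test(contingency_table(unclass(O)))$p.value)
  })
  # type-I error close to nominal at alpha = 0.05
  expect_gt(mean(p_values < 0.05), 0.01)
  expect_lt(mean(p_values < 0.05), 0.10)
})

test_that("Wilcoxon median confidence intervals behave correctly", {
  ci <- median_ci_wilcoxon(c(2, 2, 2, 2))
  expect_equal(unlist(ci[c("median", "lo", "hi")]), c(2, 2, 2),
               ignore_attr = TRUE)
  ci2 <- median_ci_wilcoxon(1:7)
  expect_equal(ci2$median, 4)
  expect_lte(ci2$lo, 4); expect_gte(ci2$hi, 4)
  expect_error(median_ci_wilcoxon(5), "at least two")
})
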