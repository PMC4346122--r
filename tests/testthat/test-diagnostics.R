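test_that("contingency construction cross-tabulates aligned calls", {
  fx <- reference_modality_calls()
  pred <- setNames(fx$calls$criteria == "TPV", fx$calls$patient_id)
  ct <- build_contingency(pred, fx$reference)
  expect_identical(c(ct$tp, ct$fp, ct$fn, ct$tn), c(9L, 4L, 2L, 10L))

  expect_error(build_contingency(logical(0), logical(0)), "named")
  expect_error(
    build_contingency(setNames(logical(0), character(0)),
                      setNames(logical(0), character(0))), "empty")
  expect_error(
    build_contingency(c(a = TRUE), c(b = TRUE)), "mismatch.*\\ba\\b")

  # a perfect classifier has no off-diagonal mass
  ref <- setNames(c(TRUE, TRUE, FALSE), c("x", "y", "z"))
  ct2 <- build_contingency(ref, ref)
  expect_identical(c(ct2$fp, ct2$fn), c(0L, 0L))
})

test_that("performance reproduces the published accuracy and percent values", {
  cases <- list(
    list(ct = contingency_2x2(9, 4, 2, 10), sens = 82, spec = 71, acc = 0.76),
    list(ct = contingency_2x2(10, 6, 1, 6), sens = 91, spec = 50, acc = 0.70),
    list(ct = contingency_2x2(8, 7, 3, 6), sens = 73, spec = 46, acc = 0.58)
  )
  for (cs in cases) {
    perf <- performance(cs$ct)
    g <- function(s) perf$estimate[perf$statistic == s]
    expect_equal(round_half_up(100 * g("sensitivity")), cs$sens)
    expect_equal(round_half_up(100 * g("specificity")), cs$spec)
    expect_equal(round_half_up(g("accuracy"), 2), cs$acc)
    expect_true(all(perf$lower <= perf$estimate & perf$estimate <= perf$upper))
    expect_true(all(perf$lower >= 0 & perf$upper <= 1))
  }
})

test_that("Clopper-Pearson intervals agree with binom.test", {
  for (n in c(5, 11, 14, 25)) {
    for (x in unique(c(0, 1, floor(n / 2), n))) {
      perf <- performance(contingency_2x2(tp = x, fp = 0, fn = n - x, tn = 1))
      row <- perf[perf$statistic == "sensitivity", ]
      bt <- binom.test(x, n)$conf.int
      expect_equal(c(row$lower, row$upper), as.numeric(bt), tolerance = 1e-10)
    }
  }
})

test_that("scaling all cells preserves estimates and narrows intervals", {
  ct <- contingency_2x2(9, 4, 2, 10)
  ct5 <- contingency_2x2(45, 20, 10, 50)
  p1 <- performance(ct)
  p5 <- performance(ct5)
  expect_equal(p1$estimate, p5$estimate)
  widths1 <- p1$upper - p1$lower
  widths5 <- p5$upper - p5$lower
  expect_true(all(widths5 < widths1))
})

test_that("zero denominators yield undefined statistics, not zero", {
  perf <- performance(contingency_2x2(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(perf$estimate[perf$statistic == "sensitivity"]))
  expect_true(is.na(perf$estimate[perf$statistic == "ppv"]))
  expect_equal(perf$estimate[perf$statistic == "specificity"], 1)
})

test_that("odds ratio matches the carrier-status cross product", {
  or <- odds_ratio(apoe_reference_table())
  expect_equal(or$or_estimate, 13.5)
  expect_false(or$correction_applied)
  expect_true(or$ci95[["lower"]] <= 13.5 && 13.5 <= or$ci95[["upper"]])

  expect_equal(odds_ratio(contingency_2x2(1, 1, 1, 1))$or_estimate, 1)

  corrected <- odds_ratio(contingency_2x2(5, 0, 2, 7))
  expect_true(corrected$correction_applied)
  expect_true(is.finite(corrected$or_estimate) && corrected$or_estimate > 0)
})

test_that("odds ratio is symmetric under transposition and label swap", {
  ct <- contingency_2x2(7, 3, 2, 9)
  transposed <- contingency_2x2(tp = ct$tp, fp = ct$fn, fn = ct$fp,
                                tn = ct$tn)
  swapped <- contingency_2x2(tp = ct$tn, fp = ct$fn, fn = ct$fp, tn = ct$tp)
  expect_equal(odds_ratio(ct)$or_estimate, odds_ratio(transposed)$or_estimate)
  expect_equal(odds_ratio(ct)$or_estimate, odds_ratio(swapped)$or_estimate)
})

test_that("Fisher's exact test matches the enumeration oracle", {
  # the published carrier table, one-sided
  expect_equal(round(fisher_exact(apoe_reference_table(), "greater"), 3),
               0.029)
  expect_equal(fisher_exact(contingency_2x2(1, 1, 1, 1), "two"), 1)

  set.seed(5)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    ct <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(fisher_exact(ct, "two"),
                 fisher_enum_two_sided(cells[1], cells[2], cells[3],
                                       cells[4]),
                 tolerance = 1e-9)
    one <- fisher_exact(ct, "greater")
    expect_equal(one, fisher_enum_one_sided_greater(cells[1], cells[2],
                                                    cells[3], cells[4]),
                 tolerance = 1e-9)
    expect_true(one >= 0 && one <= 1)
  }
})

test_that("chi-square is the uncorrected Pearson statistic", {
  cs <- chi_square(contingency_2x2(5, 5, 5, 5))
  expect_equal(cs$statistic, 0)
  expect_equal(cs$p_value, 1)
  expect_equal(chi_square(contingency_2x2(10, 0, 0, 10))$statistic, 20)
  # undefined on a zero margin
  expect_true(is.na(chi_square(contingency_2x2(3, 4, 0, 0))$statistic))
  # same association direction as Fisher on a moderate table
  ct <- contingency_2x2(9, 3, 2, 8)
  expect_lt(chi_square(ct)$p_value, 0.05)
  expect_lt(fisher_exact(ct, "two"), 0.05)
})

test_that("Cohen's kappa follows its definition and is symmetric", {
  expect_equal(cohens_kappa(c("FV", "TPV", "FV"), c("FV", "TPV", "FV"))$kappa,
               1)
  # hand-computed 10-read confusion: po = 0.8, pe = 0.5, kappa = 0.6
  a <- c(rep("FV", 5), rep("TPV", 5))
  b <- c(rep("FV", 4), "TPV", "FV", rep("TPV", 4))
  k <- cohens_kappa(a, b)
  expect_equal(k$observed_agreement, 0.8)
  expect_equal(k$expected_agreement, 0.5)
  expect_equal(k$kappa, 0.6)
  expect_equal(cohens_kappa(b, a)$kappa, k$kappa)

  # independent long random ratings drift to zero
  set.seed(8)
  x <- sample(c("FV", "TPV"), 4000, replace = TRUE)
  y <- sample(c("FV", "TPV"), 4000, replace = TRUE)
  expect_lt(abs(cohens_kappa(x, y)$kappa), 0.05)

  # perfect balanced disagreement sits at the lower bound
  expect_equal(cohens_kappa(c("FV", "TPV"), c("TPV", "FV"))$kappa, -1)
})

test_that("kappa agrees with the e1071 cross-check", {
  skip_if_not_installed("e1071")
  set.seed(21)
  a <- sample(c("FV", "TPV"), 60, replace = TRUE)
  b <- ifelse(runif(60) < 0.7, a, sample(c("FV", "TPV"), 60, replace = TRUE))
  expect_equal(cohens_kappa(a, b)$kappa,
               e1071::classAgreement(table(a, b))$kappa, tolerance = 1e-10)
})

test_that("concordance counting matches the histopathology table", {
  cases <- pathology_cases()
  pib <- setNames(cases$pib_positive, cases$patient_id)
  path_ad <- setNames(cases$ad_containing, cases$patient_id)
  cc <- concordance_count(pib, path_ad)
  expect_equal(as.integer(cc), 8L)
  expect_identical(attr(cc, "n"), 8L)

  # clinical criteria column vs amyloid status: 6 of 8 concordant
  crit <- setNames(cases$criteria == "TPV", cases$patient_id)
  expect_equal(as.integer(concordance_count(crit, pib)), 6L)

  disjoint <- concordance_count(setNames(c(TRUE, TRUE), c("a", "b")),
                                setNames(c(FALSE, FALSE), c("a", "b")))
  expect_equal(as.integer(disjoint), 0L)
})
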