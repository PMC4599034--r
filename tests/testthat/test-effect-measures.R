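test_that("odds ratios match hand-evaluated and reference values", {
  # symmetric table: OR exactly 1, CI symmetric on the log scale
  e <- odds_ratio_ci(10, 20, 10, 20)
  expect_equal(e$point, 1)
  expect_equal(log(e$ci_low), -log(e$ci_high))
  expect_equal(e$direction, "higher_is_worse_for_test")

  # (5, 20, 10, 20): OR = (5 * 10) / (15 * 10) = 1/3; frozen CI bounds
  # hand-evaluated and cross-checked against metafor::escalc("OR")
  e2 <- odds_ratio_ci(5, 20, 10, 20)
  expect_equal(e2$point, 1 / 3, tolerance = 1e-12)
  expect_equal(e2$ci_low, 0.0873770527, tolerance = 1e-8)
  expect_equal(e2$ci_high, 1.2716280494, tolerance = 1e-8)
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  e <- odds_ratio_ci(0, 20, 5, 20)
  expect_true("continuity_corrected" %in% e$flags)
  expect_true(is.finite(e$point) && e$point < 1)
  # hand value on the corrected table: (0.5 * 15.5) / (20.5 * 5.5)
  expect_equal(e$point, (0.5 * 15.5) / (20.5 * 5.5), tolerance = 1e-12)
  # no correction without a zero cell
  expect_length(odds_ratio_ci(5, 20, 10, 20)$flags, 0L)
  # uninformative table is flagged degenerate
  expect_true("degenerate" %in% odds_ratio_ci(0, 20, 0, 20)$flags)
  expect_error(odds_ratio_ci(0, 20, 5, 20, zero_cell_correction = FALSE),
               "zero cell")
  expect_error(odds_ratio_ci(0, 0, 5, 20), "at least 1")
})

test_that("standardised mean differences match frozen values", {
  # equal means: SMD exactly 0, CI symmetric about 0
  e0 <- smd_ci(10, 2, 30, 10, 3, 30)
  expect_equal(e0$point, 0)
  expect_equal(e0$ci_low, -e0$ci_high)

  # (12, 2, 30, 10, 2, 30): cohen d = 1; hedges J = 1 - 3/231
  ec <- smd_ci(12, 2, 30, 10, 2, 30, flavor = "cohen")
  expect_equal(ec$point, 1, tolerance = 1e-12)
  eh <- smd_ci(12, 2, 30, 10, 2, 30, flavor = "hedges")
  expect_equal(eh$point, 1 * (1 - 3 / 231), tolerance = 1e-12)
  expect_equal(eh$point, 0.9870, tolerance = 1e-4)
  # hand-evaluated CI: d +/- z * sqrt(60/900 + d^2/120)
  d <- 1 - 3 / 231
  half <- qnorm(0.975) * sqrt(60 / 900 + d^2 / 120)
  expect_equal(eh$ci_low, d - half, tolerance = 1e-12)
  expect_equal(eh$ci_high, d + half, tolerance = 1e-12)

  expect_error(smd_ci(5, 0, 30, 5, 0, 30), "pooled standard deviation")
  expect_error(smd_ci(5, 1, 1, 5, 1, 30), "n >= 2")
})

test_that("SMD is invariant under rescaling of the raw measurements", {
  for (k in c(0.01, 3.7, 1000)) {
    a <- smd_ci(12, 2, 25, 9, 3, 40)
    b <- smd_ci(12 * k, 2 * k, 25, 9 * k, 3 * k, 40)
    expect_equal(a$point, b$point, tolerance = 1e-12)
    expect_equal(a$ci_low, b$ci_low, tolerance = 1e-12)
    expect_equal(a$ci_high, b$ci_high, tolerance = 1e-12)
  }
})

test_that("widening the confidence level strictly widens both intervals", {
  for (lvl in c(0.80, 0.90, 0.95)) {
    wider <- lvl + 0.04
    or1 <- odds_ratio_ci(7, 40, 12, 45, ci_level = lvl)
    or2 <- odds_ratio_ci(7, 40, 12, 45, ci_level = wider)
    expect_lt(or2$ci_low, or1$ci_low)
    expect_gt(or2$ci_high, or1$ci_high)
    s1 <- smd_ci(11, 2, 30, 10, 2, 30, ci_level = lvl)
    s2 <- smd_ci(11, 2, 30, 10, 2, 30, ci_level = wider)
    expect_lt(s2$ci_low, s1$ci_low)
    expect_gt(s2$ci_high, s1$ci_high)
  }
})

test_that("OR and SMD agree with metafor::escalc on 1000 random inputs", {
  skip_if_not_installed("metafor")
  z <- qnorm(0.975)
  tabs <- random_tables(1000, seed = 11)
  ref <- metafor::escalc(measure = "OR", ai = tabs$tf, n1i = tabs$tt,
                         ci = tabs$cf, n2i = tabs$ct)
  for (i in seq_len(nrow(tabs))) {
    e <- odds_ratio_ci(tabs$tf[i], tabs$tt[i], tabs$cf[i], tabs$ct[i])
    expect_equal(log(e$point), as.numeric(ref$yi[i]), tolerance = 1e-10)
    expect_equal(e$ci_low, exp(ref$yi[i] - z * sqrt(ref$vi[i])),
                 tolerance = 1e-10)
    expect_equal(e$ci_high, exp(ref$yi[i] + z * sqrt(ref$vi[i])),
                 tolerance = 1e-10)
  }
  # Cohen flavor against metafor's uncorrected standardised difference;
  # the small-sample factor itself is the stated closed form (metafor
  # applies the exact gamma-function correction instead, which agrees
  # with the approximation only to ~1e-5).
  sums <- random_summaries(1000, seed = 12)
  refs <- metafor::escalc(measure = "SMD", m1i = sums$m1, sd1i = sums$s1,
                          n1i = sums$n1, m2i = sums$m2, sd2i = sums$s2,
                          n2i = sums$n2, correct = FALSE)
  for (i in seq_len(nrow(sums))) {
    e <- smd_ci(sums$m1[i], sums$s1[i], sums$n1[i],
                sums$m2[i], sums$s2[i], sums$n2[i], flavor = "cohen")
    expect_equal(e$point, as.numeric(refs$yi[i]), tolerance = 1e-10)
    expect_equal(e$ci_low, refs$yi[i] - z * sqrt(refs$vi[i]),
                 tolerance = 1e-10)
    h <- smd_ci(sums$m1[i], sums$s1[i], sums$n1[i],
                sums$m2[i], sums$s2[i], sums$n2[i], flavor = "hedges")
    m <- sums$n1[i] + sums$n2[i]
    expect_equal(h$point, e$point * (1 - 3 / (4 * m - 9)),
                 tolerance = 1e-12)
  }
})

test_that("effect dispatch honours the raw-summaries precedence rule", {
  both <- trial_dataset("b", "rct", 24, outcome_kind = "binary",
                        test_failures = 5, test_total = 20,
                        control_failures = 10, control_total = 20,
                        effect_measure = "OR", effect_point = 9,
                        effect_ci_low = 8, effect_ci_high = 10)
  e <- effect_for_dataset(both)
  expect_equal(e$point, 1 / 3, tolerance = 1e-12)  # raw wins

  one_arm <- one_arm_trial("u", "hvgic")
  expect_error(effect_for_dataset(one_arm), "no computable effect")
})
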