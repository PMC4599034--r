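test_that("the Pocock power factor matches its closed form", {
  # (z_0.975 + z_0.80)^2 = 7.8489, tabulated as 7.9 at one decimal
  expect_equal(pocock_f(0.05, 0.20), 7.84888, tolerance = 1e-5)
  expect_equal(ceiling(pocock_f(0.05, 0.20) * 10) / 10, 7.9)
  # z at beta = 0.5 vanishes analytically
  expect_equal(pocock_f(0.05, 0.50), qnorm(0.975)^2, tolerance = 1e-12)
  expect_equal(pocock_f(0.05, 0.50), 3.8414588, tolerance = 1e-6)
  expect_error(pocock_f(0, 0.2), "strictly between")
  expect_error(pocock_f(0.05, 1), "strictly between")
})

test_that("screen_config resolves the power factor as asked", {
  expect_equal(screen_config()$f, 7.9)
  expect_equal(screen_config(f_value = "computed")$f,
               pocock_f(0.05, 0.20))
  expect_equal(screen_config(f_value = 8.1)$f, 8.1)
  expect_error(screen_config(alpha = 0), "strictly between")
  expect_error(screen_config(delta_pct = 0), "delta_pct")
})

test_that("required sample size matches the two-proportion formula", {
  # P2 = 10: ((20*80 + 10*90)/100) * 7.9 = 25 * 7.9
  expect_equal(required_sample_size(10), 197.5, tolerance = 1e-12)
  # P2 = 20: ((30*70 + 20*80)/100) * 7.9 = 37 * 7.9
  expect_equal(required_sample_size(20), 292.3, tolerance = 1e-12)
  expect_error(required_sample_size(95), "outside")
})

test_that("N_P is symmetric under evaluating from the other arm", {
  up <- screen_config(delta_pct = 10)
  down <- screen_config(delta_pct = -10)
  for (p2 in c(5, 10, 25, 45, 70)) {
    expect_equal(required_sample_size(p2, up),
                 required_sample_size(p2 + 10, down), tolerance = 1e-12)
  }
})

test_that("N_P peaks when the two rates straddle 50%", {
  expect_gt(required_sample_size(45), required_sample_size(10))
  expect_gt(required_sample_size(45), required_sample_size(80))
})

test_that("screening exempts laboratory data and uses a strict threshold", {
  lab <- trial_dataset("lab", "laboratory", 0, outcome_kind = "continuous",
                       test_mean = 1, test_sd = 1, test_n = 5,
                       control_mean = 0, control_sd = 1, control_n = 5)
  expect_equal(screen_dataset(lab)$decision, "exempt_laboratory")

  # control 5/50 gives P2 = 10%, threshold 2 * 197.5 = 395
  small <- binary_trial("rct_small", tf = 5, tt = 50, cf = 5, ct = 50)
  s <- screen_dataset(small)
  expect_equal(s$p2_pct, 10)
  expect_equal(s$threshold, 395)
  expect_equal(s$n_t, 100)
  expect_equal(s$decision, "excluded")

  # N_T exactly at the threshold is included ("lower than" is strict)
  at <- binary_trial("rct_at", tf = 20, tt = 195, cf = 20, ct = 200)
  expect_equal(screen_dataset(at)$n_t, 395)
  expect_equal(screen_dataset(at)$decision, "included")
  below <- binary_trial("rct_below", tf = 20, tt = 194, cf = 20, ct = 200)
  expect_equal(screen_dataset(below)$decision, "excluded")
})

test_that("one-arm HVGIC screening requires an explicit reference rate", {
  hv <- one_arm_trial("hv", "hvgic", f = 30, n = 300)
  expect_error(screen_dataset(hv), "reference_control_rate_pct")
  s <- screen_dataset(hv, screen_config(reference_control_rate_pct = 10))
  expect_equal(s$p2_pct, 10)
  expect_equal(s$n_t, 300)           # the single arm's total
  expect_equal(s$decision, "excluded")

  # amalgam-only rows supply their own control rate
  am <- one_arm_trial("am", "amalgam", f = 40, n = 400)
  s2 <- screen_dataset(am)
  expect_equal(s2$p2_pct, 10)
  expect_equal(s2$decision, "included")
})

test_that("with the control rate fixed, more data never flips to excluded", {
  cfg <- screen_config(reference_control_rate_pct = 10)
  sizes <- seq(50, 1000, by = 50)
  dec <- vapply(sizes, function(n) {
    screen_dataset(one_arm_trial("x", "hvgic", f = round(n / 10), n = n),
                   cfg)$decision
  }, character(1))
  first_inc <- match("included", dec)
  expect_false(is.na(first_inc))
  expect_true(all(dec[first_inc:length(dec)] == "included"))
})

test_that("screening yields exactly one decision per dataset", {
  tab <- bind_tables(
    binary_trial("a", tf = 40, tt = 400, cf = 40, ct = 400),
    binary_trial("b", tf = 5, tt = 50, cf = 5, ct = 50),
    trial_dataset("lab", "laboratory", 0, outcome_kind = "continuous",
                  test_mean = 1, test_sd = 1, test_n = 5,
                  control_mean = 0, control_sd = 1, control_n = 5)
  )
  scr <- screen_datasets(tab)
  expect_equal(nrow(scr), nrow(tab))
  counts <- table(factor(scr$decision,
                         c("included", "excluded", "exempt_laboratory")))
  expect_equal(sum(counts), nrow(tab))   # read = included + excluded + exempt
  expect_equal(as.vector(counts), c(1L, 1L, 1L))
})

test_that("per-trial selection follows follow-up and meta-analysis rules", {
  mk <- function(fu, meta = FALSE, tt = 400, ct = 400) {
    binary_trial("trial", fu = fu, meta = meta,
                 tf = 40, tt = tt, cf = 40, ct = ct)
  }
  # longest follow-up wins among included datasets
  tab <- bind_tables(mk(12), mk(24), mk(36))
  sel <- select_per_trial(tab, screen_datasets(tab))
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$follow_up_months, 36)
  expect_equal(attr(sel, "dropped"), 2L)

  # power-excluded longest follow-up: the next sufficient one is chosen
  tab2 <- bind_tables(mk(24),
                      binary_trial("trial", fu = 36, tf = 5, tt = 50,
                                   cf = 5, ct = 50))
  sel2 <- select_per_trial(tab2, screen_datasets(tab2))
  expect_equal(sel2$follow_up_months, 24)

  # meta-analysis rows outrank longer single datasets
  tab3 <- bind_tables(mk(24, meta = TRUE), mk(72))
  sel3 <- select_per_trial(tab3, screen_datasets(tab3))
  expect_true(sel3$is_meta_analysis)
  expect_equal(sel3$follow_up_months, 24)

  # a trial whose datasets are all excluded contributes nothing
  tab4 <- bind_tables(binary_trial("gone", tf = 5, tt = 50, cf = 5,
                                   ct = 50))
  sel4 <- select_per_trial(tab4, screen_datasets(tab4))
  expect_equal(nrow(sel4), 0L)
})
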