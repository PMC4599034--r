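# Fixtures are built in code; no files are shipped.

binary_trial <- function(id = "t1", design = "rct", fu = 24, meta = FALSE,
                         tf = 10, tt = 100, cf = 10, ct = 100) {
  trial_dataset(trial_id = id, design = design, follow_up_months = fu,
                is_meta_analysis = meta, outcome_kind = "binary",
                test_failures = tf, test_total = tt,
                control_failures = cf, control_total = ct)
}

one_arm_trial <- function(id, material = c("hvgic", "amalgam"),
                          fu = 24, f = 10, n = 100,
                          design = "uncontrolled_clinical") {
  material <- match.arg(material)
  if (material == "hvgic") {
    trial_dataset(trial_id = id, design = design, follow_up_months = fu,
                  outcome_kind = "binary", test_failures = f,
                  test_total = n)
  } else {
    trial_dataset(trial_id = id, design = design, follow_up_months = fu,
                  outcome_kind = "binary", control_failures = f,
                  control_total = n)
  }
}

bind_tables <- function(...) {
  as_evidence_table(do.call(rbind, lapply(list(...), as.data.frame)))
}

# Random non-degenerate 2x2 tables for property suites.
random_tables <- function(n, seed) {
  set.seed(seed)
  data.frame(
    tt = tt <- sample(20:500, n, replace = TRUE),
    ct = ct <- sample(20:500, n, replace = TRUE),
    tf = vapply(tt, function(k) sample(seq_len(k - 1), 1), integer(1)),
    cf = vapply(ct, function(k) sample(seq_len(k - 1), 1), integer(1))
  )
}

# Random continuous-arm summaries with positive spread.
random_summaries <- function(n, seed) {
  set.seed(seed)
  data.frame(
    m1 = rnorm(n, 10, 4), s1 = runif(n, 0.5, 5),
    n1 = sample(5:200, n, replace = TRUE),
    m2 = rnorm(n, 10, 4), s2 = runif(n, 0.5, 5),
    n2 = sample(5:200, n, replace = TRUE)
  )
}

support_of <- function(events) {
  vapply(events, `[[`, character(1), "support")
}
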