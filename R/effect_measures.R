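#' Odds ratio with Wald confidence interval from a 2x2 table
#'
#' Point estimate is the cross-product ratio on the table
#' \{a = test failures, b = test non-failures, c = control failures,
#' d = control non-failures\}, i.e. OR = (a d)/(b c). The interval is the
#' log-scale Wald CI, `exp(log(OR) +/- z * SE)` with
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. When any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to all four cells before
#' computation and the estimate is flagged `"continuity_corrected"`.
#'
#' @param test_failures,test_total Failure count and total in the test
#'   (HVGIC) arm.
#' @param control_failures,control_total Same for the control (amalgam) arm.
#' @param ci_level Confidence level (default 0.95); the z-quantile is
#'   computed from the normal distribution, not hard-coded.
#' @param zero_cell_correction Apply the +0.5 correction when a cell is
#'   zero (default `TRUE`). With the correction off a zero cell makes the
#'   estimate undefined and is an error.
#' @return An [effect_estimate()] with `measure = "OR"` and
#'   `direction = "higher_is_worse_for_test"` (a failure outcome: odds
#'   above 1 mean the test material fails more often).
#' @examples
#' odds_ratio_ci(5, 20, 10, 20)
#' @export
odds_ratio_ci <- function(test_failures, test_total,
                          control_failures, control_total,
                          ci_level = 0.95, zero_cell_correction = TRUE) {
  stopifnot(is.numeric(test_failures), is.numeric(test_total),
            is.numeric(control_failures), is.numeric(control_total))
  if (test_total < 1 || control_total < 1) {
    stop("odds ratio undefined: each arm needs a total of at least 1",
         call. = FALSE)
  }
  if (test_failures < 0 || test_failures > test_total ||
      control_failures < 0 || control_failures > control_total) {
    stop("failures must lie between 0 and the arm total", call. = FALSE)
  }
  a <- test_failures
  b <- test_total - test_failures
  c_ <- control_failures
  d <- control_total - control_failures
  flags <- character()
  if (any(c(a, b, c_, d) == 0)) {
    if (!zero_cell_correction) {
      stop("zero cell in 2x2 table and continuity correction disabled",
           call. = FALSE)
    }
    a <- a + 0.5
    b <- b + 0.5
    c_ <- c_ + 0.5
    d <- d + 0.5
    flags <- "continuity_corrected"
    # both arms all failures, or neither arm any: the table carries no
    # contrast even after correction
    if ((test_failures == test_total &&
         control_failures == control_total) ||
        (test_failures == 0 && control_failures == 0)) {
      flags <- c(flags, "degenerate")
    }
  }
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  effect_estimate("OR", or,
                  exp(log(or) - z * se), exp(log(or) + z * se),
                  ci_level = ci_level,
                  direction = "higher_is_worse_for_test",
                  flags = flags)
}

#' Standardised mean difference with confidence interval
#'
#' Computes `d = (test_mean - control_mean) / s_pooled` with the pooled
#' standard deviation
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' The `"hedges"` flavor (default) applies the small-sample correction
#' `J = 1 - 3 / (4 (n1 + n2) - 9)`; `"cohen"` leaves the pooled-SD value
#' uncorrected. The CI is
#' `point +/- z * sqrt((n1 + n2)/(n1 n2) + point^2 / (2 (n1 + n2)))`.
#'
#' @param test_mean,test_sd,test_n Summaries of the test (HVGIC) arm.
#' @param control_mean,control_sd,control_n Summaries of the control
#'   (amalgam) arm. Both `n` must be at least 2 and the pooled SD positive.
#' @param ci_level Confidence level (default 0.95).
#' @param flavor `"hedges"` (default) or `"cohen"`.
#' @param direction Direction convention for the outcome being
#'   standardised; laboratory outcomes differ in whether a higher value
#'   means a stronger or a weaker material, so the caller must say.
#' @return An [effect_estimate()] with `measure = "SMD"`.
#' @examples
#' smd_ci(12, 2, 30, 10, 2, 30, flavor = "cohen")
#' @export
smd_ci <- function(test_mean, test_sd, test_n,
                   control_mean, control_sd, control_n,
                   ci_level = 0.95, flavor = c("hedges", "cohen"),
                   direction = "higher_is_worse_for_test") {
  flavor <- match.arg(flavor)
  stopifnot(is.numeric(test_mean), is.numeric(test_sd),
            is.numeric(control_mean), is.numeric(control_sd))
  if (test_n < 2 || control_n < 2) {
    stop("each arm needs n >= 2 for a standardised mean difference",
         call. = FALSE)
  }
  if (test_sd < 0 || control_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  n1 <- test_n
  n2 <- control_n
  s_pooled <- sqrt(((n1 - 1) * test_sd^2 + (n2 - 1) * control_sd^2) /
                     (n1 + n2 - 2))
  if (s_pooled <= 0) {
    stop("degenerate estimate: pooled standard deviation is zero",
         call. = FALSE)
  }
  d <- (test_mean - control_mean) / s_pooled
  if (flavor == "hedges") {
    d <- d * (1 - 3 / (4 * (n1 + n2) - 9))
  }
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  effect_estimate("SMD", d, d - z * se, d + z * se,
                  ci_level = ci_level, direction = direction)
}

#' Effect estimate for one evidence-table row
#'
#' Dispatch rule: when raw arm summaries are present they are used (binary
#' outcome -> [odds_ratio_ci()], continuous -> [smd_ci()]); otherwise the
#' reported effect columns are returned verbatim. Raw summaries take
#' precedence when both are present. One-arm datasets carry no computable
#' contrast and are an error here — they enter the analysis only through
#' the naive-indirect pairing flow.
#'
#' @param ds A one-row `evidence_table`.
#' @param ci_level,smd_flavor,zero_cell_correction Passed to the
#'   computation routines.
#' @return An [effect_estimate()].
#' @export
effect_for_dataset <- function(ds, ci_level = 0.95,
                               smd_flavor = c("hedges", "cohen"),
                               zero_cell_correction = TRUE) {
  stopifnot(is.data.frame(ds), nrow(ds) == 1L)
  smd_flavor <- match.arg(smd_flavor)
  row <- ds[1, , drop = FALSE]
  if (row$outcome_kind == "binary" && row_has_two_binary_arms(row)) {
    return(odds_ratio_ci(row$test_failures, row$test_total,
                         row$control_failures, row$control_total,
                         ci_level = ci_level,
                         zero_cell_correction = zero_cell_correction))
  }
  if (row$outcome_kind == "continuous" && row_has_raw(row)) {
    return(smd_ci(row$test_mean, row$test_sd, row$test_n,
                  row$control_mean, row$control_sd, row$control_n,
                  ci_level = ci_level, flavor = smd_flavor,
                  direction = row$effect_direction))
  }
  if (row_has_reported(row)) {
    return(effect_estimate(row$effect_measure, row$effect_point,
                           row$effect_ci_low, row$effect_ci_high,
                           ci_level = ci_level,
                           direction = row$effect_direction,
                           flags = "reported"))
  }
  stop(sprintf(
    "dataset '%s': no computable effect (one-arm data or missing columns)",
    row$trial_id), call. = FALSE)
}

#' Naive-indirect odds ratios from one-arm datasets
#'
#' Pairs one-arm HVGIC datasets (test arm only) with one-arm amalgam
#' datasets (control arm only) in the order given, forming a 2x2 table per
#' pair as if the two uncontrolled trials had been a head-to-head
#' comparison. This is the naive-indirect contrast the prior evidence base
#' rests on — deliberately without randomisation, which is exactly the
#' methodological weakness the synthesis accounts for.
#'
#' @param hvgic_rows,amalgam_rows `evidence_table` subsets holding one-arm
#'   rows of each material. Extra rows beyond the shorter list are left
#'   unpaired and ignored.
#' @inheritParams effect_for_dataset
#' @return A list of [effect_estimate()]s, one per pair (possibly empty).
#' @export
naive_indirect_effects <- function(hvgic_rows, amalgam_rows,
                                   ci_level = 0.95,
                                   zero_cell_correction = TRUE) {
  stopifnot(is.data.frame(hvgic_rows), is.data.frame(amalgam_rows))
  n_pairs <- min(nrow(hvgic_rows), nrow(amalgam_rows))
  if (n_pairs == 0L) return(list())
  lapply(seq_len(n_pairs), function(i) {
    h <- hvgic_rows[i, ]
    a <- amalgam_rows[i, ]
    if (is.na(h$test_total) || is.na(a$control_total)) {
      stop("naive-indirect pairing needs a test arm in the HVGIC row and ",
           "a control arm in the amalgam row", call. = FALSE)
    }
    odds_ratio_ci(h$test_failures, h$test_total,
                  a$control_failures, a$control_total,
                  ci_level = ci_level,
                  zero_cell_correction = zero_cell_correction)
  })
}
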