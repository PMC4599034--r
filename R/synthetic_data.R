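#' Synthetic evidence-table configuration
#'
#' The generator emulates the structure of the extracted evidence base:
#' two-arm RCT datasets reported at several follow-ups (the new-evidence
#' stratum), one-arm uncontrolled clinical datasets of each material (the
#' naive-indirect prior stratum), and laboratory comparisons with
#' continuous material-property outcomes. Clinical failure counts are
#' binomial at the configured true rates; laboratory summaries are normal
#' at a configured true standardised effect.
#'
#' Defaults describe the evidence base the analysis targets: equal 10%
#' failure rates for both materials (the no-difference ground truth the
#' clinical literature supports), modest arm sizes of 100-400 restorations
#' so that a realistic share of datasets fails the power screen, 12/24/36
#' month follow-ups, around ten trials per stratum, and heterogeneous
#' laboratory effects centred on zero with unit spread.
#'
#' @param seed Integer seed; one seed drives the whole table, with
#'   deterministic per-stratum substreams derived from it.
#' @param n_rct Number of RCTs (each contributes one dataset per
#'   follow-up).
#' @param n_uncontrolled_hvgic,n_uncontrolled_amalgam Numbers of one-arm
#'   trials of each material.
#' @param n_lab Number of laboratory comparisons.
#' @param hvgic_failure_rate_pct,amalgam_failure_rate_pct True cumulative
#'   failure rates in percent at the longest follow-up.
#' @param arm_size_range Integer `c(min, max)` for arm sizes.
#' @param followups_months Follow-up grid for RCT datasets (cumulative
#'   failures are non-decreasing along it); one-arm trials report a single
#'   follow-up drawn from the values `>= 12`.
#' @param lab_effect_mean,lab_effect_sd Mean and between-trial SD of the
#'   true standardised laboratory effect (on the
#'   `higher_is_worse_for_test` coding unless `lab_direction` says
#'   otherwise).
#' @param lab_group_size Per-arm size of laboratory comparisons.
#' @param lab_direction Direction convention written into laboratory rows.
#' @param meta_analysis_fraction Fraction of RCTs whose longest follow-up
#'   row is flagged as a meta-analysis result.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_rct = 10L,
                       n_uncontrolled_hvgic = 10L,
                       n_uncontrolled_amalgam = 10L,
                       n_lab = 10L,
                       hvgic_failure_rate_pct = 10,
                       amalgam_failure_rate_pct = 10,
                       arm_size_range = c(100L, 400L),
                       followups_months = c(12, 24, 36),
                       lab_effect_mean = 0,
                       lab_effect_sd = 1,
                       lab_group_size = 20L,
                       lab_direction = "higher_is_worse_for_test",
                       meta_analysis_fraction = 0.2) {
  stopifnot(length(seed) == 1L, is.numeric(seed))
  if (hvgic_failure_rate_pct < 0 || hvgic_failure_rate_pct > 100 ||
      amalgam_failure_rate_pct < 0 || amalgam_failure_rate_pct > 100) {
    stop("failure rates must lie in [0, 100] percent", call. = FALSE)
  }
  if (length(arm_size_range) != 2L ||
      arm_size_range[1] > arm_size_range[2] || arm_size_range[1] < 1) {
    stop("arm_size_range must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  if (lab_group_size < 2) {
    stop("lab_group_size must be at least 2", call. = FALSE)
  }
  if (meta_analysis_fraction < 0 || meta_analysis_fraction > 1) {
    stop("meta_analysis_fraction must lie in [0, 1]", call. = FALSE)
  }
  lab_direction <- match.arg(lab_direction, DIRECTIONS)
  structure(
    list(seed = as.integer(seed), n_rct = n_rct,
         n_uncontrolled_hvgic = n_uncontrolled_hvgic,
         n_uncontrolled_amalgam = n_uncontrolled_amalgam,
         n_lab = n_lab,
         hvgic_failure_rate_pct = hvgic_failure_rate_pct,
         amalgam_failure_rate_pct = amalgam_failure_rate_pct,
         arm_size_range = as.integer(arm_size_range),
         followups_months = sort(followups_months),
         lab_effect_mean = lab_effect_mean,
         lab_effect_sd = lab_effect_sd,
         lab_group_size = as.integer(lab_group_size),
         lab_direction = lab_direction,
         meta_analysis_fraction = meta_analysis_fraction),
    class = "sim_config"
  )
}

# Deterministic substream per generator so the strata can be produced
# independently or together with identical results. Offsets are arbitrary
# fixed constants; the combined seed stays far below 2^31.
substream_seed <- function(cfg, offset) (cfg$seed %% 1000000L) * 1000L + offset

draw_arm_size <- function(cfg) {
  r <- cfg$arm_size_range
  if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
}

# Cumulative failures across the follow-up grid: each interval adds new
# binomial failures among the survivors, with a constant interval hazard
# chosen so the expected cumulative rate at the last follow-up equals the
# configured true rate.
cumulative_failures <- function(n, rate_pct, k) {
  p_final <- rate_pct / 100
  p_int <- 1 - (1 - p_final)^(1 / k)
  fails <- integer(k)
  at_risk <- n
  cum <- 0L
  for (j in seq_len(k)) {
    new <- stats::rbinom(1L, at_risk, p_int)
    cum <- cum + new
    at_risk <- at_risk - new
    fails[j] <- cum
  }
  fails
}

#' Generate synthetic RCT datasets
#'
#' Two-arm datasets with binomial failure counts at the configured true
#' rates, one dataset per follow-up per trial, cumulative failures
#' non-decreasing in follow-up, and a configured fraction of trials
#' carrying a meta-analysis flag on their longest follow-up row.
#'
#' @param cfg A [sim_config()].
#' @return An `evidence_table` of RCT rows.
#' @export
generate_rct_datasets <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg, 101L))
  fu <- cfg$followups_months
  k <- length(fu)
  rows <- lapply(seq_len(cfg$n_rct), function(i) {
    n1 <- draw_arm_size(cfg)
    n2 <- draw_arm_size(cfg)
    f1 <- cumulative_failures(n1, cfg$hvgic_failure_rate_pct, k)
    f2 <- cumulative_failures(n2, cfg$amalgam_failure_rate_pct, k)
    meta <- stats::runif(1) < cfg$meta_analysis_fraction
    data.frame(
      trial_id = sprintf("rct_%03d", i), design = "rct",
      follow_up_months = fu,
      is_meta_analysis = c(rep(FALSE, k - 1), meta),
      outcome_kind = "binary",
      test_failures = f1, test_total = n1,
      control_failures = f2, control_total = n2,
      stringsAsFactors = FALSE
    )
  })
  as_evidence_table(do.call(rbind, rows))
}

#' Generate synthetic one-arm uncontrolled clinical datasets
#'
#' One-arm trials of each material with binomial failure counts, one
#' dataset per trial, follow-up drawn from the configured grid restricted
#' to at least 12 months. HVGIC-only rows carry only a test arm;
#' amalgam-only rows carry only a control arm.
#'
#' @param cfg A [sim_config()].
#' @return An `evidence_table` of uncontrolled clinical rows.
#' @export
generate_uncontrolled_datasets <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg, 202L))
  fu_pool <- cfg$followups_months[cfg$followups_months >= 12]
  if (length(fu_pool) == 0L) fu_pool <- 12
  one_arm <- function(i, material) {
    n <- draw_arm_size(cfg)
    rate <- if (material == "hvgic") cfg$hvgic_failure_rate_pct
            else cfg$amalgam_failure_rate_pct
    f <- stats::rbinom(1L, n, rate / 100)
    fup <- fu_pool[sample.int(length(fu_pool), 1L)]
    if (material == "hvgic") {
      data.frame(trial_id = sprintf("uncon_hvgic_%03d", i),
                 design = "uncontrolled_clinical",
                 follow_up_months = fup, is_meta_analysis = FALSE,
                 outcome_kind = "binary",
                 test_failures = f, test_total = n,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(trial_id = sprintf("uncon_amalgam_%03d", i),
                 design = "uncontrolled_clinical",
                 follow_up_months = fup, is_meta_analysis = FALSE,
                 outcome_kind = "binary",
                 control_failures = f, control_total = n,
                 stringsAsFactors = FALSE)
    }
  }
  rows <- c(lapply(seq_len(cfg$n_uncontrolled_hvgic), one_arm,
                   material = "hvgic"),
            lapply(seq_len(cfg$n_uncontrolled_amalgam), one_arm,
                   material = "amalgam"))
  tabs <- lapply(rows, function(df) {
    for (col in setdiff(EVIDENCE_COLUMNS, names(df))) {
      df[[col]] <- if (col %in% NUMERIC_COLUMNS) NA_real_
                   else NA_character_
    }
    df[EVIDENCE_COLUMNS]
  })
  if (length(tabs) == 0L) return(empty_evidence_table())
  as_evidence_table(do.call(rbind, tabs))
}

#' Generate synthetic laboratory comparison datasets
#'
#' Continuous-outcome comparisons of a material property between the two
#' materials: per trial a true standardised effect is drawn from
#' `Normal(lab_effect_mean, lab_effect_sd)` and each arm's summaries come
#' from unit-variance normal samples of size `lab_group_size`. The
#' direction convention is written into every row explicitly.
#'
#' @param cfg A [sim_config()].
#' @return An `evidence_table` of laboratory rows (follow-up 0).
#' @export
generate_lab_datasets <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg, 303L))
  n <- cfg$lab_group_size
  rows <- lapply(seq_len(cfg$n_lab), function(i) {
    delta <- stats::rnorm(1, cfg$lab_effect_mean, cfg$lab_effect_sd)
    y_test <- stats::rnorm(n, delta, 1)
    y_ctrl <- stats::rnorm(n, 0, 1)
    data.frame(
      trial_id = sprintf("lab_%03d", i), design = "laboratory",
      follow_up_months = 0, is_meta_analysis = FALSE,
      outcome_kind = "continuous",
      test_mean = mean(y_test), test_sd = stats::sd(y_test), test_n = n,
      control_mean = mean(y_ctrl), control_sd = stats::sd(y_ctrl),
      control_n = n,
      effect_direction = cfg$lab_direction,
      stringsAsFactors = FALSE
    )
  })
  as_evidence_table(do.call(rbind, rows))
}

#' Generate a complete synthetic evidence table
#'
#' Binds the three strata ([generate_rct_datasets()],
#' [generate_uncontrolled_datasets()], [generate_lab_datasets()]) into one
#' table ready for [run_pipeline()]. Identical configurations produce
#' identical tables.
#'
#' @param cfg A [sim_config()].
#' @return An `evidence_table`.
#' @examples
#' tab <- generate_evidence_table(sim_config(seed = 7))
#' table(tab$design)
#' @export
generate_evidence_table <- function(cfg = sim_config()) {
  as_evidence_table(rbind(
    as.data.frame(generate_rct_datasets(cfg)),
    as.data.frame(generate_uncontrolled_datasets(cfg)),
    as.data.frame(generate_lab_datasets(cfg))
  ))
}
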