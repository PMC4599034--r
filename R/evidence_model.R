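#' @keywords internal
"_PACKAGE"

DESIGNS <- c("uncontrolled_clinical", "laboratory", "rct")
OUTCOME_KINDS <- c("binary", "continuous")
MEASURES <- c("OR", "SMD")
DIRECTIONS <- c("higher_is_worse_for_test", "higher_is_better_for_test")

# Canonical column order of the evidence table. One row = one extractable
# dataset from one trial; empty cell = absent.
EVIDENCE_COLUMNS <- c(
  "trial_id", "design", "follow_up_months", "is_meta_analysis",
  "outcome_kind",
  "test_failures", "test_total", "control_failures", "control_total",
  "test_mean", "test_sd", "test_n", "control_mean", "control_sd",
  "control_n",
  "effect_measure", "effect_point", "effect_ci_low", "effect_ci_high",
  "effect_direction"
)
MANDATORY_COLUMNS <- c(
  "trial_id", "design", "follow_up_months", "is_meta_analysis",
  "outcome_kind"
)
NUMERIC_COLUMNS <- c(
  "follow_up_months",
  "test_failures", "test_total", "control_failures", "control_total",
  "test_mean", "test_sd", "test_n", "control_mean", "control_sd",
  "control_n", "effect_point", "effect_ci_low", "effect_ci_high"
)

#' Construct an effect estimate
#'
#' An effect estimate is one comparison between the test condition (HVGIC,
#' a high-viscosity glass-ionomer restorative) and the control condition
#' (silver amalgam): an odds ratio (`"OR"`) for binary failure outcomes or a
#' standardised mean difference (`"SMD"`) for continuous laboratory
#' outcomes, with a confidence interval. The `direction` field records which
#' side of the null favours the control material, so that downstream
#' classification can map significance onto the rival hypotheses without
#' assuming a sign convention.
#'
#' @param measure `"OR"` or `"SMD"`.
#' @param point Point estimate. Must be strictly positive for an OR.
#' @param ci_low,ci_high Confidence-interval bounds, `ci_low <= point <=
#'   ci_high`.
#' @param ci_level Confidence level as a fraction (default 0.95).
#' @param direction `"higher_is_worse_for_test"` (values above the null mean
#'   the test material performs worse, e.g. failure odds) or
#'   `"higher_is_better_for_test"` (e.g. a strength measurement).
#' @param flags Character vector of provenance flags, e.g.
#'   `"continuity_corrected"` or `"degenerate"`.
#' @return An object of class `effect_estimate`.
#' @examples
#' effect_estimate("OR", 1.3, 0.8, 2.1)
#' @export
effect_estimate <- function(measure, point, ci_low, ci_high,
                            ci_level = 0.95,
                            direction = "higher_is_worse_for_test",
                            flags = character()) {
  measure <- match.arg(measure, MEASURES)
  direction <- match.arg(direction, DIRECTIONS)
  stopifnot(is.numeric(point), is.numeric(ci_low), is.numeric(ci_high),
            length(point) == 1L, length(ci_low) == 1L,
            length(ci_high) == 1L)
  if (!(ci_level > 0 && ci_level < 1)) {
    stop("ci_level must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!(ci_low <= point && point <= ci_high)) {
    stop("invalid interval: need ci_low <= point <= ci_high", call. = FALSE)
  }
  if (measure == "OR" && (point <= 0 || ci_low <= 0)) {
    stop("an odds ratio and its lower CI bound must be strictly positive",
         call. = FALSE)
  }
  structure(
    list(measure = measure, point = point, ci_low = ci_low,
         ci_high = ci_high, ci_level = ci_level, direction = direction,
         flags = flags),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s %.4g [%.0f%% CI %.4g, %.4g] (%s)%s\n",
              x$measure, x$point, 100 * x$ci_level, x$ci_low, x$ci_high,
              x$direction,
              if (length(x$flags)) paste0(" flags: ",
                                          paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Construct an evidence source
#'
#' A named body of evidence contributing one probability ratio
#' P(E|H1)/P(E|H2) to the synthesis. In `tallied` mode the probabilities
#' derive from counts of classified events supporting each hypothesis; in
#' `fixed` mode they are supplied directly (e.g. the equivocal 0.50/0.50
#' weighting given to evidence judged unreliable for clinical inference).
#'
#' @param name Source label, e.g. `"Evidence 1"`.
#' @param n_H1,n_H2 Event counts supporting H1 / H2 (tallied mode).
#' @param p_H1,p_H2 Fixed probabilities summing to 1 (fixed mode).
#' @return An object of class `evidence_source` with a `mode` field.
#' @examples
#' evidence_source("Evidence 1", n_H1 = 9, n_H2 = 8)
#' evidence_source("Evidence 1", p_H1 = 0.5, p_H2 = 0.5)
#' @export
evidence_source <- function(name, n_H1 = NULL, n_H2 = NULL,
                            p_H1 = NULL, p_H2 = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  tallied <- !is.null(n_H1) || !is.null(n_H2)
  fixed <- !is.null(p_H1) || !is.null(p_H2)
  if (tallied == fixed) {
    stop("supply either counts (n_H1, n_H2) or probabilities (p_H1, p_H2)",
         call. = FALSE)
  }
  if (tallied) {
    stopifnot(is.numeric(n_H1), is.numeric(n_H2))
    if (n_H1 < 0 || n_H2 < 0 || n_H1 != round(n_H1) || n_H2 != round(n_H2)) {
      stop("event counts must be non-negative integers", call. = FALSE)
    }
    if (n_H1 + n_H2 < 1) {
      stop("a tallied source needs at least one event", call. = FALSE)
    }
    out <- list(name = name, mode = "tallied",
                n_H1 = as.integer(n_H1), n_H2 = as.integer(n_H2))
  } else {
    stopifnot(is.numeric(p_H1), is.numeric(p_H2))
    if (p_H1 < 0 || p_H2 < 0 || abs(p_H1 + p_H2 - 1) > 1e-12) {
      stop("fixed probabilities must be non-negative and sum to 1",
           call. = FALSE)
    }
    out <- list(name = name, mode = "fixed", p_H1 = p_H1, p_H2 = p_H2)
  }
  structure(out, class = "evidence_source")
}

# Probabilities (p_H1, p_H2) of a source, from raw counts in tallied mode.
source_probs <- function(src, smoothing = FALSE) {
  stopifnot(inherits(src, "evidence_source"))
  if (src$mode == "fixed") {
    return(c(p_H1 = src$p_H1, p_H2 = src$p_H2))
  }
  n1 <- src$n_H1
  n2 <- src$n_H2
  if (smoothing) {
    n1 <- n1 + 1L
    n2 <- n2 + 1L
  }
  n <- n1 + n2
  c(p_H1 = n1 / n, p_H2 = n2 / n)
}

#' @export
print.evidence_source <- function(x, ...) {
  p <- source_probs(x)
  if (x$mode == "tallied") {
    cat(sprintf("%s: %d H1-events vs %d H2-events (P(E|H1) = %.4g, P(E|H2) = %.4g)\n",
                x$name, x$n_H1, x$n_H2, p[[1]], p[[2]]))
  } else {
    cat(sprintf("%s: fixed P(E|H1) = %.4g, P(E|H2) = %.4g\n",
                x$name, p[[1]], p[[2]]))
  }
  invisible(x)
}

#' Build a one-row evidence table for a single trial dataset
#'
#' Convenience constructor used in examples and tests; the usual entry point
#' for bulk data is [read_evidence_table()] or the synthetic generators.
#'
#' @param trial_id Opaque trial identifier; several datasets (e.g. follow-up
#'   intervals) may share one `trial_id`.
#' @param design `"uncontrolled_clinical"`, `"laboratory"` or `"rct"`.
#' @param follow_up_months Follow-up duration; 0 is allowed for laboratory
#'   comparisons.
#' @param is_meta_analysis Whether the row reports a meta-analysis result
#'   (given selection priority over single datasets within a trial).
#' @param outcome_kind `"binary"` (restoration failure counts) or
#'   `"continuous"` (laboratory summaries).
#' @param test_failures,test_total Failure count and evaluated total in the
#'   test (HVGIC) arm.
#' @param control_failures,control_total Same for the control (amalgam) arm;
#'   absent for one-arm HVGIC datasets.
#' @param test_mean,test_sd,test_n,control_mean,control_sd,control_n
#'   Continuous-outcome summaries.
#' @param effect_measure,effect_point,effect_ci_low,effect_ci_high
#'   Pre-computed effect estimate, used when raw summaries are unavailable.
#' @param effect_direction Direction convention for the (reported or
#'   derived) effect; see [effect_estimate()].
#' @return A validated one-row `evidence_table`.
#' @export
trial_dataset <- function(trial_id, design, follow_up_months,
                          is_meta_analysis = FALSE,
                          outcome_kind = "binary",
                          test_failures = NA, test_total = NA,
                          control_failures = NA, control_total = NA,
                          test_mean = NA, test_sd = NA, test_n = NA,
                          control_mean = NA, control_sd = NA,
                          control_n = NA,
                          effect_measure = NA, effect_point = NA,
                          effect_ci_low = NA, effect_ci_high = NA,
                          effect_direction = NA) {
  df <- data.frame(
    trial_id = trial_id, design = design,
    follow_up_months = follow_up_months,
    is_meta_analysis = is_meta_analysis, outcome_kind = outcome_kind,
    test_failures = as.numeric(test_failures),
    test_total = as.numeric(test_total),
    control_failures = as.numeric(control_failures),
    control_total = as.numeric(control_total),
    test_mean = as.numeric(test_mean), test_sd = as.numeric(test_sd),
    test_n = as.numeric(test_n), control_mean = as.numeric(control_mean),
    control_sd = as.numeric(control_sd), control_n = as.numeric(control_n),
    effect_measure = as.character(effect_measure),
    effect_point = as.numeric(effect_point),
    effect_ci_low = as.numeric(effect_ci_low),
    effect_ci_high = as.numeric(effect_ci_high),
    effect_direction = as.character(effect_direction),
    stringsAsFactors = FALSE
  )
  as_evidence_table(df)
}

row_has_raw <- function(row) {
  if (row$outcome_kind == "binary") {
    (!is.na(row$test_total) && !is.na(row$test_failures)) ||
      (!is.na(row$control_total) && !is.na(row$control_failures))
  } else {
    all(!is.na(c(row$test_mean, row$test_sd, row$test_n,
                 row$control_mean, row$control_sd, row$control_n)))
  }
}

row_has_two_binary_arms <- function(row) {
  all(!is.na(c(row$test_failures, row$test_total,
               row$control_failures, row$control_total)))
}

row_has_reported <- function(row) {
  !is.na(row$effect_measure) && !is.na(row$effect_point) &&
    !is.na(row$effect_ci_low) && !is.na(row$effect_ci_high)
}

# One diagnostic message per invalid row; NA for valid rows.
validate_evidence_row <- function(row) {
  problems <- character()
  if (is.na(row$trial_id) || !nzchar(row$trial_id)) {
    problems <- c(problems, "missing trial_id")
  }
  if (!row$design %in% DESIGNS) {
    problems <- c(problems, sprintf("unknown design '%s'", row$design))
  }
  if (!row$outcome_kind %in% OUTCOME_KINDS) {
    problems <- c(problems,
                  sprintf("unknown outcome_kind '%s'", row$outcome_kind))
  }
  if (is.na(row$follow_up_months) || row$follow_up_months < 0) {
    problems <- c(problems, "follow_up_months must be non-negative")
  }
  if (is.na(row$is_meta_analysis)) {
    problems <- c(problems, "is_meta_analysis must be TRUE or FALSE")
  }
  for (arm in c("test", "control")) {
    f <- row[[paste0(arm, "_failures")]]
    n <- row[[paste0(arm, "_total")]]
    if (!is.na(f) && !is.na(n)) {
      if (n < 1) {
        problems <- c(problems, sprintf("%s_total must be >= 1", arm))
      } else if (f < 0 || f > n) {
        problems <- c(problems,
                      sprintf("%s_failures (%g) exceeds %s_total (%g)",
                              arm, f, arm, n))
      }
    } else if (xor(is.na(f), is.na(n))) {
      problems <- c(problems,
                    sprintf("%s arm needs both failures and total", arm))
    }
    s <- row[[paste0(arm, "_sd")]]
    k <- row[[paste0(arm, "_n")]]
    if (!is.na(s) && s < 0) {
      problems <- c(problems, sprintf("%s_sd must be >= 0", arm))
    }
    if (!is.na(k) && k < 2) {
      problems <- c(problems, sprintf("%s_n must be >= 2", arm))
    }
  }
  has_raw <- isTRUE(row$design %in% DESIGNS) &&
    isTRUE(row$outcome_kind %in% OUTCOME_KINDS) && row_has_raw(row)
  has_rep <- row_has_reported(row)
  if (has_rep) {
    if (!row$effect_measure %in% MEASURES) {
      problems <- c(problems, sprintf("unknown effect_measure '%s'",
                                      row$effect_measure))
    } else if (!(row$effect_ci_low <= row$effect_point &&
                 row$effect_point <= row$effect_ci_high)) {
      problems <- c(problems, "reported effect CI must bracket the point")
    } else if (row$effect_measure == "OR" &&
               (row$effect_point <= 0 || row$effect_ci_low <= 0)) {
      problems <- c(problems, "reported OR and lower CI must be positive")
    }
  }
  if (!has_raw && !has_rep && length(problems) == 0L) {
    problems <- c(problems,
                  "neither raw arm summaries nor a reported effect present")
  }
  if (isTRUE(row$design == "rct") && length(problems) == 0L) {
    two_arms <- if (row$outcome_kind == "binary") {
      row_has_two_binary_arms(row)
    } else {
      row_has_raw(row)
    }
    if (!two_arms && !has_rep) {
      problems <- c(problems, "rct rows require two arms or a reported effect")
    }
  }
  if (length(problems) == 0L) NA_character_
  else paste(problems, collapse = "; ")
}

#' Coerce a data frame to a validated evidence table
#'
#' Adds any missing optional columns as `NA`, coerces column types, and
#' checks every row against the dataset invariants (arm counts consistent,
#' at least one of raw summaries / reported effect present, two arms for
#' RCTs, valid reported CIs). Uncontrolled clinical rows with follow-up
#' below 12 months are flagged with a warning but kept: follow-up
#' enforcement belongs to screening configuration, not the reader.
#'
#' @param df A data frame with at least the mandatory columns `trial_id`,
#'   `design`, `follow_up_months`, `is_meta_analysis`, `outcome_kind`.
#' @param on_invalid `"error"` (default) aborts listing every invalid row;
#'   `"drop"` removes invalid rows with one warning per row and records the
#'   diagnostics in the `"diagnostics"` attribute.
#' @return An `evidence_table` (a classed data frame).
#' @export
as_evidence_table <- function(df, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("evidence table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(EVIDENCE_COLUMNS, names(df))) {
    df[[col]] <- if (col %in% NUMERIC_COLUMNS) NA_real_ else NA_character_
  }
  df <- df[EVIDENCE_COLUMNS]
  df$trial_id <- as.character(df$trial_id)
  df$design <- as.character(df$design)
  df$outcome_kind <- as.character(df$outcome_kind)
  df$effect_measure <- as.character(df$effect_measure)
  df$effect_direction <- as.character(df$effect_direction)
  if (!is.logical(df$is_meta_analysis)) {
    v <- tolower(trimws(as.character(df$is_meta_analysis)))
    df$is_meta_analysis <- v %in% c("true", "t", "1", "yes")
    df$is_meta_analysis[v %in% c("", "na")] <- NA
  }
  for (col in NUMERIC_COLUMNS) df[[col]] <- as.numeric(df[[col]])
  empty_dir <- is.na(df$effect_direction) | !nzchar(df$effect_direction)
  df$effect_direction[empty_dir] <- "higher_is_worse_for_test"
  bad_dir <- !df$effect_direction %in% DIRECTIONS
  if (any(bad_dir)) {
    stop("unknown effect_direction in row(s) ",
         paste(which(bad_dir), collapse = ", "), call. = FALSE)
  }
  diagnostics <- vapply(seq_len(nrow(df)), function(i) {
    validate_evidence_row(df[i, , drop = FALSE])
  }, character(1))
  invalid <- which(!is.na(diagnostics))
  diag_df <- data.frame(row = invalid,
                        message = diagnostics[invalid],
                        stringsAsFactors = FALSE)
  if (length(invalid)) {
    msgs <- sprintf("row %d: %s", invalid, diagnostics[invalid])
    if (on_invalid == "error") {
      stop("invalid evidence table row(s):\n  ",
           paste(msgs, collapse = "\n  "), call. = FALSE)
    }
    for (m in msgs) warning(m, call. = FALSE)
    df <- df[-invalid, , drop = FALSE]
    rownames(df) <- NULL
  }
  short_fu <- which(df$design == "uncontrolled_clinical" &
                      df$follow_up_months < 12)
  if (length(short_fu)) {
    warning("uncontrolled clinical row(s) with follow-up < 12 months: ",
            paste(short_fu, collapse = ", "),
            " (kept; screening configuration governs inclusion)",
            call. = FALSE)
  }
  structure(df, class = c("evidence_table", "data.frame"),
            diagnostics = diag_df)
}

# Zero-row table with the full canonical schema.
empty_evidence_table <- function() {
  df <- as.data.frame(
    setNames(lapply(EVIDENCE_COLUMNS, function(col) {
      if (col %in% NUMERIC_COLUMNS) numeric(0)
      else if (col == "is_meta_analysis") logical(0)
      else character(0)
    }), EVIDENCE_COLUMNS),
    stringsAsFactors = FALSE
  )
  as_evidence_table(df)
}

#' Read an evidence table from CSV
#'
#' The CSV schema is one row per extractable dataset, long format, header
#' required, empty cell = absent; columns as documented in
#' [trial_dataset()]. Rows violating the dataset invariants are rejected
#' with row-indexed diagnostics.
#'
#' @param path Path to a CSV file.
#' @inheritParams as_evidence_table
#' @return An `evidence_table`.
#' @seealso [write_evidence_table()]
#' @export
read_evidence_table <- function(path, on_invalid = c("error", "drop")) {
  if (!file.exists(path)) {
    stop("evidence table not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  as_evidence_table(df, on_invalid = match.arg(on_invalid))
}

#' Write an evidence table to CSV
#'
#' @param tab An `evidence_table`.
#' @param path Output path; absent values become empty cells.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(tab, path) {
  stopifnot(inherits(tab, "evidence_table"))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "")
  invisible(path)
}
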