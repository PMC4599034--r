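#' Power-screen configuration
#'
#' Holds the assumptions behind the statistical-power screen applied to
#' clinical failure-rate datasets: type I error `alpha`, type II error
#' `beta`, the detectable difference `delta_pct` in percentage points
#' (test-arm failure rate assumed `delta_pct` above the control rate), and
#' the Pocock power factor.
#'
#' @param alpha Type I error risk (default 0.05).
#' @param beta Type II error risk (default 0.20; power 80%).
#' @param delta_pct Detectable failure-rate difference in percentage
#'   points (default 10). Negative values evaluate the screen from the
#'   other arm's perspective and are allowed for symmetry checks.
#' @param f_value `"paper"` uses the tabulated constant 7.9 so published
#'   screening decisions reproduce exactly; `"computed"` uses
#'   [pocock_f()] at `(alpha, beta)`; a number pins it directly.
#' @param reference_control_rate_pct Control (amalgam) failure rate in
#'   percent to assume for one-arm HVGIC datasets, which have no amalgam
#'   arm of their own. Mandatory whenever such datasets are screened; no
#'   silent default exists.
#' @return An object of class `screen_config` with the resolved `f`.
#' @export
screen_config <- function(alpha = 0.05, beta = 0.20, delta_pct = 10,
                          f_value = "paper",
                          reference_control_rate_pct = NULL) {
  if (!(alpha > 0 && alpha < 1) || !(beta > 0 && beta < 1)) {
    stop("alpha and beta must lie strictly between 0 and 1", call. = FALSE)
  }
  if (delta_pct == 0 || abs(delta_pct) >= 100) {
    stop("delta_pct must be non-zero and smaller than 100 in magnitude",
         call. = FALSE)
  }
  f <- if (identical(f_value, "paper")) {
    7.9
  } else if (identical(f_value, "computed")) {
    pocock_f(alpha, beta)
  } else if (is.numeric(f_value) && length(f_value) == 1L && f_value > 0) {
    f_value
  } else {
    stop("f_value must be \"paper\", \"computed\" or a positive number",
         call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta, delta_pct = delta_pct,
         f_value = f_value, f = f,
         reference_control_rate_pct = reference_control_rate_pct),
    class = "screen_config"
  )
}

#' Pocock power factor
#'
#' `f(alpha, beta) = (z_{1-alpha/2} + z_{1-beta})^2`, the multiplier in
#' Pocock's two-proportion sample-size formula. At the conventional
#' alpha = 0.05, beta = 0.20 this evaluates to 7.8489, tabulated as 7.9.
#'
#' @param alpha,beta Error risks, each strictly inside (0, 1).
#' @return The power factor (positive real).
#' @examples
#' pocock_f(0.05, 0.20)
#' @export
pocock_f <- function(alpha, beta) {
  if (!(alpha > 0 && alpha < 1) || !(beta > 0 && beta < 1)) {
    stop("alpha and beta must lie strictly between 0 and 1", call. = FALSE)
  }
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(1 - beta))^2
}

#' Required per-group sample size (Pocock formula)
#'
#' `N_P = ((P1 (100 - P1) + P2 (100 - P2)) / (P2 - P1)^2) * f(alpha, beta)`
#' on the percentage scale, with the test-arm rate `P1 = P2 + delta_pct`.
#' The value is returned unrounded; the exclusion rule consumes the real
#' value directly.
#'
#' @param p2_pct Control-group (amalgam) failure rate in percent.
#' @param cfg A [screen_config()].
#' @return `N_P`, the required sample size per group.
#' @examples
#' required_sample_size(10) # 197.5 under the defaults
#' @export
required_sample_size <- function(p2_pct, cfg = screen_config()) {
  stopifnot(inherits(cfg, "screen_config"), is.numeric(p2_pct))
  p1 <- p2_pct + cfg$delta_pct
  if (p2_pct < 0 || p2_pct > 100 || p1 < 0 || p1 > 100) {
    stop(sprintf(
      "rates outside [0, 100]: P2 = %g%%, P1 = P2 + %g = %g%%",
      p2_pct, cfg$delta_pct, p1), call. = FALSE)
  }
  ((p1 * (100 - p1) + p2_pct * (100 - p2_pct)) / (p1 - p2_pct)^2) * cfg$f
}

# Combined evaluated sample size of a dataset: sum over the arms present.
# For one-arm datasets this is the single arm's total.
dataset_n_t <- function(row) {
  sum(c(row$test_total, row$control_total), na.rm = TRUE)
}

# Control (amalgam) failure rate in percent, or NA when unobtainable.
dataset_p2_pct <- function(row, cfg) {
  if (!is.na(row$control_total) && !is.na(row$control_failures)) {
    100 * row$control_failures / row$control_total
  } else if (!is.null(cfg$reference_control_rate_pct)) {
    cfg$reference_control_rate_pct
  } else {
    NA_real_
  }
}

#' Screen one dataset for sufficient statistical power
#'
#' Laboratory datasets are exempt: they did not originate from clinical
#' investigations and are always included. Clinical binary datasets are
#' excluded when their combined sample size `N_T` is lower than twice the
#' required per-group size `2 N_P` (strict inequality: ties are included).
#' The control rate `P2` comes from the dataset's amalgam arm, or from
#' `cfg$reference_control_rate_pct` for one-arm HVGIC datasets.
#'
#' @param ds A one-row `evidence_table`.
#' @param cfg A [screen_config()].
#' @return A list with `trial_id`, `decision` (`"included"`, `"excluded"`
#'   or `"exempt_laboratory"`), `p2_pct`, `n_p`, `threshold` (= 2 N_P) and
#'   `n_t`.
#' @export
screen_dataset <- function(ds, cfg = screen_config()) {
  stopifnot(is.data.frame(ds), nrow(ds) == 1L,
            inherits(cfg, "screen_config"))
  row <- ds[1, , drop = FALSE]
  if (row$design == "laboratory") {
    return(list(trial_id = row$trial_id, decision = "exempt_laboratory",
                p2_pct = NA_real_, n_p = NA_real_, threshold = NA_real_,
                n_t = NA_real_))
  }
  if (row$outcome_kind != "binary") {
    stop(sprintf(
      "dataset '%s': the power screen covers binary failure-rate outcomes; ",
      row$trial_id),
      "non-laboratory continuous outcomes are unsupported", call. = FALSE)
  }
  if (!row_has_raw(row)) {
    stop(sprintf(
      "dataset '%s': arm totals are required to screen for power",
      row$trial_id), call. = FALSE)
  }
  p2 <- dataset_p2_pct(row, cfg)
  if (is.na(p2)) {
    stop(sprintf(
      paste0("dataset '%s' has no amalgam arm and no ",
             "reference_control_rate_pct is configured"),
      row$trial_id), call. = FALSE)
  }
  n_p <- required_sample_size(p2, cfg)
  n_t <- dataset_n_t(row)
  list(trial_id = row$trial_id,
       decision = if (n_t < 2 * n_p) "excluded" else "included",
       p2_pct = p2, n_p = n_p, threshold = 2 * n_p, n_t = n_t)
}

#' Screen every dataset in an evidence table
#'
#' @param tab An `evidence_table`.
#' @param cfg A [screen_config()].
#' @return A data frame with one row per dataset: `row`, `trial_id`,
#'   `decision`, `p2_pct`, `n_p`, `threshold`, `n_t`.
#' @export
screen_datasets <- function(tab, cfg = screen_config()) {
  stopifnot(is.data.frame(tab))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    s <- screen_dataset(tab[i, , drop = FALSE], cfg)
    data.frame(row = i, trial_id = s$trial_id, decision = s$decision,
               p2_pct = s$p2_pct, n_p = s$n_p, threshold = s$threshold,
               n_t = s$n_t, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select one dataset per trial
#'
#' Applies the de-duplication rules among datasets that survived the power
#' screen: within each `trial_id`, meta-analysis rows outrank single
#' datasets, and within the winning rank the longest follow-up wins. Each
#' trial contributes at most one dataset; a trial whose datasets were all
#' power-excluded contributes nothing.
#'
#' @param tab An `evidence_table`.
#' @param screen The decision table from [screen_datasets()] for `tab`.
#' @return The selected subset of `tab`, with attribute `"dropped"` giving
#'   the number of surviving-but-unselected datasets.
#' @export
select_per_trial <- function(tab, screen) {
  stopifnot(is.data.frame(tab), is.data.frame(screen),
            nrow(tab) == nrow(screen))
  keep <- screen$decision != "excluded"
  surv <- tab[keep, , drop = FALSE]
  if (nrow(surv) == 0L) {
    out <- tab[0, , drop = FALSE]
    attr(out, "dropped") <- 0L
    return(out)
  }
  pick <- unlist(lapply(split(seq_len(nrow(surv)), surv$trial_id),
                        function(idx) {
    g <- surv[idx, , drop = FALSE]
    ord <- order(-as.integer(g$is_meta_analysis), -g$follow_up_months)
    idx[ord[1]]
  }), use.names = FALSE)
  pick <- sort(pick)
  out <- surv[pick, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- nrow(surv) - length(pick)
  out
}
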