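#' Prior odds of H1 relative to H2
#'
#' `Odds_Pre = P(H1) / P(H2)` with `P(H2) = 1 - P(H1)`. For a tallied
#' source the odds are computed from the raw counts (`n_H1 / n_H2`), never
#' from pre-rounded probabilities: 9 vs 8 events gives exactly 9/8 =
#' 1.125, displayed as 1.12 only at report time. `n_H2 = 0` with
#' `n_H1 > 0` yields `Inf` (an explicit infinity flag in reports).
#'
#' @param prior_source An [evidence_source()].
#' @return A non-negative number, possibly `Inf`.
#' @examples
#' prior_odds(evidence_source("Evidence 1", n_H1 = 9, n_H2 = 8))
#' @export
prior_odds <- function(prior_source) {
  stopifnot(inherits(prior_source, "evidence_source"))
  if (prior_source$mode == "tallied") {
    n1 <- prior_source$n_H1
    n2 <- prior_source$n_H2
    if (n1 == 0L && n2 == 0L) {
      stop("prior odds undefined: no events in either direction",
           call. = FALSE)
    }
    if (n2 == 0L) return(Inf)
    return(n1 / n2)
  }
  if (prior_source$p_H2 == 0) {
    if (prior_source$p_H1 == 0) {
      stop("prior odds undefined: both probabilities zero", call. = FALSE)
    }
    return(Inf)
  }
  prior_source$p_H1 / prior_source$p_H2
}

# One source's contribution P(E|H1)/P(E|H2) to the likelihood ratio.
source_ratio <- function(src, smoothing = FALSE) {
  p <- source_probs(src, smoothing = smoothing &&
                      src$mode == "tallied")
  if (p[["p_H2"]] == 0) {
    stop(sprintf(
      "source '%s': P(E|H2) = 0 makes the likelihood ratio undefined %s",
      src$name, "(enable smoothing or revise the source)"), call. = FALSE)
  }
  p[["p_H1"]] / p[["p_H2"]]
}

#' Likelihood ratio over independent evidence sources
#'
#' `LR = prod_n P_n(E|H1) / P_n(E|H2)`. Fixed-mode sources contribute
#' their fixed probabilities (the equivocal 0.50/0.50 source contributes
#' exactly 1); tallied sources contribute their count-derived
#' probabilities. A source with `P(E|H1) = 0` drives the whole product to
#' zero — every subsequent multiplication stays zero — while
#' `P(E|H2) = 0` has no finite answer and is an error naming the source,
#' unless add-one smoothing is enabled.
#'
#' @param sources A list of [evidence_source()]s (order irrelevant). An
#'   empty list gives LR = 1.
#' @param smoothing Apply Laplace (add-one) smoothing to the counts of
#'   every tallied source (default `FALSE`; the literal calculus lets
#'   zeros propagate).
#' @return A non-negative number.
#' @examples
#' likelihood_ratio(list(
#'   evidence_source("Evidence 1", p_H1 = 0.5, p_H2 = 0.5),
#'   evidence_source("Evidence 2", n_H1 = 0, n_H2 = 3)))
#' @export
likelihood_ratio <- function(sources, smoothing = FALSE) {
  stopifnot(is.list(sources))
  ratios <- vapply(sources, source_ratio, numeric(1),
                   smoothing = smoothing)
  prod(ratios)
}

#' Posterior odds
#'
#' `Odds_Post = Odds_Pre x LR`. The indeterminate product `Inf x 0` (or
#' `0 x Inf`) is an explicit error — no finite answer is defensible — and
#' is never silently resolved to 0 or infinity.
#'
#' @param odds_pre Prior odds (non-negative, possibly `Inf`).
#' @param lr Likelihood ratio (non-negative, possibly `Inf`).
#' @return The posterior odds.
#' @examples
#' posterior_odds(1.125, 0)
#' @export
posterior_odds <- function(odds_pre, lr) {
  stopifnot(is.numeric(odds_pre), is.numeric(lr),
            odds_pre >= 0, lr >= 0)
  if ((is.infinite(odds_pre) && lr == 0) ||
      (odds_pre == 0 && is.infinite(lr))) {
    stop("posterior odds undefined: infinite odds multiplied by zero",
         call. = FALSE)
  }
  odds_pre * lr
}

#' Assemble a full synthesis result
#'
#' Runs the odds calculus end to end: prior odds from `prior_source`, one
#' probability ratio per new source, their product as the likelihood
#' ratio, and the posterior odds, packaged with the pipeline flow counts.
#'
#' @param prior_source [evidence_source()] the prior odds derive from.
#' @param new_sources List of [evidence_source()]s carrying the new
#'   evidence (may be empty: the update is then vacuous and the posterior
#'   equals the prior).
#' @param smoothing Add-one smoothing for tallied `new_sources` (the prior
#'   tally is never smoothed). With smoothing on, every ratio is finite
#'   and strictly positive.
#' @param flow Optional named list of pipeline flow counts (datasets read,
#'   excluded, selected, events classified).
#' @return An object of class `synthesis_result` with fields `odds_pre`,
#'   `per_source_ratios` (named numeric), `likelihood_ratio`, `odds_post`
#'   and `flow`.
#' @examples
#' synthesize(evidence_source("Evidence 1", n_H1 = 9, n_H2 = 8),
#'            list(evidence_source("Evidence 1", p_H1 = .5, p_H2 = .5),
#'                 evidence_source("Evidence 2", n_H1 = 0, n_H2 = 3)))
#' @export
synthesize <- function(prior_source, new_sources = list(),
                       smoothing = FALSE, flow = NULL) {
  stopifnot(inherits(prior_source, "evidence_source"), is.list(new_sources))
  pre <- prior_odds(prior_source)
  ratios <- vapply(new_sources, source_ratio, numeric(1),
                   smoothing = smoothing)
  names(ratios) <- vapply(new_sources, `[[`, character(1), "name")
  lr <- prod(ratios)
  structure(
    list(odds_pre = pre, per_source_ratios = ratios,
         likelihood_ratio = lr, odds_post = posterior_odds(pre, lr),
         flow = flow),
    class = "synthesis_result"
  )
}

# Display rounding used only in reports: two decimals, half to even.
display_round <- function(x) {
  ifelse(is.infinite(x), x, round(x, 2))
}

fmt_odds <- function(x) {
  if (is.infinite(x)) "Inf" else format(display_round(x), nsmall = 2)
}

#' @export
print.synthesis_result <- function(x, ...) {
  cat("Bayesian odds synthesis\n")
  cat("1. Hypotheses\n")
  cat("   H1: the test condition is inferior to the control\n")
  cat("   H2: the test condition is not inferior to the control\n")
  cat("2. Prior odds of H1 relative to H2\n")
  cat(sprintf("   Odds_Pre = %s\n", fmt_odds(x$odds_pre)))
  cat("3. Likelihood ratio (LR) in support of H1 relative to H2\n")
  for (nm in names(x$per_source_ratios)) {
    cat(sprintf("   %s: P(E|H1)/P(E|H2) = %s\n", nm,
                fmt_odds(x$per_source_ratios[[nm]])))
  }
  cat(sprintf("   LR = %s\n", fmt_odds(x$likelihood_ratio)))
  cat("4. Posterior odds of H1 relative to H2\n")
  cat(sprintf("   Odds_Post = Odds_Pre x LR = %s\n", fmt_odds(x$odds_post)))
  if (!is.null(x$flow)) {
    cat("Flow counts:",
        paste(sprintf("%s=%s", names(x$flow), unlist(x$flow)),
              collapse = " "), "\n")
  }
  invisible(x)
}

# JSON keeps infinities portable as the string "inf".
encode_odds <- function(x) if (is.infinite(x)) "inf" else x
decode_odds <- function(x) if (identical(x, "inf")) Inf else as.numeric(x)

#' Write a synthesis report to JSON
#'
#' The report carries every `synthesis_result` field plus a
#' human-readable summary block mirroring the four numbered sections of
#' the printed synthesis (hypotheses, prior odds, likelihood ratio,
#' posterior odds). Infinite odds are encoded as the string `"inf"` to
#' keep the JSON portable. The file round-trips through [read_report()].
#'
#' @param result A `synthesis_result`.
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "synthesis_result"))
  ratios <- lapply(seq_along(result$per_source_ratios), function(i) {
    list(source = names(result$per_source_ratios)[i],
         ratio = encode_odds(result$per_source_ratios[[i]]))
  })
  summary_lines <- utils::capture.output(print(result))
  doc <- list(
    odds_pre = encode_odds(result$odds_pre),
    per_source_ratios = ratios,
    likelihood_ratio = encode_odds(result$likelihood_ratio),
    odds_post = encode_odds(result$odds_post),
    flow = result$flow,
    summary = summary_lines
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a synthesis report back from JSON
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return The reconstructed `synthesis_result`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  ratios <- vapply(doc$per_source_ratios, function(r) decode_odds(r$ratio),
                   numeric(1))
  names(ratios) <- vapply(doc$per_source_ratios, `[[`, character(1),
                          "source")
  flow <- if (is.null(doc$flow)) NULL else lapply(doc$flow, as.integer)
  structure(
    list(odds_pre = decode_odds(doc$odds_pre),
         per_source_ratios = ratios,
         likelihood_ratio = decode_odds(doc$likelihood_ratio),
         odds_post = decode_odds(doc$odds_post),
         flow = flow),
    class = "synthesis_result"
  )
}
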