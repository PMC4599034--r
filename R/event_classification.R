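#' Classify an effect estimate as supporting H1 or H2
#'
#' The two rival hypotheses are H1 (the test material, HVGIC, is
#' clinically inferior to the control, amalgam) and H2 (it is not
#' inferior). An event supports H1 only when its confidence interval
#' indicates a statistically significant effect in favour of amalgam —
#' i.e. the CI lies strictly on the amalgam-favouring side of the null
#' (1 for an OR, 0 for an SMD), with the side given by the estimate's
#' `direction`. Non-significant events and events significantly favouring
#' HVGIC both support H2: "not inferior" covers equivalence as well as
#' superiority. A CI endpoint exactly at the null counts as containing it
#' (conservative toward H2) and is flagged as a boundary case.
#'
#' @param e An [effect_estimate()].
#' @param source_name Name of the evidence source the event belongs to.
#' @return An object of class `classified_event`: list with `estimate`,
#'   `source_name`, `support` (`"H1"` or `"H2"`), `reason`
#'   (`"significant_favors_control"`, `"not_significant"`,
#'   `"significant_favors_test"`) and logical `boundary`.
#' @examples
#' classify_event(effect_estimate("OR", 2.5, 1.2, 5.0), "Evidence 2")
#' @export
classify_event <- function(e, source_name) {
  stopifnot(inherits(e, "effect_estimate"),
            is.character(source_name), length(source_name) == 1L)
  null_value <- if (e$measure == "OR") 1 else 0
  boundary <- e$ci_low == null_value || e$ci_high == null_value
  above <- e$ci_low > null_value   # CI strictly above the null
  below <- e$ci_high < null_value  # CI strictly below the null
  # which side favours the control material (amalgam)
  control_side_above <- e$direction == "higher_is_worse_for_test"
  reason <- if (above) {
    if (control_side_above) "significant_favors_control"
    else "significant_favors_test"
  } else if (below) {
    if (control_side_above) "significant_favors_test"
    else "significant_favors_control"
  } else {
    "not_significant"
  }
  structure(
    list(estimate = e, source_name = source_name,
         support = if (reason == "significant_favors_control") "H1"
                   else "H2",
         reason = reason, boundary = boundary),
    class = "classified_event"
  )
}

#' @export
print.classified_event <- function(x, ...) {
  cat(sprintf("[%s] %s (%s%s)\n", x$source_name, x$support, x$reason,
              if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' Tally classified events into an evidence source
#'
#' Counts the H1- and H2-supporting events attributed to one named source
#' and returns the corresponding tallied [evidence_source()], from which
#' P(E|H1) = n_H1 / N and P(E|H2) = n_H2 / N derive.
#'
#' @param events A list of `classified_event`s (possibly from several
#'   sources).
#' @param source_name The source to tally; events attributed to other
#'   sources are ignored.
#' @return A tallied [evidence_source()].
#' @examples
#' ev <- list(classify_event(effect_estimate("OR", 2.5, 1.2, 5.0), "E2"),
#'            classify_event(effect_estimate("OR", 1.3, 0.8, 2.1), "E2"))
#' tally_events(ev, "E2")
#' @export
tally_events <- function(events, source_name) {
  stopifnot(is.list(events), is.character(source_name))
  mine <- Filter(function(ev) {
    stopifnot(inherits(ev, "classified_event"))
    ev$source_name == source_name
  }, events)
  if (length(mine) == 0L) {
    stop(sprintf("no events to tally for source '%s'", source_name),
         call. = FALSE)
  }
  support <- vapply(mine, `[[`, character(1), "support")
  evidence_source(source_name,
                  n_H1 = sum(support == "H1"),
                  n_H2 = sum(support == "H2"))
}

#' Classify the events of an evidence table subset
#'
#' Convenience wrapper: computes the effect for each row with
#' [effect_for_dataset()] and classifies it under the given source name.
#'
#' @param tab An `evidence_table` whose rows each yield a computable
#'   effect.
#' @param source_name Evidence-source label for all rows of `tab`.
#' @inheritParams effect_for_dataset
#' @return A list of `classified_event`s.
#' @export
classify_datasets <- function(tab, source_name, ci_level = 0.95,
                              smd_flavor = "hedges",
                              zero_cell_correction = TRUE) {
  stopifnot(is.data.frame(tab))
  lapply(seq_len(nrow(tab)), function(i) {
    e <- effect_for_dataset(tab[i, , drop = FALSE], ci_level = ci_level,
                            smd_flavor = smd_flavor,
                            zero_cell_correction = zero_cell_correction)
    classify_event(e, source_name)
  })
}
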