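#' Clinical event types
#'
#' The closed set of non-fatal clinical events tracked by the QALY accounting
#' and the microsimulation engine: ischaemic heart disease (IHD), myocardial
#' infarction (MI), stroke, congestive heart failure (CHF), blindness,
#' amputation, renal failure and diabetic foot ulcer. Death is not an event
#' type; it is handled through follow-up (death/censor times) and the death
#' equation of a risk-equation set.
#'
#' @return Character vector of the eight event type codes.
#' @export
#' @examples
#' event_types()
event_types <- function() {
  c("IHD", "MI", "STROKE", "CHF", "BLINDNESS", "AMPUTATION",
    "RENAL_FAILURE", "ULCER")
}

#' Event types that may recur
#'
#' MI, stroke and amputation may occur twice per patient; all other events
#' are modelled as first occurrences only.
#'
#' @return Character vector of recurrent event type codes.
#' @export
recurrent_event_types <- function() {
  c("MI", "STROKE", "AMPUTATION")
}

assert_event_types <- function(x, what = "event type") {
  bad <- setdiff(unique(as.character(x)), event_types())
  if (length(bad) > 0) {
    stop("Unknown ", what, "(s): ", paste(bad, collapse = ", "),
         ". Valid types: ", paste(event_types(), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
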