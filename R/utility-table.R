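#' Construct a utility table
#'
#' A utility table holds the baseline health-state utility and, for each
#' clinical event type, the utility decrement applied in the year of the
#' event and in subsequent years, together with the maximum number of
#' occurrences of each event that carry a decrement. Decrements are stored
#' as non-negative magnitudes and applied subtractively; utilities are
#' allowed to go negative (additive model, no floor).
#'
#' @param baseline_utility Utility at entry, in (0, 1].
#' @param decrements Named list over event types; each element is a list or
#'   numeric vector with components `event_year` and `subsequent`, both
#'   non-negative magnitudes.
#' @param max_counted Named integer vector over event types: the number of
#'   occurrences (counting any pre-baseline occurrence) that carry a
#'   decrement. Defaults to 2 for MI, stroke and amputation and 1 otherwise.
#'
#' @return An object of class `qv_utility_table`.
#' @seealso [default_utility_table()], [alt_utility_table()],
#'   [read_utility_table()]
#' @export
utility_table <- function(baseline_utility, decrements, max_counted = NULL) {
  if (!is.numeric(baseline_utility) || length(baseline_utility) != 1 ||
      is.na(baseline_utility) || baseline_utility <= 0 || baseline_utility > 1) {
    stop("baseline_utility must be a single number in (0, 1]", call. = FALSE)
  }
  assert_event_types(names(decrements))
  missing_ev <- setdiff(event_types(), names(decrements))
  if (length(missing_ev) > 0) {
    stop("decrements missing for: ", paste(missing_ev, collapse = ", "),
         call. = FALSE)
  }
  dec <- lapply(decrements[event_types()], function(d) {
    d <- as.list(d)
    if (is.null(d$event_year) || is.null(d$subsequent)) {
      stop("each decrement needs 'event_year' and 'subsequent'", call. = FALSE)
    }
    ev <- as.numeric(d$event_year); su <- as.numeric(d$subsequent)
    if (is.na(ev) || is.na(su) || ev < 0 || su < 0) {
      stop("decrements must be non-negative magnitudes", call. = FALSE)
    }
    list(event_year = ev, subsequent = su)
  })
  if (is.null(max_counted)) {
    max_counted <- stats::setNames(
      ifelse(event_types() %in% recurrent_event_types(), 2L, 1L),
      event_types())
  } else {
    assert_event_types(names(max_counted))
    full <- stats::setNames(
      ifelse(event_types() %in% recurrent_event_types(), 2L, 1L),
      event_types())
    full[names(max_counted)] <- as.integer(max_counted)
    max_counted <- full
    if (any(max_counted < 0)) stop("max_counted must be >= 0", call. = FALSE)
  }
  structure(
    list(baseline_utility = baseline_utility,
         decrements = dec,
         max_counted = max_counted[event_types()]),
    class = "qv_utility_table")
}

#' Default utility table
#'
#' Baseline utility 0.807 with additive event decrements: MI 0.065 in the
#' event year only; stroke 0.165 and renal failure 0.330 permanently; IHD and
#' blindness carry no decrement. The decrements for heart failure,
#' amputation and ulcer (and subsequent-year MI) are not published alongside
#' the others; they ship here as clearly labelled placeholders taken from the
#' alternative utility set of [alt_utility_table()], which is fully citable.
#' Second MI, stroke and amputation carry the same decrement as the first;
#' third occurrences (and second ulcers) carry none.
#'
#' @return A `qv_utility_table`.
#' @export
#' @examples
#' tab <- default_utility_table()
#' tab$baseline_utility
default_utility_table <- function() {
  utility_table(
    baseline_utility = 0.807,
    decrements = list(
      IHD           = list(event_year = 0,     subsequent = 0),
      MI            = list(event_year = 0.065, subsequent = 0),
      STROKE        = list(event_year = 0.165, subsequent = 0.165),
      # placeholder from the alternative set: not separately published
      CHF           = list(event_year = 0.108, subsequent = 0.108),
      BLINDNESS     = list(event_year = 0,     subsequent = 0),
      # placeholder from the alternative set
      AMPUTATION    = list(event_year = 0.280, subsequent = 0.280),
      RENAL_FAILURE = list(event_year = 0.330, subsequent = 0.330),
      # placeholder from the alternative set
      ULCER         = list(event_year = 0.170, subsequent = 0.170)
    ))
}

#' Alternative utility table (sensitivity analysis set)
#'
#' The fully specified alternative utility value set used in sensitivity
#' analysis SA4: initial utility 0.785; decrements IHD 0.09, MI 0.055,
#' stroke 0.164, heart failure 0.108, blindness 0.074, ulcer 0.170,
#' amputation 0.280, renal failure 0.204; subsequent-year decrements equal
#' to the event-year decrement.
#'
#' @return A `qv_utility_table`.
#' @export
alt_utility_table <- function() {
  dec <- c(IHD = 0.09, MI = 0.055, STROKE = 0.164, CHF = 0.108,
           BLINDNESS = 0.074, AMPUTATION = 0.280, RENAL_FAILURE = 0.204,
           ULCER = 0.170)
  utility_table(
    baseline_utility = 0.785,
    decrements = stats::setNames(lapply(event_types(), function(e) {
      list(event_year = unname(dec[e]), subsequent = unname(dec[e]))
    }), event_types()))
}

#' Read / write a utility table as YAML
#'
#' The on-disk schema is `baseline_utility`, `decrements: {EVENT:
#' {event_year, subsequent}}` and `max_counted: {EVENT: n}`.
#'
#' @param path File path.
#' @return `read_utility_table()` returns a `qv_utility_table`;
#'   `write_utility_table()` returns `path` invisibly.
#' @export
read_utility_table <- function(path) {
  x <- yaml::read_yaml(path)
  utility_table(baseline_utility = x$baseline_utility,
                decrements = x$decrements,
                max_counted = if (!is.null(x$max_counted))
                  unlist(x$max_counted) else NULL)
}

#' @rdname read_utility_table
#' @param table A `qv_utility_table`.
#' @export
write_utility_table <- function(table, path) {
  stopifnot(inherits(table, "qv_utility_table"))
  yaml::write_yaml(
    list(baseline_utility = table$baseline_utility,
         decrements = table$decrements,
         max_counted = as.list(table$max_counted)),
    path)
  invisible(path)
}

#' @export
print.qv_utility_table <- function(x, ...) {
  cat("Utility table (additive decrements, no floor)\n")
  cat("  baseline utility:", x$baseline_utility, "\n")
  d <- do.call(rbind, lapply(event_types(), function(e) {
    data.frame(event = e,
               event_year = x$decrements[[e]]$event_year,
               subsequent = x$decrements[[e]]$subsequent,
               max_counted = x$max_counted[[e]])
  }))
  print(d, row.names = FALSE)
  invisible(x)
}
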