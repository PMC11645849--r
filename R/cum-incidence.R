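#' Observed cumulative incidence with death as a competing risk
#'
#' Aalen–Johansen estimate of the cumulative incidence function (CIF) of an
#' event in the presence of death as a competing risk:
#' `CIF(t) = sum over event times <= t of S(t-) * d/n`, with `S` the
#' all-cause Kaplan–Meier among the analysis subset. With no deaths in the
#' data this reduces exactly to 1 minus the Kaplan–Meier of the event.
#' Pointwise 95% confidence intervals use the log(-log) transform.
#'
#' Subset rules follow first/second-event plotting conventions:
#' `"no_history"` restricts to patients with no pre-baseline history of the
#' event (first events), `"with_history"` to patients with such history
#' (their first on-study occurrence is a second event), `"all"` uses every
#' patient (used for death and for the any-event composite).
#'
#' The special event codes `"DEATH"` (death as the event of interest, no
#' competing risk) and `"ANY_EVENT"` (first event of any type, including
#' death, as a composite) are also accepted.
#'
#' Event times are taken as the annual cycle index of the first qualifying
#' on-study occurrence; death and censoring times may be fractional years.
#' An event and a death recorded at the same time are both processed
#' against the at-risk set just before that time.
#'
#' @param trial A [trial_data()] object.
#' @param event_type One of [event_types()], `"DEATH"` or `"ANY_EVENT"`.
#' @param subset_rule `"no_history"`, `"with_history"` or `"all"`.
#' @param conf_level Confidence level for the pointwise interval.
#' @return An object of class `qv_cif_curve`: a data frame with columns
#'   `time`, `estimate`, `lo`, `hi` and attributes `event`, `source`,
#'   `subset_rule`, `n`.
#' @export
observed_cif <- function(trial, event_type,
                         subset_rule = c("no_history", "with_history", "all"),
                         conf_level = 0.95) {
  stopifnot(inherits(trial, "qv_trial"))
  subset_rule <- match.arg(subset_rule)
  special <- event_type %in% c("DEATH", "ANY_EVENT")
  if (!special) assert_event_types(event_type)

  pats <- trial$patients
  if (!special && subset_rule != "all") {
    flag <- pats[[paste0("prior_", event_type)]]
    pats <- if (subset_rule == "no_history") pats[!flag, , drop = FALSE]
            else pats[flag, , drop = FALSE]
  }
  if (nrow(pats) == 0) stop("analysis subset is empty", call. = FALSE)

  death_time <- ifelse(!is.na(pats$death_time) &
                         pats$death_time <= pats$censor_time,
                       pats$death_time, NA_real_)
  ev <- trial$events[trial$events$patient_id %in% pats$patient_id, ,
                     drop = FALSE]
  if (event_type == "DEATH") {
    etime <- rep(NA_real_, nrow(pats))
  } else if (event_type == "ANY_EVENT") {
    first <- stats::aggregate(year_index ~ patient_id, data = ev, FUN = min)
    etime <- first$year_index[match(pats$patient_id, first$patient_id)]
  } else {
    evs <- ev[ev$event_type == event_type & ev$occurrence_index == 1, ,
              drop = FALSE]
    etime <- evs$year_index[match(pats$patient_id, evs$patient_id)]
  }

  if (event_type == "DEATH") {
    time <- pmin(pats$censor_time, death_time, na.rm = TRUE)
    status <- ifelse(!is.na(death_time) & death_time <= pats$censor_time,
                     1L, 0L)
    f <- survival::survfit(
      survival::Surv(time, status) ~ 1, conf.type = "log-log",
      conf.int = conf_level)
    est <- 1 - f$surv
    lo <- 1 - f$upper
    hi <- 1 - f$lower
    times <- f$time[f$n.event > 0]
    est <- est[f$n.event > 0]; lo <- lo[f$n.event > 0]; hi <- hi[f$n.event > 0]
  } else {
    # first occurrence of the event, with death as the competing risk.
    # Events are recorded on the annual-cycle grid while deaths are
    # fractional: a death in the same cycle as an event does not pre-empt
    # it (events occur at the start of the year, death mid-year).
    has_event <- !is.na(etime)
    death_cyc <- ceiling(death_time - 1e-9)
    if (event_type == "ANY_EVENT") {
      event_wins <- has_event & (is.na(death_time) | etime <= death_cyc)
      death_first <- !is.na(death_time) & !event_wins
      time <- ifelse(event_wins, etime,
                     ifelse(death_first, death_time, pats$censor_time))
      status <- factor(ifelse(event_wins | death_first, "event", "censor"),
                       levels = c("censor", "event", "death"))
    } else {
      event_wins <- has_event & (is.na(death_time) | etime <= death_cyc)
      death_first <- !is.na(death_time) & !event_wins
      time <- ifelse(event_wins, etime,
                     ifelse(death_first, death_time, pats$censor_time))
      status <- factor(ifelse(event_wins, "event",
                              ifelse(death_first, "death", "censor")),
                       levels = c("censor", "event", "death"))
    }
    if (sum(status == "event") == 0) {
      warning("no on-study occurrences of ", event_type,
              " in the analysis subset; returning a flat zero curve")
      out <- data.frame(time = c(0, max(time)), estimate = 0, lo = 0, hi = 0)
      return(new_cif_curve(out, event_type, "observed", subset_rule,
                           nrow(pats)))
    }
    f <- survival::survfit(survival::Surv(time, status) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
    j <- match("event", f$states)
    keep <- f$n.event[, j] > 0
    times <- f$time[keep]
    est <- f$pstate[keep, j]
    lo <- f$lower[keep, j]
    hi <- f$upper[keep, j]
  }
  out <- rbind(data.frame(time = 0, estimate = 0, lo = 0, hi = 0),
               data.frame(time = times, estimate = est, lo = lo, hi = hi))
  new_cif_curve(out, event_type, "observed", subset_rule, nrow(pats))
}

new_cif_curve <- function(df, event, source, subset_rule = "all", n = NA) {
  structure(df, class = c("qv_cif_curve", "data.frame"),
            event = event, source = source, subset_rule = subset_rule, n = n)
}

#' Predicted cumulative incidence from simulated event counts
#'
#' Converts per-cycle cumulative predicted event counts into a predicted
#' cumulative incidence curve: cumulative events divided by the number of
#' individuals at the start of simulation, stepping at annual cycle
#' boundaries.
#'
#' @param cum_events Numeric vector of cumulative predicted events at
#'   cycles `1..H` (already summed/averaged over loops and patients).
#' @param n_at_start Number of individuals at the start of simulation
#'   (use 1 if `cum_events` is already a per-individual mean).
#' @param event Event label attached to the curve.
#' @return A `qv_cif_curve` with `source = "predicted"` (no CI).
#' @export
predicted_cif <- function(cum_events, n_at_start = 1, event = "event") {
  if (n_at_start <= 0) stop("n_at_start must be > 0", call. = FALSE)
  est <- as.numeric(cum_events) / n_at_start
  if (any(diff(est) < -1e-12)) {
    stop("cumulative event counts must be non-decreasing", call. = FALSE)
  }
  out <- data.frame(time = c(0, seq_along(est)), estimate = c(0, est),
                    lo = NA_real_, hi = NA_real_)
  new_cif_curve(out, event, "predicted", "all", n_at_start)
}

step_interp <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "constant", rule = 2,
                f = 0, ties = "ordered")$y
}

#' Compare observed and predicted cumulative incidence curves
#'
#' Aligns an observed (Aalen–Johansen, fractional times) and a predicted
#' (annual-step) curve on the annual cycle grid, interpolating the observed
#' step function onto cycle boundaries, and flags at each grid time whether
#' the predicted estimate lies within the observed confidence interval.
#'
#' @param observed,predicted `qv_cif_curve` objects for the same event.
#' @return A list of class `qv_cif_comparison`: `table` (grid data frame
#'   with `time`, `observed`, `lo`, `hi`, `predicted`, `in_ci`) and
#'   `fraction_in_ci`.
#' @export
compare_curves <- function(observed, predicted) {
  stopifnot(inherits(observed, "qv_cif_curve"),
            inherits(predicted, "qv_cif_curve"))
  if (!identical(attr(observed, "event"), attr(predicted, "event"))) {
    stop("curves are for different events: ", attr(observed, "event"),
         " vs ", attr(predicted, "event"), call. = FALSE)
  }
  grid <- predicted$time[predicted$time > 0]
  grid <- grid[grid <= max(observed$time)]
  if (length(grid) == 0) {
    stop("no overlap between predicted grid and observed follow-up",
         call. = FALSE)
  }
  obs <- step_interp(observed$time, observed$estimate, grid)
  lo <- step_interp(observed$time, observed$lo, grid)
  hi <- step_interp(observed$time, observed$hi, grid)
  pred <- step_interp(predicted$time, predicted$estimate, grid)
  in_ci <- pred >= lo & pred <= hi
  structure(list(table = data.frame(time = grid, observed = obs,
                                    lo = lo, hi = hi, predicted = pred,
                                    in_ci = in_ci),
                 fraction_in_ci = mean(in_ci),
                 event = attr(observed, "event")),
            class = "qv_cif_comparison")
}

#' Tidy a set of CIF curves for export
#'
#' @param curves List of `qv_cif_curve` objects.
#' @return A tidy data frame: `event`, `source`, `subset_rule`, `time`,
#'   `estimate`, `lo`, `hi`.
#' @export
cif_to_table <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(event = attr(cv, "event"), source = attr(cv, "source"),
               subset_rule = attr(cv, "subset_rule"),
               time = cv$time, estimate = cv$estimate,
               lo = cv$lo, hi = cv$hi)
  }))
}

#' Plot an observed-vs-predicted CIF comparison
#'
#' @param x A `qv_cif_comparison`.
#' @param ... Unused.
#' @return A ggplot object (requires ggplot2).
#' @export
plot.qv_cif_comparison <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- x$table
  ggplot2::ggplot(d, ggplot2::aes(x = time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi), alpha = 0.2) +
    ggplot2::geom_step(ggplot2::aes(y = observed)) +
    ggplot2::geom_step(ggplot2::aes(y = predicted), colour = "red") +
    ggplot2::labs(x = "Years since randomization",
                  y = "Cumulative incidence",
                  title = x$event) +
    ggplot2::theme_minimal()
}

#' @export
print.qv_cif_curve <- function(x, ...) {
  cat(attr(x, "source"), "cumulative incidence of", attr(x, "event"),
      "(subset:", attr(x, "subset_rule"), ", n =", attr(x, "n"), ")\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
print.qv_cif_comparison <- function(x, ...) {
  cat("CIF comparison for", x$event, "- fraction of grid times in CI:",
      round(x$fraction_in_ci, 3), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
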