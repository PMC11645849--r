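#' QALY accounting options
#'
#' Options controlling how annual utility traces are turned into QALYs.
#' The defaults reproduce the base-case accounting: no discounting, full
#' follow-up horizon, censor-year accrual proportional to the fraction of
#' the year on study, and occurrence counting in which second MI, stroke
#' and amputation carry the same decrement as the first (counting any
#' pre-baseline occurrence) while third occurrences and second ulcers carry
#' none.
#'
#' @param discount_rate Annual discount rate (fraction, >= 0). Cycle `t`
#'   is discounted by `1/(1+r)^(t-1)`: the first year is undiscounted,
#'   consistent with events occurring at the start of each year.
#' @param horizon_years Truncate accounting after this many annual cycles
#'   (`NULL` = full follow-up).
#' @param exclude_censor_year Drop the accrual term of the annual cycle in
#'   which the patient is censored.
#' @param life_years_mode Fix utility at 1, so the output is (discounted)
#'   life-years rather than QALYs.
#' @param second_event_rule Occurrence-counting rule; see Details.
#'
#' @details
#' Occurrence-counting rules, applied when deciding whether the k-th
#' occurrence of an event carries a decrement:
#' \describe{
#'   \item{`default`}{Occurrences are counted including any pre-baseline
#'     history flag; an occurrence carries a decrement only while the
#'     running count is within the table's `max_counted` (2 for MI, stroke,
#'     amputation; 1 otherwise).}
#'   \item{`count_all_since_randomization`}{Prior history is ignored and up
#'     to two occurrences since randomization of MI, stroke, amputation,
#'     blindness and ulcer carry decrements.}
#'   \item{`exclude_second_events`}{As default, but second MI, stroke and
#'     amputation carry no decrement.}
#'   \item{`exclude_second_events_and_ulcer`}{As above, and ulcer carries no
#'     decrement at all.}
#' }
#'
#' @return An object of class `qv_qaly_options`.
#' @export
qaly_options <- function(discount_rate = 0, horizon_years = NULL,
                         exclude_censor_year = FALSE,
                         life_years_mode = FALSE,
                         second_event_rule = c(
                           "default", "count_all_since_randomization",
                           "exclude_second_events",
                           "exclude_second_events_and_ulcer")) {
  second_event_rule <- match.arg(second_event_rule)
  if (discount_rate < 0) stop("discount_rate must be >= 0", call. = FALSE)
  if (!is.null(horizon_years)) {
    horizon_years <- as.integer(horizon_years)
    if (horizon_years < 1) stop("horizon_years must be >= 1", call. = FALSE)
  }
  structure(list(discount_rate = discount_rate,
                 horizon_years = horizon_years,
                 exclude_censor_year = isTRUE(exclude_censor_year),
                 life_years_mode = isTRUE(life_years_mode),
                 second_event_rule = second_event_rule),
            class = "qv_qaly_options")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Effective counting parameters per event type for a given rule:
# an occurrence carries a decrement iff offset + running count <= max_eff,
# where offset is 1 when the pre-baseline history flag counts.
second_event_params <- function(table, rule, prior) {
  ev <- event_types()
  offset <- stats::setNames(as.integer(prior[ev]), ev)
  max_eff <- as.numeric(table$max_counted[ev])
  names(max_eff) <- ev
  if (rule == "count_all_since_randomization") {
    offset[] <- 0L
    bump <- c("MI", "STROKE", "AMPUTATION", "BLINDNESS", "ULCER")
    max_eff[bump] <- pmax(max_eff[bump], 2)
  } else if (rule == "exclude_second_events") {
    max_eff[recurrent_event_types()] <- pmin(max_eff[recurrent_event_types()], 1)
  } else if (rule == "exclude_second_events_and_ulcer") {
    max_eff[recurrent_event_types()] <- pmin(max_eff[recurrent_event_types()], 1)
    max_eff["ULCER"] <- 0
  }
  list(offset = offset, max_eff = max_eff)
}

# Split a (possibly fractional) follow-up time into annual cycles:
# number of cycles, index of the censor cycle and its fractional weight.
split_censor_time <- function(C) {
  if (abs(C - round(C)) < 1e-9) {
    Cc <- as.integer(round(C)); frac <- 0
  } else {
    Cc <- as.integer(ceiling(C)); frac <- C - floor(C)
  }
  list(cycles = Cc, frac = frac)
}

# Vectorised accounting kernel shared by trial QALYs, model QALYs and the
# microsimulation engine. Operates on n parallel histories over annual
# cycles:
#   occ          named list over event types of n x H matrices of new
#                occurrences (0/1)
#   death_cycle  integer vector length n; NA = no death
#   censor_end   scalar end of accounting absent death (fractional years)
# Weights: 1 for complete years, the fractional part of censor_end in the
# censor year, 0.5 in the death year (half-cycle correction), 0 after.
# A death is effective when its cycle falls in or before the censor cycle.
qaly_kernel <- function(occ, death_cycle, prior, table, options, censor_end) {
  n <- length(death_cycle)
  cs <- split_censor_time(censor_end)
  Cc <- cs$cycles; frac <- cs$frac
  H <- max(1L, Cc)

  w <- numeric(H)
  full_years <- Cc - (frac > 0)
  if (full_years > 0) w[seq_len(full_years)] <- 1
  if (frac > 0) w[Cc] <- frac
  W <- matrix(w, n, H, byrow = TRUE)

  eff_death <- !is.na(death_cycle) & death_cycle <= Cc
  if (any(eff_death)) {
    D <- death_cycle[eff_death]
    Tm <- matrix(seq_len(H), sum(eff_death), H, byrow = TRUE)
    W[eff_death, ] <- (Tm < D) + 0.5 * (Tm == D)
  }

  U <- matrix(table$baseline_utility, n, H)
  pars <- second_event_params(table, options$second_event_rule, prior)
  cum_mat <- upper.tri(diag(H), diag = TRUE) * 1  # O %*% cum_mat = row cumsum
  for (e in names(occ)) {
    O <- occ[[e]]
    if (is.null(O) || !any(O > 0)) next
    if (ncol(O) < H) O <- cbind(O, matrix(0L, n, H - ncol(O)))
    O <- O[, seq_len(H), drop = FALSE]
    d <- table$decrements[[e]]
    if (d$event_year == 0 && d$subsequent == 0) next
    cumO <- O %*% cum_mat
    counted <- O * ((pars$offset[[e]] + cumO) <= pars$max_eff[[e]])
    cum_counted <- counted %*% cum_mat
    U <- U - d$event_year * counted - d$subsequent * (cum_counted - counted)
  }

  list(utilities = U, weights = W, H = H, censor_cycle = Cc,
       eff_death = eff_death)
}

# Reduce kernel output to per-history QALYs under the remaining options
# (life-years mode, censor-year exclusion, horizon, discounting).
kernel_qalys <- function(k, options) {
  U <- if (options$life_years_mode) 1 else k$utilities
  W <- k$weights
  if (options$exclude_censor_year && k$censor_cycle >= 1 &&
      k$censor_cycle <= k$H) {
    W[, k$censor_cycle] <- 0
  }
  Hh <- min(k$H, options$horizon_years %||% k$H)
  disc <- (1 + options$discount_rate)^-(seq_len(Hh) - 1)
  UW <- (U * W)[, seq_len(Hh), drop = FALSE]
  as.vector(UW %*% disc)
}

# Build n x H occurrence matrices from a long events table.
events_to_occ <- function(events, n_index, H, n) {
  occ <- stats::setNames(vector("list", length(event_types())), event_types())
  if (is.null(events) || nrow(events) == 0) return(occ)
  keep <- events$year_index <= H
  events <- events[keep, , drop = FALSE]
  n_index <- n_index[keep]
  for (e in unique(events$event_type)) {
    O <- matrix(0L, n, H)
    sel <- events$event_type == e
    O[cbind(n_index[sel], events$year_index[sel])] <- 1L
    occ[[e]] <- O
  }
  occ
}

#' Build the annual utility trace for one patient
#'
#' Converts a patient's observed event history and follow-up into a
#' per-cycle utility trace with accrual weights: utility in cycle `t` is
#' the baseline utility minus the decrements of all counted event
#' occurrences active in that cycle (event-year decrement in the cycle of
#' occurrence, subsequent-years decrement afterwards); weights are 1 for
#' complete years, 0.5 in the death year, and the fractional part of the
#' censoring time in the censor year. Utilities may go negative: decrements
#' are additive with no floor.
#'
#' @param record A [patient_record()].
#' @param table A [utility_table()].
#' @param options [qaly_options()]; only the occurrence-counting rule
#'   affects the trace itself.
#' @return An object of class `qv_utility_trace` with fields `utilities`,
#'   `weights`, `death_cycle`, `censor_cycle`.
#' @export
#' @examples
#' p <- patient_record("p1", 60, 0, 10, censor_time = 2,
#'                     events = data.frame(event_type = "MI",
#'                                         occurrence_index = 1,
#'                                         year_index = 1))
#' build_utility_trace(p, default_utility_table(), qaly_options())
build_utility_trace <- function(record, table, options = qaly_options()) {
  stopifnot(inherits(record, "qv_patient"), inherits(table, "qv_utility_table"))
  died <- patient_died(record)
  death_cycle <- if (died) as.integer(ceiling(record$death_time - 1e-9)) else NA_integer_
  if (died && death_cycle < 1L) death_cycle <- 1L
  cs <- split_censor_time(record$censor_time)
  H <- max(1L, cs$cycles)
  occ <- events_to_occ(record$events,
                       n_index = rep(1L, nrow(record$events)),
                       H = H, n = 1L)
  k <- qaly_kernel(occ, death_cycle, record$prior, table, options,
                   censor_end = record$censor_time)
  # present the trace up to the last accounted cycle
  Hp <- if (died) max(1L, death_cycle) else k$H
  structure(list(utilities = as.vector(k$utilities[1, seq_len(Hp)]),
                 weights = as.vector(k$weights[1, seq_len(Hp)]),
                 death_cycle = death_cycle,
                 censor_cycle = k$censor_cycle),
            class = "qv_utility_trace")
}

#' Total (discounted) QALYs from a utility trace
#'
#' Sums `utilities[t] * weights[t] / (1 + r)^(t-1)` over annual cycles,
#' optionally truncated at a horizon, with the censor-year term dropped
#' (`exclude_censor_year`) or utilities fixed at 1 (`life_years_mode`).
#'
#' @param trace A `qv_utility_trace`, or any list with numeric `utilities`
#'   and `weights` of equal length (optionally `censor_cycle`).
#' @param options [qaly_options()].
#' @return Total QALYs (scalar, QALY-years).
#' @export
qalys_from_trace <- function(trace, options = qaly_options()) {
  u <- as.numeric(trace$utilities)
  w <- as.numeric(trace$weights)
  if (length(u) != length(w)) {
    stop("utilities and weights must have equal length", call. = FALSE)
  }
  if (options$life_years_mode) u <- rep(1, length(u))
  cc <- trace$censor_cycle
  if (options$exclude_censor_year && !is.null(cc) && !is.na(cc) &&
      cc >= 1 && cc <= length(w)) {
    w[cc] <- 0
  }
  H <- min(length(u), options$horizon_years %||% length(u))
  if (H < 1) return(0)
  disc <- (1 + options$discount_rate)^-(seq_len(H) - 1)
  sum(u[seq_len(H)] * w[seq_len(H)] * disc)
}

#' Trial QALYs for one patient
#'
#' QALYs implied by the patient's observed events and survival under the
#' utility table's assumptions: events at the start of the year, death
#' halfway through the year (half-cycle correction), the censor year
#' weighted by the fraction of the year on study.
#'
#' @inheritParams build_utility_trace
#' @param options [qaly_options()].
#' @return Total trial QALYs (scalar).
#' @export
#' @examples
#' p <- patient_record("p1", 60, 0, 10, censor_time = 2.5)
#' trial_qalys(p, default_utility_table())  # 0.807 * (1 + 1 + 0.5)
trial_qalys <- function(record, table, options = qaly_options()) {
  qalys_from_trace(build_utility_trace(record, table, options), options)
}

#' Model QALYs for one patient from simulated loop histories
#'
#' Applies the same accounting rules to each simulated loop and averages.
#' Accounting is truncated at the patient's censoring time — for patients
#' who died on study, at the administrative end time, the follow-up they
#' would have had absent death. Loops in which the simulated patient dies
#' in or before the censor year contribute the half-cycle-weighted utility
#' for the death year; surviving loops contribute the fraction-of-year
#' weighted utility in the censor year.
#'
#' @param loop_histories List of loops, each a list with components
#'   `events` (data frame: `event_type`, `occurrence_index`, `year_index`)
#'   and `death_cycle` (integer or `NA`).
#' @inheritParams trial_qalys
#' @return Mean QALYs over loops (scalar).
#' @export
model_qalys <- function(loop_histories, record, table,
                        options = qaly_options()) {
  if (length(loop_histories) == 0) {
    stop("at least one loop history is required", call. = FALSE)
  }
  n <- length(loop_histories)
  censor_end <- if (patient_died(record)) record$administrative_end_time
                else record$censor_time
  cs <- split_censor_time(censor_end)
  H <- max(1L, cs$cycles)
  ev_list <- lapply(seq_len(n), function(i) {
    ev <- loop_histories[[i]]$events
    if (is.null(ev) || nrow(ev) == 0) return(NULL)
    ev$.loop <- i
    ev
  })
  events <- do.call(rbind, ev_list)
  occ <- if (is.null(events)) {
    stats::setNames(vector("list", length(event_types())), event_types())
  } else {
    events_to_occ(events, n_index = events$.loop, H = H, n = n)
  }
  death_cycle <- vapply(loop_histories, function(l) {
    dc <- l$death_cycle
    if (is.null(dc) || is.na(dc)) NA_integer_ else as.integer(dc)
  }, integer(1))
  k <- qaly_kernel(occ, death_cycle, record$prior, table, options, censor_end)
  mean(kernel_qalys(k, options))
}

#' @export
print.qv_utility_trace <- function(x, ...) {
  d <- data.frame(cycle = seq_along(x$utilities),
                  utility = x$utilities, weight = x$weights)
  print(d, row.names = FALSE)
  invisible(x)
}
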