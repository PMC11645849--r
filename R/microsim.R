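#' Simulation configuration
#'
#' @param n_loops Number of Monte Carlo loops per patient (>= 1). The
#'   default of 50,000 is the loop count at which per-patient means are
#'   well converged; validation runs on large cohorts typically use fewer.
#' @param seed Master seed. Every random draw in the engine derives from
#'   it; identical (seed, config, inputs) reproduce every output bit for
#'   bit.
#' @param horizon_years Simulation horizon in annual cycles (default 7).
#' @return An object of class `qv_sim_config`.
#' @export
sim_config <- function(n_loops = 50000, seed = 1L, horizon_years = 7L) {
  n_loops <- as.integer(n_loops)
  horizon_years <- as.integer(horizon_years)
  if (n_loops < 1) stop("n_loops must be >= 1", call. = FALSE)
  if (horizon_years < 1) stop("horizon_years must be >= 1", call. = FALSE)
  structure(list(n_loops = n_loops, seed = as.integer(seed),
                 horizon_years = horizon_years),
            class = "qv_sim_config")
}

# Deterministic per-patient substream seed: changing the number of loops
# or the set of other patients never reshuffles a given patient's draws.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483629 + 1000003 * index) %% 2147483629)
}

# Vectorised annual-cycle simulation of n_loops parallel histories for one
# patient. Within-year policy: all event draws use start-of-year state
# (simultaneous draws); the death draw follows the event draws and may
# reference same-cycle events via new_<EVENT>; history updates at year end;
# no transitions after death.
#
# Returns occ (named list of n x H 0/1 matrices), death_cycle (int, NA if
# none within the horizon).
sim_patient_core <- function(record, eqs, config) {
  n <- config$n_loops
  H <- config$horizon_years
  ev_present <- intersect(event_types(), names(eqs$equations))
  has_death <- "DEATH" %in% names(eqs$equations)

  base <- list(age = record$age, female = record$female,
               diabetes_duration = record$diabetes_duration)
  if (!is.null(record$covariates)) {
    base <- c(base, as.list(record$covariates))
  }
  prior <- as.integer(record$prior[event_types()])
  names(prior) <- event_types()
  max_occ <- vapply(ev_present, function(e) {
    if (isTRUE(eqs$equations[[e]]$second_event)) 2L else 1L
  }, integer(1))

  occ <- stats::setNames(
    lapply(ev_present, function(e) matrix(0L, n, H)), ev_present)
  counts <- matrix(0L, n, length(ev_present),
                   dimnames = list(NULL, ev_present))
  alive <- rep(TRUE, n)
  death_cycle <- rep(NA_integer_, n)

  for (t in seq_len(H)) {
    if (!any(alive)) break
    new_draws <- stats::setNames(
      lapply(ev_present, function(e) logical(n)), ev_present)
    make_resolve <- function(new_ok) {
      function(nm) {
        if (!is.null(base[[nm]])) return(base[[nm]])
        if (nm == "age_current") return(record$age + t - 1)
        if (nm == "diabetes_duration_current") {
          return(record$diabetes_duration + t - 1)
        }
        if (nm == "year") return(t)
        if (startsWith(nm, "hist_")) {
          e <- sub("^hist_", "", nm)
          assert_event_types(e)
          cnt <- prior[[e]] + (if (e %in% ev_present) counts[, e] else 0L)
          return(as.numeric(cnt >= 1))
        }
        if (startsWith(nm, "count_")) {
          e <- sub("^count_", "", nm)
          assert_event_types(e)
          return(prior[[e]] + (if (e %in% ev_present) counts[, e] else 0L))
        }
        if (new_ok && startsWith(nm, "new_")) {
          e <- sub("^new_", "", nm)
          assert_event_types(e)
          return(as.numeric(if (e %in% ev_present) new_draws[[e]] else 0))
        }
        stop("equation requires covariate '", nm,
             "' not available in the simulated state", call. = FALSE)
      }
    }
    resolve_events <- make_resolve(new_ok = FALSE)
    for (e in ev_present) {
      p <- equation_prob(eqs$equations[[e]], resolve_events)
      u <- stats::runif(n)
      eligible <- alive & (prior[[e]] + counts[, e] < max_occ[[e]])
      hit <- eligible & (u < p)
      if (any(hit)) {
        occ[[e]][hit, t] <- 1L
        new_draws[[e]] <- hit
      }
    }
    if (has_death) {
      p <- equation_prob(eqs$equations[["DEATH"]], make_resolve(new_ok = TRUE))
      u <- stats::runif(n)
      dying <- alive & (u < p)
      if (any(dying)) {
        death_cycle[dying] <- t
        alive[dying] <- FALSE
      }
    }
    for (e in ev_present) {
      if (any(new_draws[[e]])) {
        counts[, e] <- counts[, e] + as.integer(new_draws[[e]])
      }
    }
  }
  list(occ = occ, death_cycle = death_cycle)
}

#' Simulate a single Monte Carlo loop for one patient
#'
#' One stochastic realisation of the patient's event/death trajectory over
#' the simulation horizon, with its full-horizon utility trace, QALYs and
#' life-years. Within each annual cycle, all eligible events are drawn
#' independently from start-of-year state, then death is drawn (events in
#' the death cycle still apply before the half-year death weight), then
#' history is updated.
#'
#' @param record A [patient_record()].
#' @param eqs A [risk_equation_set()].
#' @param table A [utility_table()].
#' @param config A [sim_config()]; `n_loops` is ignored (one loop),
#'   `seed` determines the draw.
#' @param options [qaly_options()] for the loop's QALY accrual.
#' @return A list of class `qv_loop_outcome` with `events` (data frame),
#'   `death_cycle` (integer or `NA`), `trace` (`qv_utility_trace` over the
#'   full horizon), `qalys` and `life_years`.
#' @export
simulate_loop <- function(record, eqs, table, config = sim_config(),
                          options = qaly_options()) {
  cfg1 <- config
  cfg1$n_loops <- 1L
  set.seed(cfg1$seed)
  core <- sim_patient_core(record, eqs, cfg1)
  H <- cfg1$horizon_years
  ev_rows <- list()
  for (e in names(core$occ)) {
    cyc <- which(core$occ[[e]][1, ] == 1L)
    if (length(cyc) > 0) {
      ev_rows[[e]] <- data.frame(event_type = e,
                                 occurrence_index = seq_along(cyc),
                                 year_index = cyc)
    }
  }
  events <- if (length(ev_rows) > 0) {
    ev <- do.call(rbind, ev_rows)
    rownames(ev) <- NULL
    ev[order(ev$year_index, ev$event_type), , drop = FALSE]
  } else {
    data.frame(event_type = character(), occurrence_index = integer(),
               year_index = integer())
  }
  k <- qaly_kernel(core$occ, core$death_cycle, record$prior, table, options,
                   censor_end = H)
  trace <- structure(list(utilities = as.vector(k$utilities[1, ]),
                          weights = as.vector(k$weights[1, ]),
                          death_cycle = core$death_cycle[1],
                          censor_cycle = k$censor_cycle),
                     class = "qv_utility_trace")
  lyopt <- options; lyopt$life_years_mode <- TRUE
  structure(list(events = events, death_cycle = core$death_cycle[1],
                 trace = trace,
                 qalys = kernel_qalys(k, options)[1],
                 life_years = kernel_qalys(k, lyopt)[1]),
            class = "qv_loop_outcome")
}

# Per-cycle mean cumulative incidence bookkeeping from a simulated core:
# all occurrences, first in-simulation occurrences, death and the first-of-
# any-event (including death) composite, each as mean cumulative counts per
# starting individual.
core_cum_incidence <- function(core, H, n) {
  cum_mat <- upper.tri(diag(H), diag = TRUE) * 1
  rows <- list()
  any_first <- rep(NA_integer_, n)
  for (e in names(core$occ)) {
    O <- core$occ[[e]]
    cumO <- O %*% cum_mat
    first <- O * (cumO == 1)
    rows[[e]] <- data.frame(
      event = e, cycle = seq_len(H),
      mean_cum_events = colMeans(cumO),
      mean_cum_first = colMeans(first %*% cum_mat))
    has <- rowSums(O) > 0
    fe <- rep(NA_integer_, n)
    if (any(has)) {
      fe[has] <- max.col(O[has, , drop = FALSE] == 1L, ties.method = "first")
    }
    any_first <- pmin(any_first, fe, na.rm = TRUE)
  }
  dc <- core$death_cycle
  death_cum <- vapply(seq_len(H), function(t) mean(!is.na(dc) & dc <= t),
                      numeric(1))
  rows[["DEATH"]] <- data.frame(event = "DEATH", cycle = seq_len(H),
                                mean_cum_events = death_cum,
                                mean_cum_first = death_cum)
  any_first <- pmin(any_first, dc, na.rm = TRUE)
  any_cum <- vapply(seq_len(H), function(t)
    mean(!is.na(any_first) & any_first <= t), numeric(1))
  rows[["ANY_EVENT"]] <- data.frame(event = "ANY_EVENT", cycle = seq_len(H),
                                    mean_cum_events = any_cum,
                                    mean_cum_first = any_cum)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monte Carlo model predictions for one patient
#'
#' Simulates `n_loops` independent trajectories and averages: mean model
#' QALYs and life-years (truncated at the patient's censoring time — the
#' administrative end time for patients who died on study — with the
#' per-loop censor-year death adjustment of [model_qalys()]), plus
#' per-cycle mean cumulative event counts over the full simulation horizon.
#'
#' @inheritParams simulate_loop
#' @param options A single [qaly_options()] or a named list of option sets;
#'   QALY and life-year means are returned per set.
#' @return A list of class `qv_patient_sim`: `mean_qalys`,
#'   `mean_life_years` (named vectors over option sets), `cum_incidence`
#'   (data frame: event, cycle, mean_cum_events, mean_cum_first) and `n_loops`.
#' @export
run_patient <- function(record, eqs, table, config = sim_config(),
                        options = qaly_options()) {
  single <- inherits(options, "qv_qaly_options")
  option_sets <- if (single) list(base = options) else options
  set.seed(config$seed)
  core <- sim_patient_core(record, eqs, config)
  censor_end <- min(if (patient_died(record)) record$administrative_end_time
                    else record$censor_time,
                    config$horizon_years)
  mean_q <- mean_ly <- stats::setNames(numeric(length(option_sets)),
                                       names(option_sets))
  for (nm in names(option_sets)) {
    opt <- option_sets[[nm]]
    k <- qaly_kernel(core$occ, core$death_cycle, record$prior, table, opt,
                     censor_end = censor_end)
    mean_q[nm] <- mean(kernel_qalys(k, opt))
    lyopt <- opt; lyopt$life_years_mode <- TRUE
    mean_ly[nm] <- mean(kernel_qalys(k, lyopt))
  }
  structure(list(mean_qalys = if (single) unname(mean_q["base"]) else mean_q,
                 mean_life_years = if (single) unname(mean_ly["base"]) else mean_ly,
                 cum_incidence = core_cum_incidence(core,
                                                    config$horizon_years,
                                                    config$n_loops),
                 n_loops = config$n_loops),
            class = "qv_patient_sim")
}

#' Monte Carlo convergence diagnostic
#'
#' Runs the largest requested loop count once and reports the running mean
#' QALYs and life-years at each grid point, with a batch standard error.
#' Convergence at a grid point is declared when the running mean moved by
#' less than `tol` from the previous grid point.
#'
#' @inheritParams simulate_loop
#' @param loop_grid Ascending integer vector of loop counts.
#' @param tol Convergence tolerance on successive running means (QALYs).
#' @return Data frame: `n_loops`, `running_mean_qalys`,
#'   `running_mean_life_years`, `se_qalys`, `converged`.
#' @export
convergence_diagnostic <- function(record, eqs, table,
                                   loop_grid = c(1000, 5000, 10000, 25000, 50000),
                                   config = sim_config(), tol = 0.01,
                                   options = qaly_options()) {
  loop_grid <- sort(as.integer(loop_grid))
  cfg <- config
  cfg$n_loops <- max(loop_grid)
  set.seed(cfg$seed)
  core <- sim_patient_core(record, eqs, cfg)
  censor_end <- min(if (patient_died(record)) record$administrative_end_time
                    else record$censor_time,
                    cfg$horizon_years)
  k <- qaly_kernel(core$occ, core$death_cycle, record$prior, table, options,
                   censor_end = censor_end)
  q <- kernel_qalys(k, options)
  lyopt <- options; lyopt$life_years_mode <- TRUE
  ly <- kernel_qalys(k, lyopt)
  cq <- cumsum(q); cly <- cumsum(ly)
  rm_q <- cq[loop_grid] / loop_grid
  rm_ly <- cly[loop_grid] / loop_grid
  se <- vapply(loop_grid, function(m) stats::sd(q[seq_len(m)]) / sqrt(m),
               numeric(1))
  conv <- c(NA, abs(diff(rm_q)) < tol)
  data.frame(n_loops = loop_grid, running_mean_qalys = rm_q,
             running_mean_life_years = rm_ly, se_qalys = se,
             converged = conv)
}

#' @export
print.qv_patient_sim <- function(x, ...) {
  cat("Patient simulation over", x$n_loops, "loops\n")
  cat("  mean QALYs:     ", paste(round(x$mean_qalys, 4), collapse = " "), "\n")
  cat("  mean life-years:", paste(round(x$mean_life_years, 4), collapse = " "), "\n")
  invisible(x)
}
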