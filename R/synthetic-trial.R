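#' Cohort specification for the synthetic trial generator
#'
#' Describes the baseline joint distribution of a synthetic cardiovascular
#' outcome trial cohort in type 2 diabetes: about three quarters with prior
#' cardiovascular events and diabetes diagnosed a median of 12 years before
#' randomization. The exact covariate joint distribution of any real trial
#' is not public; the defaults here are plausible placeholders chosen once
#' and documented, not estimates.
#'
#' @param n_patients Cohort size (>= 1).
#' @param age_mean,age_sd,age_range Baseline age: normal, truncated to
#'   `age_range`.
#' @param female_frac Fraction female.
#' @param prior_cvd_frac Fraction with prior cardiovascular events (any of
#'   MI, IHD, stroke); default 0.73.
#' @param diab_dur_meanlog,diab_dur_sdlog Log-normal diabetes duration;
#'   defaults give a median of 12 years.
#' @param cvd_cond_prev Named conditional prevalences of prior MI, IHD and
#'   stroke among patients with prior cardiovascular events (at least one
#'   is guaranteed per such patient).
#' @param other_prev Named prevalences of pre-baseline history for the
#'   non-cardiovascular events.
#' @return An object of class `qv_cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        age_mean = 62, age_sd = 8, age_range = c(40, 86),
                        female_frac = 0.38,
                        prior_cvd_frac = 0.73,
                        diab_dur_meanlog = log(12), diab_dur_sdlog = 0.6,
                        cvd_cond_prev = c(MI = 0.45, IHD = 0.60, STROKE = 0.23),
                        other_prev = c(CHF = 0.16, BLINDNESS = 0.02,
                                       AMPUTATION = 0.02,
                                       RENAL_FAILURE = 0.03, ULCER = 0.03)) {
  stopifnot(n_patients >= 1)
  fracs <- c(female_frac, prior_cvd_frac, cvd_cond_prev, other_prev)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (all(cvd_cond_prev == 0) && prior_cvd_frac > 0) {
    stop("cvd_cond_prev cannot be all zero when prior_cvd_frac > 0",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 female_frac = female_frac, prior_cvd_frac = prior_cvd_frac,
                 diab_dur_meanlog = diab_dur_meanlog,
                 diab_dur_sdlog = diab_dur_sdlog,
                 cvd_cond_prev = cvd_cond_prev, other_prev = other_prev),
            class = "qv_cohort_spec")
}

#' Follow-up specification for the synthetic trial generator
#'
#' Follow-up mimics a staggered-entry outcome trial with administrative
#' censoring at a common calendar end date: per-patient administrative
#' follow-up is uniform over `entry_window`, truncated at `max_years`, and
#' patients may withdraw early with a constant annual probability. The
#' defaults are calibrated so that median on-study follow-up (including
#' deaths under the default truth process) is close to `target_median`.
#'
#' @param max_years Maximum follow-up (default 7).
#' @param target_median Target median follow-up (default 3.2); recorded for
#'   reference and checked by the package's tests, not enforced row-wise.
#' @param entry_window Range (years) of administrative follow-up times
#'   induced by staggered entry.
#' @param withdrawal_prob Constant annual probability of withdrawal.
#' @return An object of class `qv_followup_spec`.
#' @export
followup_spec <- function(max_years = 7, target_median = 3.2,
                          entry_window = c(0.5, 7),
                          withdrawal_prob = 0.025) {
  if (target_median <= 0 || target_median > max_years) {
    stop("target_median must be in (0, max_years]", call. = FALSE)
  }
  if (withdrawal_prob < 0 || withdrawal_prob >= 1) {
    stop("withdrawal_prob must be in [0, 1)", call. = FALSE)
  }
  structure(list(max_years = max_years, target_median = target_median,
                 entry_window = entry_window,
                 withdrawal_prob = withdrawal_prob),
            class = "qv_followup_spec")
}

#' Default "truth" risk equation set
#'
#' A plausible annual-probability model used as the data-generating truth
#' process of the synthetic trial (and as the self-validation candidate):
#' complementary log-log equations with age and history effects, annual
#' first-event probabilities of roughly 0.3–1.5% per event, second
#' occurrences of MI, stroke and amputation, and mortality around 2% per
#' year rising with age and after cardiovascular events.
#'
#' @return A `qv_risk_equations`.
#' @export
default_truth_equations <- function() {
  risk_equation_set(list(
    IHD = list(form = "cloglog",
               coefficients = c(intercept = -5.8, age_current = 0.02),
               second_event = FALSE),
    MI = list(form = "cloglog",
              coefficients = c(intercept = -6.0, age_current = 0.025,
                               hist_MI = 0.5, hist_STROKE = 0.3),
              second_event = TRUE),
    STROKE = list(form = "cloglog",
                  coefficients = c(intercept = -6.6, age_current = 0.03,
                                   hist_STROKE = 0.6, hist_MI = 0.3),
                  second_event = TRUE),
    CHF = list(form = "cloglog",
               coefficients = c(intercept = -6.4, age_current = 0.03,
                                hist_MI = 0.6),
               second_event = FALSE),
    BLINDNESS = list(form = "cloglog",
                     coefficients = c(intercept = -6.2, year = 0.02),
                     second_event = FALSE),
    AMPUTATION = list(form = "cloglog",
                      coefficients = c(intercept = -6.8, hist_ULCER = 1.0),
                      second_event = TRUE),
    RENAL_FAILURE = list(form = "cloglog",
                         coefficients = c(intercept = -6.6,
                                          diabetes_duration = 0.02),
                         second_event = FALSE),
    ULCER = list(form = "cloglog",
                 coefficients = c(intercept = -6.3,
                                  diabetes_duration = 0.015),
                 second_event = FALSE),
    DEATH = list(form = "cloglog",
                 coefficients = c(intercept = -6.7, age_current = 0.04,
                                  hist_MI = 0.5, hist_STROKE = 0.5,
                                  hist_CHF = 0.6, hist_RENAL_FAILURE = 0.8,
                                  new_MI = 0.8, new_STROKE = 0.8))
  ))
}

#' Generate a synthetic baseline cohort
#'
#' Draws a reproducible baseline table from a [cohort_spec()]: ages,
#' sex, diabetes duration and pre-baseline event history flags. Patients
#' flagged with prior cardiovascular events have at least one of prior MI,
#' IHD or stroke.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A patients data frame (no follow-up columns yet).
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "qv_cohort_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_patients
  age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                   spec$age_range[1]), spec$age_range[2])
  female <- as.integer(stats::runif(n) < spec$female_frac)
  dur <- stats::rlnorm(n, spec$diab_dur_meanlog, spec$diab_dur_sdlog)
  cvd <- stats::runif(n) < spec$prior_cvd_frac

  flags <- matrix(FALSE, n, length(event_types()),
                  dimnames = list(NULL, event_types()))
  cvd_ev <- c("MI", "IHD", "STROKE")
  todo <- which(cvd)
  while (length(todo) > 0) {
    draw <- matrix(stats::runif(3 * length(todo)), ncol = 3) <
      matrix(spec$cvd_cond_prev[cvd_ev], length(todo), 3, byrow = TRUE)
    flags[todo, cvd_ev] <- draw
    todo <- todo[rowSums(draw) == 0]  # redraw until at least one CVD flag
  }
  for (e in names(spec$other_prev)) {
    flags[, e] <- stats::runif(n) < spec$other_prev[[e]]
  }

  out <- data.frame(patient_id = sprintf("S%05d", seq_len(n)),
                    age = round(age, 1), female = female,
                    diabetes_duration = round(dur, 1),
                    stringsAsFactors = FALSE)
  for (e in event_types()) out[[paste0("prior_", e)]] <- flags[, e]
  out
}

#' Generate synthetic event histories and follow-up from a truth process
#'
#' Each patient receives exactly one realisation of the annual-cycle truth
#' process (a single microsimulation loop under `truth_eqs`), then
#' censoring is applied: follow-up ends at the earliest of death,
#' withdrawal and administrative study end. Censoring is independent of
#' the event process given covariates (non-informative). The
#' administrative end time is recorded for every patient, including
#' decedents, for use in model-QALY truncation.
#'
#' @param patients Baseline table from [generate_cohort()].
#' @param truth_eqs A [risk_equation_set()] acting as the truth process.
#' @param followup A [followup_spec()].
#' @param seed Integer seed.
#' @return A [trial_data()] object. Deaths are recorded at the midpoint of
#'   their annual cycle (the half-cycle convention); events carry their
#'   1-based cycle index.
#' @export
generate_truth_histories <- function(patients, truth_eqs,
                                     followup = followup_spec(), seed = 1L) {
  stopifnot(inherits(truth_eqs, "qv_risk_equations"),
            inherits(followup, "qv_followup_spec"))
  n <- nrow(patients)
  H <- as.integer(ceiling(followup$max_years))
  set.seed(as.integer(seed))
  admin <- stats::runif(n, followup$entry_window[1], followup$entry_window[2])
  admin <- pmin(admin, followup$max_years)
  w <- followup$withdrawal_prob
  withdraw <- if (w > 0) stats::rexp(n, rate = -log(1 - w)) else rep(Inf, n)
  censor <- pmin(admin, withdraw)

  patients$death_time <- NA_real_
  patients$censor_time <- censor
  patients$administrative_end_time <- admin

  prior_cols <- paste0("prior_", event_types())
  ev_list <- vector("list", n)
  for (i in seq_len(n)) {
    prior <- stats::setNames(as.logical(patients[i, prior_cols]),
                             event_types())
    rec <- patient_record(patients$patient_id[i], age = patients$age[i],
                          female = patients$female[i],
                          diabetes_duration = patients$diabetes_duration[i],
                          prior = prior, censor_time = censor[i],
                          administrative_end_time = admin[i])
    cfg <- sim_config(n_loops = 1, seed = derive_seed(seed, i),
                      horizon_years = H)
    set.seed(cfg$seed)
    core <- sim_patient_core(rec, truth_eqs, cfg)
    dth <- core$death_cycle[1]
    death_time <- if (!is.na(dth)) dth - 0.5 else NA_real_
    end <- min(censor[i], if (!is.na(death_time)) death_time else Inf)
    if (!is.na(death_time) && death_time <= censor[i]) {
      patients$death_time[i] <- death_time
    } else {
      death_time <- NA_real_
    }
    rows <- list()
    for (e in names(core$occ)) {
      cyc <- which(core$occ[[e]][1, ] == 1L)
      cyc <- cyc[cyc <= ceiling(end - 1e-9)]
      if (length(cyc) > 0) {
        rows[[e]] <- data.frame(patient_id = patients$patient_id[i],
                                event_type = e,
                                occurrence_index = seq_along(cyc),
                                year_index = cyc)
      }
    }
    if (length(rows) > 0) ev_list[[i]] <- do.call(rbind, rows)
  }
  events <- do.call(rbind, ev_list)
  if (is.null(events)) {
    events <- data.frame(patient_id = character(), event_type = character(),
                         occurrence_index = integer(), year_index = integer())
  }
  rownames(events) <- NULL
  trial_data(patients, events)
}

#' Generate a complete synthetic trial
#'
#' Convenience wrapper: [generate_cohort()] then
#' [generate_truth_histories()], with sub-seeds derived from one master
#' seed.
#'
#' @param n_patients Cohort size.
#' @param seed Master seed.
#' @param spec,followup,truth_eqs Component specifications (defaults used
#'   when `NULL`).
#' @return A `qv_trial`.
#' @export
generate_trial <- function(n_patients, seed = 1L, spec = NULL,
                           followup = followup_spec(),
                           truth_eqs = default_truth_equations()) {
  if (is.null(spec)) spec <- cohort_spec(n_patients)
  patients <- generate_cohort(spec, seed = derive_seed(seed, 1))
  generate_truth_histories(patients, truth_eqs, followup,
                           seed = derive_seed(seed, 2))
}

#' Write a self-contained synthetic fixture to disk
#'
#' Writes `patients.csv`, `events.csv`, `truth_eqs.yaml`, `utilities.yaml`
#' and a `manifest.yaml` recording the seed and generation parameters, so
#' the file set can be regenerated byte-identically and round-trips through
#' the package readers.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_patients,seed Passed to [generate_trial()].
#' @param table Utility table to include.
#' @param truth_eqs Truth equations to include.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(out_dir, n_patients = 50, seed = 20260101,
                          table = default_utility_table(),
                          truth_eqs = default_truth_equations()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trial <- generate_trial(n_patients, seed = seed, truth_eqs = truth_eqs)
  paths <- c(patients = file.path(out_dir, "patients.csv"),
             events = file.path(out_dir, "events.csv"),
             truth_eqs = file.path(out_dir, "truth_eqs.yaml"),
             utilities = file.path(out_dir, "utilities.yaml"),
             manifest = file.path(out_dir, "manifest.yaml"))
  write_trial_data(trial, paths[["patients"]], paths[["events"]])
  write_risk_equations(truth_eqs, paths[["truth_eqs"]])
  write_utility_table(table, paths[["utilities"]])
  yaml::write_yaml(list(generator = "qalyval::write_fixture",
                        n_patients = n_patients, seed = seed,
                        synthetic = TRUE,
                        note = paste("Fully synthetic data generated from",
                                     "the package's truth process; no real",
                                     "trial data.")),
                   paths[["manifest"]])
  invisible(paths)
}
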