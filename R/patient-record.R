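#' Construct a single patient record
#'
#' A patient record bundles the baseline covariates, pre-baseline event
#' history flags, observed in-trial events (annual cycles, 1-based), and the
#' follow-up bookkeeping needed for QALY accounting: the death time (if the
#' patient died on study), the censoring time, and the administrative end
#' time — the follow-up the patient would have had absent death, used to
#' truncate model predictions for decedents.
#'
#' @param patient_id Identifier (scalar).
#' @param age Age at randomization, years.
#' @param female 1 if female, 0 if male.
#' @param diabetes_duration Years since diabetes diagnosis at randomization.
#' @param prior Named logical vector over [event_types()]: pre-baseline
#'   history flags. Missing names default to `FALSE`.
#' @param events Data frame with columns `event_type`, `occurrence_index`
#'   (1-based, consecutive per event type) and `year_index` (1-based annual
#'   cycle of occurrence). May have zero rows.
#' @param death_time Years from randomization to death, or `NA` if the
#'   patient did not die on study.
#' @param censor_time Years from randomization to censoring (fractional
#'   years allowed).
#' @param administrative_end_time Years from randomization to the
#'   administrative study end for this patient. Defaults to `censor_time`.
#' @param covariates Optional named numeric vector of extra baseline
#'   covariates made available to risk equations.
#'
#' @return An object of class `qv_patient`.
#' @export
#' @examples
#' patient_record("p1", age = 62, female = 0, diabetes_duration = 12,
#'                censor_time = 3.2)
patient_record <- function(patient_id, age, female, diabetes_duration,
                           prior = NULL, events = NULL,
                           death_time = NA_real_, censor_time,
                           administrative_end_time = NULL,
                           covariates = NULL) {
  pr <- stats::setNames(rep(FALSE, length(event_types())), event_types())
  if (!is.null(prior)) {
    assert_event_types(names(prior), "prior flag")
    pr[names(prior)] <- as.logical(prior)
  }
  if (is.null(events)) {
    events <- data.frame(event_type = character(), occurrence_index = integer(),
                         year_index = integer())
  }
  events <- as.data.frame(events)
  if (nrow(events) > 0) {
    assert_event_types(events$event_type)
    if (any(events$year_index < 1)) {
      stop("year_index must be >= 1 (1-based annual cycles)", call. = FALSE)
    }
    # occurrence indices must be consecutive from 1 within each event type
    for (e in unique(events$event_type)) {
      occ <- sort(events$occurrence_index[events$event_type == e])
      if (!identical(as.integer(occ), seq_along(occ))) {
        stop("occurrence_index must be consecutive from 1 for ", e,
             call. = FALSE)
      }
    }
  }
  if (is.na(censor_time) || censor_time < 0) {
    stop("censor_time must be a non-negative number", call. = FALSE)
  }
  if (!is.na(death_time) && death_time < 0) {
    stop("death_time must be non-negative", call. = FALSE)
  }
  if (is.null(administrative_end_time)) administrative_end_time <- censor_time
  structure(
    list(patient_id = patient_id,
         age = as.numeric(age),
         female = as.numeric(female),
         diabetes_duration = as.numeric(diabetes_duration),
         prior = pr,
         events = events,
         death_time = as.numeric(death_time),
         censor_time = as.numeric(censor_time),
         administrative_end_time = as.numeric(administrative_end_time),
         covariates = covariates),
    class = "qv_patient")
}

patient_died <- function(record) {
  !is.na(record$death_time) && record$death_time <= record$censor_time
}

#' Read trial data from CSV files
#'
#' Reads the two-file tabular representation of a trial: `patients.csv` (one
#' row per patient: id, covariates, prior-event flags `prior_<EVENT>`,
#' `death_time`, `censor_time`, `administrative_end_time`) and `events.csv`
#' (long format: `patient_id`, `event_type`, `occurrence_index`,
#' `year_index`).
#'
#' @param patients_csv,events_csv File paths.
#' @return An object of class `qv_trial` with components `patients`
#'   (data frame) and `events` (data frame).
#' @export
read_trial_data <- function(patients_csv, events_csv) {
  patients <- utils::read.csv(patients_csv, stringsAsFactors = FALSE)
  events <- utils::read.csv(events_csv, stringsAsFactors = FALSE)
  trial_data(patients, events)
}

#' Assemble trial data from in-memory tables
#'
#' @param patients,events Data frames in the layout of [read_trial_data()].
#' @return A `qv_trial` object.
#' @export
trial_data <- function(patients, events) {
  req <- c("patient_id", "age", "female", "diabetes_duration",
           "death_time", "censor_time", "administrative_end_time")
  miss <- setdiff(req, names(patients))
  if (length(miss) > 0) {
    stop("patients table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (e in event_types()) {
    col <- paste0("prior_", e)
    if (!col %in% names(patients)) patients[[col]] <- FALSE
    patients[[col]] <- as.logical(patients[[col]])
  }
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patients table", call. = FALSE)
  }
  if (nrow(events) > 0) {
    assert_event_types(events$event_type)
    unknown <- setdiff(events$patient_id, patients$patient_id)
    if (length(unknown) > 0) {
      stop("events reference unknown patients: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(patients = patients, events = events), class = "qv_trial")
}

#' Write trial data to CSV files
#'
#' @param trial A `qv_trial`.
#' @param patients_csv,events_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_trial_data <- function(trial, patients_csv, events_csv) {
  stopifnot(inherits(trial, "qv_trial"))
  utils::write.csv(trial$patients, patients_csv, row.names = FALSE)
  utils::write.csv(trial$events, events_csv, row.names = FALSE)
  invisible(c(patients_csv, events_csv))
}

#' Extract one patient record from trial data
#'
#' @param trial A `qv_trial`.
#' @param patient_id The patient to extract.
#' @return A `qv_patient`.
#' @export
get_patient <- function(trial, patient_id) {
  i <- match(patient_id, trial$patients$patient_id)
  if (is.na(i)) stop("no such patient: ", patient_id, call. = FALSE)
  row <- trial$patients[i, , drop = FALSE]
  ev <- trial$events[trial$events$patient_id == patient_id,
                     c("event_type", "occurrence_index", "year_index"),
                     drop = FALSE]
  prior <- stats::setNames(
    vapply(event_types(), function(e) isTRUE(row[[paste0("prior_", e)]]),
           logical(1)),
    event_types())
  extra <- setdiff(names(row),
                   c("patient_id", "age", "female", "diabetes_duration",
                     "death_time", "censor_time", "administrative_end_time",
                     paste0("prior_", event_types())))
  covs <- NULL
  if (length(extra) > 0) {
    num <- extra[vapply(row[extra], is.numeric, logical(1))]
    if (length(num) > 0) covs <- stats::setNames(as.numeric(row[1, num]), num)
  }
  patient_record(patient_id = row$patient_id, age = row$age,
                 female = row$female,
                 diabetes_duration = row$diabetes_duration,
                 prior = prior, events = ev,
                 death_time = row$death_time,
                 censor_time = row$censor_time,
                 administrative_end_time = row$administrative_end_time,
                 covariates = covs)
}

#' @export
print.qv_trial <- function(x, ...) {
  cat("Trial data:", nrow(x$patients), "patients,",
      nrow(x$events), "event records\n")
  died <- sum(!is.na(x$patients$death_time) &
                x$patients$death_time <= x$patients$censor_time)
  cat("  deaths on study:", died, "\n")
  fup <- pmin(x$patients$censor_time, x$patients$death_time, na.rm = TRUE)
  cat("  median follow-up:", round(stats::median(fup), 2), "y\n")
  invisible(x)
}
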