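# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; no data files are read except the shipped synthetic
# example under inst/extdata.

# A risk equation set in which nothing ever happens.
zero_eqs <- function() {
  risk_equation_set(list(
    MI = list(form = "logistic", coefficients = c(intercept = -1e6)),
    DEATH = list(form = "logistic", coefficients = c(intercept = -1e6))))
}

# Single permanent-decrement event with constant annual probability p and
# no death: expected QALYs over H years have the closed form
#   H*u0 - d * sum_t (1 - (1-p)^t).
const_hazard_eqs <- function(p) {
  risk_equation_set(list(
    STROKE = list(form = "logistic", coefficients = c(intercept = qlogis(p)))))
}

const_hazard_expected_qalys <- function(p, H, u0, d) {
  H * u0 - d * sum(1 - (1 - p)^seq_len(H))
}

# Utility table with a single configurable decrement (default: permanent
# stroke decrement), everything else zero.
one_decrement_table <- function(event = "STROKE", d = 0.165, u0 = 0.807,
                                subsequent = d) {
  dec <- setNames(lapply(event_types(), function(e) {
    if (e == event) list(event_year = d, subsequent = subsequent)
    else list(event_year = 0, subsequent = 0)
  }), event_types())
  utility_table(baseline_utility = u0, decrements = dec)
}

zero_decrement_table <- function(u0 = 0.807) {
  dec <- setNames(lapply(event_types(), function(e) {
    list(event_year = 0, subsequent = 0)
  }), event_types())
  utility_table(baseline_utility = u0, decrements = dec)
}

simple_patient <- function(id = "p1", censor_time = 3, death_time = NA_real_,
                           events = NULL, prior = NULL, age = 60,
                           admin = NULL) {
  patient_record(id, age = age, female = 0, diabetes_duration = 10,
                 prior = prior, events = events, death_time = death_time,
                 censor_time = censor_time,
                 administrative_end_time = admin)
}

# Aalen-Johansen counting-process oracle for the CIF of cause 1 with
# cause 2 competing: status 0 = censor, 1 = event, 2 = death. Both causes
# at a tied time use the at-risk set just before that time.
aj_oracle <- function(time, status, eval_times = NULL) {
  ut <- sort(unique(time[status > 0]))
  S <- 1
  cif1 <- 0
  cif2 <- 0
  out <- data.frame(time = numeric(), cif1 = numeric(), cif2 = numeric(),
                    surv = numeric())
  for (t in ut) {
    n_risk <- sum(time >= t)
    d1 <- sum(time == t & status == 1)
    d2 <- sum(time == t & status == 2)
    cif1 <- cif1 + S * d1 / n_risk
    cif2 <- cif2 + S * d2 / n_risk
    S <- S * (1 - (d1 + d2) / n_risk)
    out <- rbind(out, data.frame(time = t, cif1 = cif1, cif2 = cif2,
                                 surv = S))
  }
  if (!is.null(eval_times)) {
    idx <- vapply(eval_times, function(tt) {
      w <- which(out$time <= tt)
      if (length(w) == 0) NA_integer_ else max(w)
    }, integer(1))
    data.frame(time = eval_times,
               cif1 = ifelse(is.na(idx), 0, out$cif1[idx]),
               cif2 = ifelse(is.na(idx), 0, out$cif2[idx]),
               surv = ifelse(is.na(idx), 1, out$surv[idx]))
  } else {
    out
  }
}

# Small trial data built directly from vectors (one event per patient max).
tiny_trial <- function(event_time = NULL, death_time = NULL, censor_time,
                       prior_flag = NULL, event_type = "MI") {
  n <- length(censor_time)
  if (is.null(death_time)) death_time <- rep(NA_real_, n)
  if (is.null(prior_flag)) prior_flag <- rep(FALSE, n)
  ids <- sprintf("t%03d", seq_len(n))
  pats <- data.frame(patient_id = ids, age = 60, female = 0,
                     diabetes_duration = 10,
                     death_time = death_time, censor_time = censor_time,
                     administrative_end_time = censor_time,
                     stringsAsFactors = FALSE)
  pats[[paste0("prior_", event_type)]] <- prior_flag
  evs <- if (is.null(event_time) || all(is.na(event_time))) {
    data.frame(patient_id = character(), event_type = character(),
               occurrence_index = integer(), year_index = integer())
  } else {
    keep <- !is.na(event_time)
    data.frame(patient_id = ids[keep], event_type = event_type,
               occurrence_index = 1L,
               year_index = as.integer(event_time[keep]),
               stringsAsFactors = FALSE)
  }
  trial_data(pats, evs)
}
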