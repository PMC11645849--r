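#' Catalogue of validation analyses
#'
#' The closed set of analyses the validation pipeline can run: the base
#' case (model QALYs vs trial QALYs), life-years versions, two extreme
#' deliberately biased cross-comparisons (model life-years vs trial QALYs
#' and vice versa), and eight sensitivity analyses varying the accounting
#' rules (second-event counting, alternative utilities, censor-year
#' exclusion, discounting, short horizons).
#'
#' @return Data frame with one row per analysis id and a description.
#' @export
analysis_catalogue <- function() {
  data.frame(
    id = c("base", "life_years", "ly_vs_qaly", "qaly_vs_ly",
           paste0("sa", 1:8)),
    description = c(
      "Model QALYs v. trial QALYs (base case)",
      "Model life-years v. trial life-years",
      "Model life-years v. trial QALYs (extreme bias)",
      "Model QALYs v. trial life-years (extreme bias)",
      "Trial QALYs count second events since randomization regardless of history",
      "Excluding disutility from second MI/stroke/amputation (no-prior subset)",
      "Excluding ulcer and second events (no-prior subset)",
      "Alternative utility values",
      "Excluding QALYs in the censor year",
      "Discounting QALYs at 3.5% per annum",
      "1-y time horizon",
      "3-y time horizon"),
    stringsAsFactors = FALSE)
}

# Internal: full per-analysis configuration.
analysis_defs <- function(table, alt_table) {
  d <- qaly_options()
  defs <- list(
    base       = list(model_opts = d, trial_opts = d,
                      model_ly = FALSE, trial_ly = FALSE, table = table),
    life_years = list(model_opts = d, trial_opts = d,
                      model_ly = TRUE, trial_ly = TRUE, table = table),
    ly_vs_qaly = list(model_opts = d, trial_opts = d,
                      model_ly = TRUE, trial_ly = FALSE, table = table),
    qaly_vs_ly = list(model_opts = d, trial_opts = d,
                      model_ly = FALSE, trial_ly = TRUE, table = table),
    sa1 = list(model_opts = d,
               trial_opts = qaly_options(
                 second_event_rule = "count_all_since_randomization"),
               model_ly = FALSE, trial_ly = FALSE, table = table),
    sa2 = list(model_opts = qaly_options(
                 second_event_rule = "exclude_second_events"),
               trial_opts = qaly_options(
                 second_event_rule = "exclude_second_events"),
               model_ly = FALSE, trial_ly = FALSE, table = table,
               subset = "no_prior_msa"),
    sa3 = list(model_opts = qaly_options(
                 second_event_rule = "exclude_second_events_and_ulcer"),
               trial_opts = qaly_options(
                 second_event_rule = "exclude_second_events_and_ulcer"),
               model_ly = FALSE, trial_ly = FALSE, table = table,
               subset = "no_prior_msa"),
    sa4 = list(model_opts = d, trial_opts = d,
               model_ly = FALSE, trial_ly = FALSE, table = alt_table),
    sa5 = list(model_opts = qaly_options(exclude_censor_year = TRUE),
               trial_opts = qaly_options(exclude_censor_year = TRUE),
               model_ly = FALSE, trial_ly = FALSE, table = table),
    sa6 = list(model_opts = qaly_options(discount_rate = 0.035),
               trial_opts = qaly_options(discount_rate = 0.035),
               model_ly = FALSE, trial_ly = FALSE, table = table),
    sa7 = list(model_opts = qaly_options(horizon_years = 1),
               trial_opts = qaly_options(horizon_years = 1),
               model_ly = FALSE, trial_ly = FALSE, table = table),
    sa8 = list(model_opts = qaly_options(horizon_years = 3),
               trial_opts = qaly_options(horizon_years = 3),
               model_ly = FALSE, trial_ly = FALSE, table = table)
  )
  defs
}

#' Derive standard subgroup labels
#'
#' Adds the standard validation subgroups to a patients table: age band at
#' randomization (`<65` / `>=65`), prior MI/IHD/stroke (`yes`/`no`) and
#' diabetes duration (`<5y` / `>=5y`).
#'
#' @param patients Patients data frame.
#' @return Data frame with columns `age_band`, `prior_cvd`, `diab_duration`.
#' @export
subgroup_labels <- function(patients) {
  data.frame(
    age_band = ifelse(patients$age < 65, "<65", ">=65"),
    prior_cvd = ifelse(patients$prior_MI | patients$prior_IHD |
                         patients$prior_STROKE, "yes", "no"),
    diab_duration = ifelse(patients$diabetes_duration < 5, "<5y", ">=5y"),
    stringsAsFactors = FALSE)
}

#' Simulate model predictions for every patient in a trial
#'
#' Runs the microsimulation engine for each patient under one candidate
#' model, re-using a single set of simulated histories per patient across
#' multiple QALY accounting specifications, and accumulating predicted
#' cumulative incidence over the cohort (first events among patients with
#' no baseline history of the event, second events among those with
#' history, death and the any-event composite over everyone).
#'
#' @param trial A [trial_data()] object.
#' @param eqs A [risk_equation_set()] (the candidate model).
#' @param config A [sim_config()]; each patient gets a substream seed
#'   derived from `config$seed` and the patient's row index.
#' @param specs Named list of accounting specifications, each a list with
#'   `options` ([qaly_options()]) and `table` ([utility_table()]).
#' @return A list of class `qv_cohort_sim`: `pred` (data frame of
#'   per-patient mean QALYs `qalys_<spec>` and life-years `ly_<spec>`) and
#'   `cum` (data frame: `event`, `subset_rule`, `cycle`, `cum_incidence`,
#'   `n`).
#' @export
run_cohort <- function(trial, eqs, config = sim_config(),
                       specs = list(base = list(options = qaly_options(),
                                                table = default_utility_table()))) {
  stopifnot(inherits(trial, "qv_trial"))
  n_pat <- nrow(trial$patients)
  H <- config$horizon_years
  qmat <- lymat <- matrix(NA_real_, n_pat, length(specs),
                          dimnames = list(NULL, names(specs)))
  acc <- list()  # event|subset -> list(sum = numeric(H), n = 0)
  add_acc <- function(key, cum_first) {
    if (is.null(acc[[key]])) acc[[key]] <<- list(sum = numeric(H), n = 0L)
    acc[[key]]$sum <<- acc[[key]]$sum + cum_first
    acc[[key]]$n <<- acc[[key]]$n + 1L
  }
  for (i in seq_len(n_pat)) {
    rec <- get_patient(trial, trial$patients$patient_id[i])
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    set.seed(cfg$seed)
    core <- sim_patient_core(rec, eqs, cfg)
    censor_end <- min(if (patient_died(rec)) rec$administrative_end_time
                      else rec$censor_time, H)
    for (s in names(specs)) {
      opt <- specs[[s]]$options
      k <- qaly_kernel(core$occ, core$death_cycle, rec$prior,
                       specs[[s]]$table, opt, censor_end)
      qmat[i, s] <- mean(kernel_qalys(k, opt))
      lyopt <- opt; lyopt$life_years_mode <- TRUE
      lymat[i, s] <- mean(kernel_qalys(k, lyopt))
    }
    ci <- core_cum_incidence(core, H, cfg$n_loops)
    for (e in names(core$occ)) {
      cf <- ci$mean_cum_first[ci$event == e]
      key <- if (rec$prior[[e]]) paste0(e, "|with_history")
             else paste0(e, "|no_history")
      add_acc(key, cf)
    }
    add_acc("DEATH|all", ci$mean_cum_events[ci$event == "DEATH"])
    add_acc("ANY_EVENT|all", ci$mean_cum_events[ci$event == "ANY_EVENT"])
  }
  cum <- do.call(rbind, lapply(names(acc), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    data.frame(event = parts[1], subset_rule = parts[2], cycle = seq_len(H),
               cum_incidence = acc[[key]]$sum / acc[[key]]$n,
               n = acc[[key]]$n, stringsAsFactors = FALSE)
  }))
  pred <- data.frame(patient_id = trial$patients$patient_id,
                     stringsAsFactors = FALSE)
  for (s in names(specs)) {
    pred[[paste0("qalys_", s)]] <- qmat[, s]
    pred[[paste0("ly_", s)]] <- lymat[, s]
  }
  structure(list(pred = pred, cum = cum, n_loops = config$n_loops),
            class = "qv_cohort_sim")
}

#' Run a full validation study
#'
#' The end-to-end workflow: for each candidate model, simulate model QALYs
#' and life-years per patient, compute trial QALYs/life-years from the
#' observed histories under each analysis's accounting rules, evaluate the
#' five performance metrics overall and by subgroup, and compare observed
#' against predicted cumulative incidence for every event.
#'
#' @param trial A [trial_data()] object.
#' @param models Named list of candidate [risk_equation_set()]s.
#' @param table Base-case [utility_table()].
#' @param alt_table Alternative utility table used by the `sa4` analysis.
#' @param analyses Character vector of analysis ids from
#'   [analysis_catalogue()].
#' @param config A [sim_config()].
#' @param subgroups Evaluate metrics by the standard subgroups as well as
#'   overall (base analysis only).
#' @param out_dir If non-`NULL`, write `metrics.csv`, `report.csv`,
#'   `cif.csv` and `manifest.yaml` there.
#' @param verbose Log per-stage progress with patient counts.
#' @return A list of class `qv_validation`: `metrics` (tidy data frame),
#'   `cif` (tidy curve table), `cif_comparisons` (per model x event
#'   in-CI summaries), `pairs` (per-analysis paired predictions) and
#'   `manifest`.
#' @export
run_validation <- function(trial, models, table = default_utility_table(),
                           alt_table = alt_utility_table(),
                           analyses = c("base", "life_years",
                                        "ly_vs_qaly", "qaly_vs_ly"),
                           config = sim_config(n_loops = 1000),
                           subgroups = TRUE, out_dir = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(trial, "qv_trial"))
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("models must be a named list of risk equation sets", call. = FALSE)
  }
  defs <- analysis_defs(table, alt_table)
  bad <- setdiff(analyses, names(defs))
  if (length(bad) > 0) {
    stop("unknown analyses: ", paste(bad, collapse = ", "),
         "; see analysis_catalogue()", call. = FALSE)
  }
  # consistency: every event type referenced by any model must be priced
  for (m in names(models)) {
    ev <- intersect(names(models[[m]]$equations), event_types())
    missing_dec <- setdiff(ev, names(table$decrements))
    if (length(missing_dec) > 0) {
      stop("model ", m, " simulates events absent from the utility table: ",
           paste(missing_dec, collapse = ", "), call. = FALSE)
    }
  }
  say <- function(...) if (verbose) message(...)
  n_pat <- nrow(trial$patients)
  say("validation: ", n_pat, " patients, ", length(models), " model(s), ",
      length(analyses), " analyses, ", config$n_loops, " loops")

  sg <- subgroup_labels(trial$patients)
  no_prior_msa <- !(trial$patients$prior_MI | trial$patients$prior_STROKE |
                      trial$patients$prior_AMPUTATION)

  # trial-side outcomes per analysis
  records <- lapply(trial$patients$patient_id, get_patient, trial = trial)
  trial_out <- list()
  for (a in analyses) {
    d <- defs[[a]]
    opt <- d$trial_opts
    if (d$trial_ly) opt$life_years_mode <- TRUE
    trial_out[[a]] <- vapply(records, trial_qalys, numeric(1),
                             table = d$table, options = opt)
  }
  say("trial outcomes computed for ", n_pat, " patients")

  # model-side: unique (options, table) accounting specs across analyses
  spec_key <- function(d) paste(d$model_opts$second_event_rule,
                                d$model_opts$discount_rate,
                                d$model_opts$exclude_censor_year,
                                d$model_opts$horizon_years %||% "full",
                                format(d$table$baseline_utility), sep = "/")
  keys <- vapply(analyses, function(a) spec_key(defs[[a]]), character(1))
  specs <- list()
  for (a in analyses) {
    k <- keys[[a]]
    if (is.null(specs[[k]])) {
      specs[[k]] <- list(options = defs[[a]]$model_opts,
                         table = defs[[a]]$table)
    }
  }

  metrics <- list(); pairs <- list(); cif_rows <- list(); cmp_rows <- list()
  for (m in names(models)) {
    say("simulating model '", m, "' (", length(specs),
        " accounting spec(s))")
    sim <- run_cohort(trial, models[[m]], config, specs)
    for (a in analyses) {
      d <- defs[[a]]
      col <- if (d$model_ly) paste0("ly_") else paste0("qalys_")
      M <- sim$pred[[paste0(col, keys[[a]])]]
      T_ <- trial_out[[a]]
      keep <- rep(TRUE, n_pat)
      if (identical(d$subset, "no_prior_msa")) keep <- no_prior_msa
      p <- paired_predictions(M[keep], T_[keep],
                              subgroups = if (subgroups && a == "base")
                                sg[keep, , drop = FALSE] else NULL,
                              patient_id = trial$patients$patient_id[keep])
      pairs[[paste(m, a, sep = ".")]] <- p
      metrics[[paste(m, a, sep = ".")]] <-
        evaluate(p, analysis = a, model = m)
    }
    # cumulative incidence: observed vs predicted
    for (e in c(event_types(), "DEATH", "ANY_EVENT")) {
      rule <- if (e %in% c("DEATH", "ANY_EVENT")) "all" else "no_history"
      prow <- sim$cum[sim$cum$event == e & sim$cum$subset_rule == rule, ]
      if (nrow(prow) == 0) next
      pred <- predicted_cif(prow$cum_incidence, 1, event = e)
      obs <- tryCatch(observed_cif(trial, e, rule),
                      warning = function(w) NULL, error = function(err) NULL)
      cif_rows[[paste(m, e, sep = ".")]] <- local({
        tab <- cif_to_table(list(pred))
        tab$model <- m
        if (!is.null(obs) && m == names(models)[1]) {
          otab <- cif_to_table(list(obs)); otab$model <- "observed"
          tab <- rbind(otab, tab)
        }
        tab
      })
      if (!is.null(obs) && sum(obs$estimate) > 0) {
        cmp <- tryCatch(compare_curves(obs, pred), error = function(err) NULL)
        if (!is.null(cmp)) {
          cmp_rows[[paste(m, e, sep = ".")]] <-
            data.frame(model = m, event = e, subset_rule = rule,
                       fraction_in_ci = cmp$fraction_in_ci)
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  cif <- do.call(rbind, cif_rows)
  cmp <- do.call(rbind, cmp_rows)
  if (!is.null(cif)) rownames(cif) <- NULL
  if (!is.null(cmp)) rownames(cmp) <- NULL
  manifest <- list(n_patients = n_pat, n_events = nrow(trial$events),
                   models = names(models), analyses = analyses,
                   n_loops = config$n_loops, seed = config$seed,
                   horizon_years = config$horizon_years)
  out <- structure(list(metrics = metrics, cif = cif,
                        cif_comparisons = cmp, pairs = pairs,
                        manifest = manifest),
                   class = "qv_validation")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(format_report(metrics),
                     file.path(out_dir, "report.csv"), row.names = FALSE)
    if (!is.null(cif)) {
      utils::write.csv(cif, file.path(out_dir, "cif.csv"), row.names = FALSE)
    }
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    say("report files written to ", out_dir)
  }
  out
}

#' Format a metric table for reporting
#'
#' Deterministic presentation formatting: outcomes as `mean (sd)` and all
#' metrics rounded to 3 decimal places.
#'
#' @param metrics Metric data frame from [run_validation()] or
#'   [evaluate()].
#' @return Data frame of formatted strings.
#' @export
format_report <- function(metrics) {
  if (is.null(metrics) || nrow(metrics) == 0) {
    return(data.frame(analysis = character(), model = character(),
                      subgroup = character(), n = integer(),
                      trial_outcome = character(), model_outcome = character(),
                      q2 = character(), r2 = character(), mae = character(),
                      mse = character(), bias = character()))
  }
  f3 <- function(x) formatC(x, digits = 3, format = "f")
  data.frame(
    analysis = metrics$analysis, model = metrics$model,
    subgroup = ifelse(metrics$subgroup_var == "overall", "overall",
                      paste0(metrics$subgroup_var, "=", metrics$subgroup)),
    n = metrics$n,
    trial_outcome = paste0(f3(metrics$mean_T), " (", f3(metrics$sd_T), ")"),
    model_outcome = paste0(f3(metrics$mean_M), " (", f3(metrics$sd_M), ")"),
    q2 = f3(metrics$q2), r2 = f3(metrics$r2), mae = f3(metrics$mae),
    mse = f3(metrics$mse), bias = f3(metrics$bias),
    stringsAsFactors = FALSE)
}

#' @export
print.qv_validation <- function(x, ...) {
  cat("Validation run:", x$manifest$n_patients, "patients,",
      x$manifest$n_loops, "loops, models:",
      paste(x$manifest$models, collapse = ", "), "\n\n")
  ov <- x$metrics[x$metrics$subgroup_var == "overall", ]
  print(format_report(ov), row.names = FALSE)
  invisible(x)
}
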