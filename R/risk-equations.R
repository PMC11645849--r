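#' Construct a coefficient-driven risk equation set
#'
#' A risk equation set maps each event type (and death, under the key
#' `DEATH`) to an annual-probability equation: a functional form
#' (`logistic` or `cloglog`, i.e. complementary log-log) and a named
#' coefficient vector over covariates and history terms. The engine is
#' fully coefficient-driven: any published or recalibrated annual-cycle
#' model can be expressed by supplying its coefficients in a config file.
#'
#' Coefficient names are resolved against the simulated patient state:
#' \itemize{
#'   \item `intercept` — the constant term;
#'   \item baseline covariates: `age`, `female`, `diabetes_duration`, or
#'     any extra covariate supplied on the patient record;
#'   \item `age_current`, `diabetes_duration_current` — baseline value plus
#'     elapsed cycles; `year` — the current annual cycle (1-based);
#'   \item `hist_<EVENT>` — 1 if the event has occurred (including
#'     pre-baseline history), else 0; `count_<EVENT>` — occurrence count
#'     including history;
#'   \item `new_<EVENT>` — same-cycle occurrence indicator; available only
#'     to the `DEATH` equation, which is drawn after the event draws.
#' }
#'
#' @param equations Named list over event types and optionally `DEATH`;
#'   each element a list with `form` ("logistic" or "cloglog"),
#'   `coefficients` (named numeric) and optionally `second_event`
#'   (logical; only MI, STROKE, AMPUTATION may be `TRUE`).
#' @return An object of class `qv_risk_equations`.
#' @seealso [read_risk_equations()], [annual_probabilities()]
#' @export
risk_equation_set <- function(equations) {
  valid <- c(event_types(), "DEATH")
  bad <- setdiff(names(equations), valid)
  if (length(bad) > 0) {
    stop("unknown equation keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  eqs <- lapply(names(equations), function(nm) {
    e <- equations[[nm]]
    form <- match.arg(e$form %||% "logistic", c("logistic", "cloglog"))
    co <- unlist(e$coefficients)
    if (is.null(co) || is.null(names(co)) || any(names(co) == "")) {
      stop("equation ", nm, ": coefficients must be a named numeric vector",
           call. = FALSE)
    }
    second <- isTRUE(e$second_event)
    if (second && !(nm %in% recurrent_event_types())) {
      stop("second_event = TRUE only allowed for ",
           paste(recurrent_event_types(), collapse = ", "), call. = FALSE)
    }
    list(form = form, coefficients = co, second_event = second)
  })
  names(eqs) <- names(equations)
  structure(list(equations = eqs), class = "qv_risk_equations")
}

#' Read / write a risk equation set as YAML
#'
#' Schema: `{EVENT: {form: logistic|cloglog, coefficients: {name: value},
#' second_event: true|false}}`, with `DEATH` as an additional key for the
#' mortality equation.
#'
#' @param path File path.
#' @return `read_risk_equations()` returns a `qv_risk_equations`;
#'   `write_risk_equations()` returns `path` invisibly.
#' @export
read_risk_equations <- function(path) {
  risk_equation_set(yaml::read_yaml(path))
}

#' @rdname read_risk_equations
#' @param eqs A `qv_risk_equations`.
#' @export
write_risk_equations <- function(eqs, path) {
  stopifnot(inherits(eqs, "qv_risk_equations"))
  yaml::write_yaml(lapply(eqs$equations, function(e) {
    list(form = e$form, coefficients = as.list(e$coefficients),
         second_event = e$second_event)
  }), path)
  invisible(path)
}

# Link function: linear predictor -> annual probability
apply_link <- function(lp, form) {
  if (form == "logistic") stats::plogis(lp) else -expm1(-exp(lp))
}

# Evaluate one equation's linear predictor given a resolver function
# resolve(name) -> scalar or vector covariate value.
equation_prob <- function(eq, resolve) {
  co <- eq$coefficients
  lp <- 0
  for (nm in names(co)) {
    if (nm == "intercept") {
      lp <- lp + co[[nm]]
    } else {
      lp <- lp + co[[nm]] * resolve(nm)
    }
  }
  apply_link(lp, eq$form)
}

#' Annual event and death probabilities for a given state
#'
#' Evaluates every equation in the set at a fixed patient state, returning
#' the annual probability of each event (and death). Deterministic in the
#' state; probabilities are guaranteed in [0, 1] by the link functions.
#'
#' @param state Named list or vector of covariate values; history terms
#'   (`hist_<EVENT>`, `count_<EVENT>`) default to 0 when absent only if
#'   no equation references them — a referenced covariate missing from
#'   `state` is a configuration error.
#' @param eqs A [risk_equation_set()].
#' @return Named numeric vector of probabilities over the equations.
#' @export
#' @examples
#' eqs <- risk_equation_set(list(
#'   MI = list(form = "logistic", coefficients = c(intercept = -4))))
#' annual_probabilities(list(), eqs)
annual_probabilities <- function(state, eqs) {
  stopifnot(inherits(eqs, "qv_risk_equations"))
  state <- as.list(state)
  resolve <- function(nm) {
    if (!is.null(state[[nm]])) return(as.numeric(state[[nm]]))
    stop("equation requires covariate '", nm, "' missing from state",
         call. = FALSE)
  }
  vapply(eqs$equations, function(e) as.numeric(equation_prob(e, resolve)),
         numeric(1))
}

#' @export
print.qv_risk_equations <- function(x, ...) {
  cat("Risk equation set with", length(x$equations), "equations:\n")
  for (nm in names(x$equations)) {
    e <- x$equations[[nm]]
    cat("  ", nm, " (", e$form,
        if (e$second_event) ", second occurrences" else "",
        "): ", paste(names(e$coefficients), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
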