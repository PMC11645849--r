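#' Paired model/trial predictions
#'
#' The substrate of all performance metrics: per-patient model predictions
#' `M` (model QALYs or life-years, averaged over simulation loops) paired
#' with observed outcomes `T` (trial QALYs or life-years), optionally with
#' subgroup labels.
#'
#' @param M,T Numeric vectors of equal length (>= 2), no missing values.
#' @param subgroups Optional data frame of per-patient subgroup labels
#'   (one column per grouping variable).
#' @param patient_id Optional identifiers.
#' @return An object of class `qv_paired` (a data frame with columns `M`,
#'   `T` and any subgroup columns).
#' @export
paired_predictions <- function(M, T, subgroups = NULL, patient_id = NULL) {
  if (length(M) != length(T)) stop("M and T must have equal length", call. = FALSE)
  if (length(M) < 2) stop("at least 2 paired observations required", call. = FALSE)
  if (anyNA(M) || anyNA(T)) stop("M and T must not contain missing values", call. = FALSE)
  d <- data.frame(M = as.numeric(M), T = as.numeric(T))
  if (!is.null(patient_id)) d$patient_id <- patient_id
  if (!is.null(subgroups)) {
    subgroups <- as.data.frame(subgroups)
    if (nrow(subgroups) != nrow(d)) {
      stop("subgroups must have one row per patient", call. = FALSE)
    }
    d <- cbind(d, subgroups)
  }
  class(d) <- c("qv_paired", "data.frame")
  d
}

as_paired <- function(paired) {
  if (inherits(paired, "qv_paired")) return(paired)
  if (is.data.frame(paired) && all(c("M", "T") %in% names(paired))) {
    return(paired_predictions(paired$M, paired$T))
  }
  stop("expected a qv_paired object or a data frame with columns M and T",
       call. = FALSE)
}

#' Bias (mean residual)
#'
#' Mean of `M - T`: positive values mean the model overestimates the
#' observed outcome, negative values underestimation.
#'
#' @param paired A [paired_predictions()] object (or data frame with
#'   columns `M` and `T`).
#' @return Scalar bias, same units as the outcome.
#' @export
#' @examples
#' bias(paired_predictions(M = c(2, 3), T = c(1, 1)))  # 1.5
bias <- function(paired) {
  p <- as_paired(paired)
  mean(p$M - p$T)
}

#' Mean squared error
#'
#' Mean of `(M - T)^2` (denominator N). Increased by both bias and poor
#' discrimination; penalises large errors more than [mae()].
#'
#' @inheritParams bias
#' @return Scalar MSE, squared outcome units.
#' @export
mse <- function(paired) {
  p <- as_paired(paired)
  mean((p$M - p$T)^2)
}

#' Mean absolute error
#'
#' @inheritParams bias
#' @return Scalar MAE, same units as the outcome.
#' @export
mae <- function(paired) {
  p <- as_paired(paired)
  mean(abs(p$M - p$T))
}

#' R-squared from regressing observed on predicted
#'
#' Coefficient of determination of the ordinary-least-squares regression of
#' `T` on `M`. Because the regression recalibrates slope and intercept,
#' R-squared measures discrimination only: it is invariant to affine
#' transformations of the predictions and does not penalise bias.
#'
#' @inheritParams bias
#' @return A list with components `r2` and `fit` (a `qv_calibration` with
#'   `slope` and `intercept` minimising `sum((a*M + b - T)^2)`).
#' @export
#' @examples
#' r_squared(paired_predictions(M = c(1, 2, 3), T = c(1, 3, 2)))$r2  # 0.25
r_squared <- function(paired) {
  p <- as_paired(paired)
  if (stats::var(p$T) <= 0) {
    stop("T has zero variance; R-squared undefined", call. = FALSE)
  }
  if (stats::var(p$M) <= 0) {
    warning("M has zero variance; regression slope undefined, R-squared set to 0")
    fit <- structure(list(slope = NA_real_, intercept = mean(p$T)),
                     class = "qv_calibration")
    return(list(r2 = 0, fit = fit))
  }
  a <- stats::cov(p$M, p$T) / stats::var(p$M)
  b <- mean(p$T) - a * mean(p$M)
  r2 <- 1 - sum((a * p$M + b - p$T)^2) / sum((p$T - mean(p$T))^2)
  list(r2 = r2,
       fit = structure(list(slope = a, intercept = b),
                       class = "qv_calibration"))
}

#' Q-squared (proportional reduction in error)
#'
#' `Q^2 = 1 - MSE / SD^2`, where MSE uses the `N` denominator and `SD^2` is
#' the sample variance of the observed outcomes with the `N - 1`
#' denominator, exactly as defined; the resulting `(N-1)/N` asymmetry is
#' intentional and is not harmonised. Q-squared captures both
#' discrimination and bias: a perfect predictor scores 1, and unlike
#' R-squared it can be negative for very poor predictors.
#'
#' @inheritParams bias
#' @return Scalar Q-squared (unitless, <= 1).
#' @export
q_squared <- function(paired) {
  p <- as_paired(paired)
  v <- stats::var(p$T)
  if (v <= 0) stop("T has zero variance; Q-squared undefined", call. = FALSE)
  1 - mse(p) / v
}

#' Q-squared from summary statistics
#'
#' Recomputes `Q^2 = 1 - MSE / SD^2` from a reported mean squared error and
#' the standard deviation of the observed outcomes, e.g. to recompute
#' published Q-squared values from tabulated MSE and SD.
#'
#' @param mse Mean squared error (>= 0).
#' @param sd Standard deviation of the observed outcomes (> 0).
#' @return Scalar Q-squared.
#' @export
#' @examples
#' q_squared_from_summary(mse = 0.210, sd = 1.087)  # ~0.822
q_squared_from_summary <- function(mse, sd) {
  if (!is.numeric(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  if (!is.numeric(mse) || mse < 0) stop("mse must be >= 0", call. = FALSE)
  1 - mse / sd^2
}

metric_report_row <- function(p, analysis = "base", model = "model",
                              subgroup_var = "overall", subgroup = "all") {
  r2 <- r_squared(p)$r2
  data.frame(analysis = analysis, model = model,
             subgroup_var = subgroup_var, subgroup = subgroup,
             n = nrow(p),
             mean_T = mean(p$T), sd_T = stats::sd(p$T),
             mean_M = mean(p$M), sd_M = stats::sd(p$M),
             q2 = q_squared(p), r2 = r2,
             mae = mae(p), mse = mse(p), bias = bias(p),
             stringsAsFactors = FALSE)
}

#' Evaluate all five metrics, overall and by subgroup
#'
#' Computes n, mean/SD of observed and predicted outcomes, Q-squared,
#' R-squared, MAE, MSE and bias for the whole sample and for each level of
#' each subgroup variable. Metrics are computed at full precision on
#' subgroup members only; rounding (3 decimal places) is left to
#' [format_report()].
#'
#' @inheritParams bias
#' @param subgroup_vars Character vector of subgroup column names present
#'   in `paired`; `NULL` uses every column other than `M`, `T`,
#'   `patient_id`.
#' @param analysis,model Labels copied into the report rows.
#' @return A data frame with one row per (overall + subgroup level).
#' @export
evaluate <- function(paired, subgroup_vars = NULL,
                     analysis = "base", model = "model") {
  p <- as_paired(paired)
  if (is.null(subgroup_vars)) {
    subgroup_vars <- setdiff(names(p), c("M", "T", "patient_id"))
  }
  miss <- setdiff(subgroup_vars, names(p))
  if (length(miss) > 0) {
    stop("subgroup variables not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- list(metric_report_row(p, analysis, model))
  for (v in subgroup_vars) {
    for (lev in unique(as.character(p[[v]]))) {
      sub <- p[as.character(p[[v]]) == lev, , drop = FALSE]
      if (nrow(sub) < 2) {
        warning("subgroup ", v, "=", lev, " has fewer than 2 patients; omitted")
        next
      }
      out[[length(out) + 1]] <-
        metric_report_row(sub, analysis, model, subgroup_var = v,
                          subgroup = lev)
    }
  }
  do.call(rbind, out)
}
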