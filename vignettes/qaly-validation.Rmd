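---
title: "Validating patient-level simulation models on QALYs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating patient-level simulation models on QALYs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qalyval)
```

## The problem

Decision-analytic microsimulation models in diabetes (and elsewhere)
predict mortality and a set of clinical events — myocardial infarction
(MI), stroke, heart failure, blindness, amputation, renal failure,
ischaemic heart disease (IHD), foot ulcer — one patient at a time, and are
used in health technology assessment to estimate quality-adjusted
life-years (QALYs). External validation usually checks each event's
incidence separately. qalyval instead validates on the *outcome the model
is actually used for*: per-patient QALYs. For each trial participant it
pairs

* **trial QALYs** `T_i` — the QALYs implied by the participant's *observed*
  events and survival, priced with the model's own utility assumptions, and
* **model QALYs** `M_i` — the QALYs the simulation model *predicts* for
  that participant over the same follow-up, averaged over Monte Carlo
  loops,

and summarises agreement with five metrics:

* bias `= mean(M_i - T_i)` (negative = underestimation),
* `MSE = mean((M_i - T_i)^2)` and `MAE = mean(|M_i - T_i|)`,
* `R^2` from the ordinary-least-squares regression of `T` on `M`
  (discrimination only — it recalibrates slope and intercept, so a
  constantly biased model keeps a high `R^2`),
* `Q^2 = 1 - MSE / SD^2`, the proportional reduction in error, where `SD`
  is the standard deviation of the observed `T_i`. `Q^2` is the headline
  metric: it captures both discrimination and bias, equals 1 for a perfect
  predictor, and can be negative for very poor ones.

A deliberate asymmetry: `MSE` uses the `N` denominator while `SD^2` uses
`N - 1`, exactly as the defining formula is written. The resulting
`(N-1)/N` factor is small and is *not* harmonised away.

## QALY accounting conventions

Both trial and model QALYs use the same discrete annual-cycle accounting:

* every participant starts at the baseline utility (default 0.807);
* events occur at the **start** of a year; each counted occurrence
  subtracts its event-year decrement in the cycle of occurrence and its
  subsequent-years decrement in later cycles. Decrements are additive with
  **no floor**, so stacked events can drive the utility negative — this is
  intentional and matches the additive utility model being emulated;
* death occurs **halfway** through its year: the death cycle accrues with
  weight 0.5 (half-cycle correction). A death at fractional time `d` is
  assigned to cycle `ceiling(d)` regardless of where in the year it falls;
* the censor year accrues in proportion to the fraction of the year the
  participant remained on study;
* for **model** QALYs, accounting runs to the participant's censoring time
  — for participants who died, to their *administrative end time* (the
  follow-up they would have had absent death). Loops in which the
  simulated patient dies in or before the censor year contribute the
  half-cycle-weighted death-year utility; surviving loops contribute the
  fractional censor-year weight. The exact published adjustment formula for
  deaths in the censor year is not in the public record; this per-loop rule
  is our declared interpretation.

Occurrence counting under the default rule: second MI, stroke and
amputation carry the same decrement as the first (counting any
pre-baseline occurrence via the history flags), while a third MI / stroke /
amputation or a second ulcer has no further impact. Alternative rules
(`count_all_since_randomization`, `exclude_second_events`,
`exclude_second_events_and_ulcer`) reproduce the corresponding sensitivity
analyses; see `?qaly_options`.

Discounting, when enabled, uses `1/(1+r)^(t-1)` for cycle `t`: the first
year is undiscounted, consistent with events at the start of the year. The
timing convention is not dictated by the accounting above; this choice is
declared here and applied uniformly. One consequence: discounting leaves a
participant with less than one year of follow-up unchanged.

### Default utility values

The base-case table ships with baseline 0.807, MI −0.065 for one year,
stroke −0.165 permanent, renal failure −0.330 permanent, and zero
decrement for IHD and blindness (neither had a significant utility effect
in the source estimation). The decrements for heart failure (−0.108),
amputation (−0.280) and ulcer (−0.170) are **labelled placeholders**
borrowed from the fully published alternative value set
(`alt_utility_table()`: baseline 0.785, all subsequent-year decrements
equal to the event-year decrement), because their base-case values are
not in the public record. Users validating a real model should supply the
exact table via `read_utility_table()`.

## The microsimulation engine

`risk_equation_set()` defines an annual-cycle model as one equation per
event plus `DEATH`: a link (`logistic` or complementary log-log, the two
standard forms for annual event probabilities) and a named coefficient
vector resolved against the simulated state (baseline covariates,
`age_current`-style time-updated terms, `hist_*`/`count_*` history terms,
and `new_*` same-cycle event indicators for the death equation). The
engine is deliberately coefficient-driven: published or recalibrated
equation systems are supplied as YAML, none are hard-coded.

Within a year, all eligible events are drawn **simultaneously from
start-of-year state**, death is drawn after the events (so fatal-event
coefficients can reference `new_MI` etc.), and history updates at year
end. No state changes after death. The internal ordering of the emulated
closed-source models is not recoverable, so this policy is declared and
fixed rather than configurable guesswork.

Reproducibility: each patient's draws come from a substream seeded
deterministically from the master seed and the patient's row index, with
loops drawn sequentially inside the substream. Changing the loop count or
removing other patients therefore never reshuffles a given patient's
trajectory, and identical `(seed, config, inputs)` reproduce every output
bit for bit.

`run_patient()` averages QALYs, life-years and cumulative event counts
over loops. The default `n_loops = 50000` is the point at which
per-patient means are comfortably converged for equation sets in the
default hazard range (`convergence_diagnostic()` shows the running mean
and its shrinking standard error); cohort-level validation summaries
average over patients as well and are stable with far fewer loops, so the
pipeline default is 1,000.

## Competing-risks incidence

`observed_cif()` estimates the cumulative incidence of each event with
death as a competing risk by the Aalen–Johansen estimator (via
`survival::survfit()` on a multi-state factor outcome), with log(−log)
pointwise confidence intervals. With no deaths it collapses exactly to
1 − Kaplan–Meier. First-event curves are restricted to patients with no
baseline history of the event; second-event curves to patients with such
history; death and the first-of-any-event composite use everyone. Observed
events sit on the annual-cycle grid while deaths and censorings are
fractional; an event and a death in the same cycle are resolved
event-first, mirroring the start-of-year / mid-year convention.
`predicted_cif()` divides the model's cumulative predicted events by the
number of individuals at the start of simulation, and `compare_curves()`
interpolates the observed step function onto cycle boundaries and reports
the fraction of grid times at which the prediction lies inside the
observed confidence band.

## The synthetic trial generator

`generate_trial()` emulates the *structure* of a large contemporary
cardiovascular outcome trial in type 2 diabetes: 73% of patients with
prior cardiovascular events, diabetes duration log-normal with median
12 years, staggered entry producing administrative censoring (uniform
administrative follow-up between 0.5 and 7 years), a constant 2.5% annual
withdrawal probability, and event histories drawn as **one realisation per
patient of the truth process** — a single engine loop under a known
`risk_equation_set()`. The withdrawal and entry-window defaults were
calibrated once against the 3.2-year target median follow-up and then
frozen. Because truth and candidate share the same model class and code
path, the validated model can in principle reach the stochastic ceiling,
and self-validation (truth model scored on its own trial) must beat any
perturbed candidate on `Q^2` and `MSE` — the package's ordering analogue
of a sharper model winning a published head-to-head comparison.

What the generator does *not* emulate: the real joint covariate
distribution (defaults are plausible placeholders, labelled as such),
informative censoring, risk-factor time paths and their imputation, and
event-definition mismatches between trial and model vocabularies. Passing
tests on synthetic trials therefore demonstrate the correctness of the
accounting, metrics and machinery — not the empirical accuracy of any
real model.

## Numerical and design choices

* Times within `1e-9` of an integer are treated as whole years when
  splitting censor times into cycles, avoiding spurious fractional cycles
  from floating-point noise.
* `r_squared()` on a zero-variance predictor returns 0 with a warning (a
  constant predictor explains nothing; the regression slope is undefined).
  Zero variance in the observed outcome is an error for both `r_squared()`
  and `q_squared()`.
* Deaths at exactly a cycle boundary belong to the earlier cycle
  (`ceiling`), matching the half-cycle convention.
* Metrics are computed at full precision; `format_report()` rounds to
  3 decimal places for presentation only.
* The `sa1` counting rule applies to trial QALYs only (that is how the
  sensitivity analysis is defined); `sa2`/`sa3` restrict to patients with
  no prior MI/stroke/amputation and apply the exclusion to both sides.

## Problem sizes

The shipped tests run the full workflow at deliberately modest sizes
chosen for tight feedback loops: single-patient engine checks at
10,000–50,000 loops, generator calibration checks at 1,500–5,000 patients,
and the self-validation ordering study at 2,000 patients × 200 loops —
large enough that the Monte Carlo error is far below the effects being
asserted, as the closed-form error bounds in the tests make explicit.

## Limitations

* The engine is annual-cycle only; within-year continuous-time accrual is
  out of scope by design.
* Utilities combine additively; multiplicative combination is not
  implemented.
* No parameter (second-order) uncertainty: validation is of point
  predictions, as in most published validation exercises.
* Confidence intervals are provided for observed incidence curves but not
  for the performance metrics themselves.
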