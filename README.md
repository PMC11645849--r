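# qalyval

QALY-based external validation of patient-level health simulation models.

## What it is for

Microsimulation models of chronic disease (the exemplar here is type 2
diabetes, with events IHD, MI, stroke, heart failure, blindness,
amputation, renal failure and foot ulcer) are used in health technology
assessment to predict quality-adjusted life-years (QALYs). Conventional
external validation checks one event at a time. qalyval validates a model
on the outcome it is actually used for: for every trial participant it
pairs

- **trial QALYs** *T<sub>i</sub>* — QALYs implied by the participant's
  observed events and survival, priced with the model's utility
  assumptions (annual cycles, events at the start of the year, death
  mid-year with half-cycle weight, fractional censor-year accrual), and
- **model QALYs** *M<sub>i</sub>* — QALYs predicted for that participant
  by Monte Carlo microsimulation over the same follow-up,

and scores the agreement with five metrics:

- bias = Σ(M<sub>i</sub> − T<sub>i</sub>)/N
- MSE = Σ(M<sub>i</sub> − T<sub>i</sub>)²/N, MAE = Σ|M<sub>i</sub> −
  T<sub>i</sub>|/N
- R² = 1 − Σ(aM<sub>i</sub> + b − T<sub>i</sub>)² / Σ(T<sub>i</sub> −
  T̄)², from OLS of T on M (discrimination only)
- **Q² = 1 − MSE/SD²**, the proportional reduction in error, with SD the
  standard deviation of the observed T<sub>i</sub> (N−1 denominator).
  Q² captures both discrimination and bias, equals 1 for a perfect
  predictor, and can go negative.

The package contains the full toolchain: the QALY accounting engine, a
coefficient-driven annual-cycle microsimulator (any equation system can be
supplied as YAML), observed vs predicted cumulative incidence with death
as a competing risk (Aalen–Johansen), a synthetic trial generator with a
known truth process, and a validation pipeline with subgroup and
sensitivity analyses plus a thin `qalyval` command-line wrapper
(`exec/qalyval`).

## Worked example

```r
library(qalyval)

# one patient: stroke in year 2, censored at 3.4 years
p <- patient_record("p1", age = 62, female = 0, diabetes_duration = 12,
                    censor_time = 3.4,
                    events = data.frame(event_type = "STROKE",
                                        occurrence_index = 1, year_index = 2))
trial_qalys(p, default_utility_table())
#> [1] 2.3478
```

0.807 + (0.807 − 0.165) + (0.807 − 0.165) + 0.4·(0.807 − 0.165) = 2.3478:
a full baseline year, the permanent stroke decrement from year 2, and 40%
of the fourth year.

A complete self-validation study on a synthetic trial (the truth process
that generated the data is also the candidate being validated):

```r
trial <- generate_trial(500, seed = 42)
res <- run_validation(trial,
                      models = list(truth = default_truth_equations()),
                      analyses = c("base", "ly_vs_qaly"),
                      config = sim_config(n_loops = 500, seed = 1))
res
#> Validation run: 500 patients, 500 loops, models: truth
#>
#>    analysis model subgroup   n trial_outcome model_outcome    q2    r2   mae   mse   bias
#>        base truth  overall 500 2.735 (1.516) 2.715 (1.339) 0.835 0.836 0.332 0.380 -0.020
#>  ly_vs_qaly truth  overall 500 2.735 (1.516) 3.423 (1.700) 0.588 0.836 0.691 0.947  0.688
```

Read the two rows together: the truth model is nearly unbiased (bias
−0.020) and achieves Q² = 0.835 — the residual error is the irreducible
stochastic variability of single trial realisations. The `ly_vs_qaly` row
deliberately scores the model's *life-years* against trial *QALYs*: a
grossly biased predictor (bias 0.688) keeps essentially the same R²
(0.836) but loses a third of its Q² — which is why Q², not R², is the
headline metric. `res$cif_comparisons` additionally reports, per event,
the fraction of annual grid times at which the predicted cumulative
incidence lies inside the observed 95% confidence band.

Sensitivity analyses (`sa1`–`sa8`: second-event counting rules,
alternative utilities, censor-year exclusion, 3.5% discounting, 1- and
3-year horizons) and the standard subgroups (age band, prior
cardiovascular disease, diabetes duration) are selected via
`analyses = ...` and reported in the same table; see
`analysis_catalogue()`.

## Layout

- `R/` — accounting (`qaly.R`, `utility-table.R`), metrics (`metrics.R`),
  engine (`risk-equations.R`, `microsim.R`), incidence
  (`cum-incidence.R`), generator (`synthetic-trial.R`), pipeline
  (`pipeline.R`)
- `vignettes/qaly-validation.Rmd` — the methods write-up: conventions,
  defaults, design decisions, limitations
- `inst/extdata/synthetic_trial_n50/` — a small fully synthetic example
  trial (CSV/YAML, regenerable byte-identically from its manifest seed)
- `exec/qalyval` — CLI: `synth | simulate | validate | report`
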