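tab <- default_utility_table()

test_that("annual probabilities follow the declared link functions", {
  eqs <- risk_equation_set(list(
    MI = list(form = "logistic", coefficients = c(intercept = 0)),
    STROKE = list(form = "logistic", coefficients = c(intercept = 1.2)),
    CHF = list(form = "logistic", coefficients = c(intercept = -1e6)),
    DEATH = list(form = "cloglog", coefficients = c(intercept = -2))))
  p <- annual_probabilities(list(), eqs)
  expect_equal(unname(p["MI"]), 0.5)
  expect_equal(unname(p["STROKE"]), 1 / (1 + exp(-1.2)))
  expect_equal(unname(p["CHF"]), 0)
  expect_equal(unname(p["DEATH"]), 1 - exp(-exp(-2)))
  expect_true(all(p >= 0 & p <= 1))
  # covariates and history terms resolve from the supplied state
  eqs2 <- risk_equation_set(list(
    MI = list(form = "logistic",
              coefficients = c(intercept = -2, age = 0.01, hist_MI = 0.5))))
  expect_equal(unname(annual_probabilities(list(age = 60, hist_MI = 1), eqs2)),
               plogis(-2 + 0.6 + 0.5))
  expect_error(annual_probabilities(list(age = 60), eqs2), "hist_MI")
})

test_that("equation construction is validated", {
  expect_error(risk_equation_set(list(FOO = list(
    form = "logistic", coefficients = c(intercept = 0)))), "unknown")
  expect_error(risk_equation_set(list(ULCER = list(
    form = "logistic", coefficients = c(intercept = 0),
    second_event = TRUE))), "second_event")
  expect_error(risk_equation_set(list(MI = list(
    form = "logistic", coefficients = 1:2))), "named")
})

test_that("risk equation sets round-trip through YAML", {
  eqs <- default_truth_equations()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_risk_equations(eqs, path)
  back <- read_risk_equations(path)
  expect_equal(back$equations, eqs$equations)
})

test_that("degenerate simulations are exact", {
  rec <- simple_patient(censor_time = 3)
  rp <- run_patient(rec, zero_eqs(), tab, sim_config(n_loops = 50, seed = 4))
  expect_equal(rp$mean_qalys, 3 * 0.807)
  expect_equal(rp$mean_life_years, 3)
  expect_true(all(rp$cum_incidence$mean_cum_events == 0 |
                    rp$cum_incidence$event %in% c("DEATH", "ANY_EVENT")))
  # certain immediate death: half a life-year
  certain <- risk_equation_set(list(
    DEATH = list(form = "logistic", coefficients = c(intercept = 1e6))))
  lo <- simulate_loop(rec, certain, tab, sim_config(seed = 1))
  expect_equal(lo$death_cycle, 1L)
  expect_equal(lo$life_years, 0.5)
  expect_equal(lo$qalys, 0.5 * 0.807)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  eqs <- default_truth_equations()
  rec <- simple_patient(censor_time = 6, prior = c(MI = TRUE))
  a <- simulate_loop(rec, eqs, tab, sim_config(seed = 77))
  b <- simulate_loop(rec, eqs, tab, sim_config(seed = 77))
  expect_identical(a, b)
  ra <- run_patient(rec, eqs, tab, sim_config(n_loops = 500, seed = 88))
  rb <- run_patient(rec, eqs, tab, sim_config(n_loops = 500, seed = 88))
  expect_identical(ra, rb)
  rc <- run_patient(rec, eqs, tab, sim_config(n_loops = 500, seed = 89))
  expect_false(identical(ra$mean_qalys, rc$mean_qalys))
})

test_that("loops respect death and occurrence caps", {
  eqs <- risk_equation_set(list(
    MI = list(form = "logistic", coefficients = c(intercept = 2),
              second_event = TRUE),
    ULCER = list(form = "logistic", coefficients = c(intercept = 2)),
    DEATH = list(form = "logistic", coefficients = c(intercept = -1))))
  for (seed in 1:10) {
    lo <- simulate_loop(simple_patient(censor_time = 7), eqs, tab,
                        sim_config(seed = seed))
    if (!is.na(lo$death_cycle)) {
      expect_true(all(lo$events$year_index <= lo$death_cycle))
    }
    n_mi <- sum(lo$events$event_type == "MI")
    expect_lte(n_mi, 2)
    expect_lte(sum(lo$events$event_type == "ULCER"), 1)
  }
  # mean cumulative incidence is non-decreasing and bounded by the cap
  rp <- run_patient(simple_patient(censor_time = 7), eqs, tab,
                    sim_config(n_loops = 2000, seed = 3))
  for (e in unique(rp$cum_incidence$event)) {
    cum <- rp$cum_incidence$mean_cum_events[rp$cum_incidence$event == e]
    expect_true(all(diff(cum) >= 0))
  }
  mi_cum <- rp$cum_incidence$mean_cum_events[rp$cum_incidence$event == "MI"]
  expect_lte(max(mi_cum), 2)
})

test_that("constant-hazard expectation matches the closed form", {
  p <- 0.15; d <- 0.165; u0 <- 0.807; H <- 7
  rec <- simple_patient(censor_time = H)
  rp <- run_patient(rec, const_hazard_eqs(p), one_decrement_table("STROKE", d),
                    sim_config(n_loops = 20000, seed = 31, horizon_years = H))
  expected <- const_hazard_expected_qalys(p, H, u0, d)
  # per-loop QALY spread bounds the Monte Carlo standard error
  worst_sd <- d * H / 2  # generous bound on sd of the per-loop QALYs
  expect_lt(abs(rp$mean_qalys - expected), 3 * worst_sd / sqrt(20000))
  # predicted first-event cumulative incidence matches 1 - (1-p)^t
  cif <- rp$cum_incidence$mean_cum_first[rp$cum_incidence$event == "STROKE"]
  expect_equal(cif, 1 - (1 - p)^(1:H), tolerance = 0.02)
})

test_that("two seeds differ by Monte-Carlo order only", {
  p <- 0.15
  cfgs <- list(sim_config(n_loops = 10000, seed = 1),
               sim_config(n_loops = 10000, seed = 2))
  means <- vapply(cfgs, function(cfg) {
    run_patient(simple_patient(censor_time = 7), const_hazard_eqs(p),
                one_decrement_table("STROKE"), cfg)$mean_qalys
  }, numeric(1))
  expect_lt(abs(diff(means)), 6 * 0.165 * 7 / 2 / sqrt(10000))
})

test_that("convergence diagnostic reports shrinking running error", {
  rec <- simple_patient(censor_time = 5)
  # degenerate process: flat at the exact value from the first grid point
  cd0 <- convergence_diagnostic(rec, zero_eqs(), tab,
                                loop_grid = c(100, 500, 1000),
                                config = sim_config(seed = 2))
  expect_true(all(cd0$running_mean_qalys == 5 * 0.807))
  expect_true(all(cd0$converged[-1]))
  # stochastic process: standard error shrinks with the loop count
  cd <- convergence_diagnostic(rec, const_hazard_eqs(0.2),
                               one_decrement_table("STROKE"),
                               loop_grid = c(1000, 5000, 20000),
                               config = sim_config(seed = 6))
  expect_true(all(diff(cd$se_qalys) < 0))
})
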