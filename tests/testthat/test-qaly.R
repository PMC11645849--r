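tab <- default_utility_table()

test_that("utility traces follow the annual-cycle accounting conventions", {
  # event-free follow-up at the baseline utility
  tr <- build_utility_trace(simple_patient(censor_time = 2), tab)
  expect_equal(tr$utilities, c(0.807, 0.807))
  expect_equal(tr$weights, c(1, 1))

  # MI decrements the event year only
  p <- simple_patient(censor_time = 3,
                      events = data.frame(event_type = "MI",
                                          occurrence_index = 1,
                                          year_index = 1))
  tr <- build_utility_trace(p, tab)
  expect_equal(tr$utilities, c(0.742, 0.807, 0.807))

  # stroke year 2 (permanent), renal failure year 3 (permanent),
  # death during year 4 (half-cycle weight)
  p <- simple_patient(censor_time = 5, death_time = 3.5,
                      events = data.frame(
                        event_type = c("STROKE", "RENAL_FAILURE"),
                        occurrence_index = c(1, 1),
                        year_index = c(2, 3)))
  tr <- build_utility_trace(p, tab)
  expect_equal(tr$utilities, c(0.807, 0.642, 0.312, 0.312))
  expect_equal(tr$weights, c(1, 1, 1, 0.5))
  expect_equal(qalys_from_trace(tr), 0.807 + 0.642 + 0.312 + 0.5 * 0.312)
})

test_that("trace-to-QALY reduction handles discounting and weights", {
  expect_equal(qalys_from_trace(list(utilities = c(0.807, 0.807),
                                     weights = c(1, 1))), 1.614)
  # first year undiscounted, later years discounted at 3.5%
  got <- qalys_from_trace(list(utilities = c(1, 1, 1), weights = c(1, 1, 0.5)),
                          qaly_options(discount_rate = 0.035))
  expect_equal(got, 1 + 1 / 1.035 + 0.5 / 1.035^2)
  expect_equal(round(got, 4), 2.4329)
})

test_that("trial QALYs accrue fractional censor years and half death years", {
  expect_equal(trial_qalys(simple_patient(censor_time = 2.5), tab),
               0.807 * 2.5)
  # life-years: death at 3.2 y falls in cycle 4 with weight 0.5
  expect_equal(trial_qalys(simple_patient(censor_time = 4, death_time = 3.2),
                           tab, qaly_options(life_years_mode = TRUE)),
               3.5)
})

test_that("occurrence counting rules distinguish history and second events", {
  two_strokes <- data.frame(event_type = "STROKE", occurrence_index = 1:2,
                            year_index = c(1, 2))
  p_hist <- simple_patient(censor_time = 3, events = two_strokes,
                           prior = c(STROKE = TRUE))
  # default rule: prior stroke counts, so only the first on-study stroke
  # (the second overall) decrements; the third overall does not
  got_default <- trial_qalys(p_hist, tab)
  expect_equal(got_default, (0.807 - 0.165) + (0.807 - 0.165) +
                 (0.807 - 0.165))
  # counting since randomization regardless of history: both decrement
  got_sa1 <- trial_qalys(p_hist, tab,
                         qaly_options(second_event_rule =
                                        "count_all_since_randomization"))
  p_nohist <- simple_patient(censor_time = 3, events = two_strokes)
  expect_equal(got_sa1, trial_qalys(p_nohist, tab))
  expect_equal(got_sa1, (0.807 - 0.165) + (0.807 - 0.330) + (0.807 - 0.330))
})

test_that("third MI/stroke/amputation and second ulcer change nothing", {
  base_events <- data.frame(event_type = c("MI", "MI", "ULCER"),
                            occurrence_index = c(1, 2, 1),
                            year_index = c(1, 2, 3))
  extra_events <- rbind(base_events,
                        data.frame(event_type = c("MI", "ULCER"),
                                   occurrence_index = c(3, 2),
                                   year_index = c(4, 4)))
  p1 <- simple_patient(censor_time = 5, events = base_events)
  p2 <- simple_patient(censor_time = 5, events = extra_events)
  expect_equal(trial_qalys(p1, tab), trial_qalys(p2, tab))
})

test_that("model QALYs average loops with per-loop censor-year death adjustment", {
  # degenerate loops: all event-free and death-free
  loops <- replicate(5, list(events = NULL, death_cycle = NA), simplify = FALSE)
  expect_equal(model_qalys(loops, simple_patient(censor_time = 3), tab),
               3 * 0.807)
  # one loop dies in year 1 (half-cycle), one survives the 1.0-y censor year
  loops2 <- list(list(events = NULL, death_cycle = 1L),
                 list(events = NULL, death_cycle = NA))
  expect_equal(model_qalys(loops2, simple_patient(censor_time = 1), tab),
               (0.5 * 0.807 + 0.807) / 2)
  expect_error(model_qalys(list(), simple_patient(censor_time = 1), tab),
               "at least one")
  # decedents are truncated at the administrative end, not the death time
  p_dead <- simple_patient(censor_time = 4, death_time = 1.5, admin = 2)
  expect_equal(model_qalys(loops, p_dead, tab), 2 * 0.807)
})

test_that("QALY invariants hold across option settings", {
  p <- simple_patient(censor_time = 4.3, death_time = NA,
                      events = data.frame(event_type = c("STROKE", "CHF"),
                                          occurrence_index = c(1, 1),
                                          year_index = c(1, 3)))
  q_base <- trial_qalys(p, tab)
  # QALYs are non-increasing in any decrement
  bigger <- one_decrement_table("STROKE", d = 0.4)
  expect_lt(trial_qalys(p, bigger), trial_qalys(p, one_decrement_table("STROKE")))
  # life-years dominate QALYs when utilities <= 1
  expect_gte(trial_qalys(p, tab, qaly_options(life_years_mode = TRUE)), q_base)
  # zero decrements: QALYs = baseline * life-years exactly
  expect_equal(trial_qalys(p, zero_decrement_table()),
               0.807 * trial_qalys(p, tab, qaly_options(life_years_mode = TRUE)))
  # zero discount rate reproduces the plain sum bit-identically
  expect_identical(trial_qalys(p, tab, qaly_options(discount_rate = 0)), q_base)
  # horizon 1 equals the first weighted trace term
  tr <- build_utility_trace(p, tab)
  expect_equal(trial_qalys(p, tab, qaly_options(horizon_years = 1)),
               tr$utilities[1] * tr$weights[1])
  # censor-year exclusion drops exactly the fractional term
  tr_full <- qalys_from_trace(tr)
  tr_excl <- trial_qalys(p, tab, qaly_options(exclude_censor_year = TRUE))
  expect_equal(tr_full - tr_excl, tr$utilities[5] * tr$weights[5])
})

test_that("utilities may go negative under stacked decrements", {
  stack <- data.frame(event_type = c("STROKE", "RENAL_FAILURE",
                                     "AMPUTATION", "ULCER"),
                      occurrence_index = 1,
                      year_index = c(1, 1, 1, 1))
  tr <- build_utility_trace(simple_patient(censor_time = 2, events = stack), tab)
  expect_equal(tr$utilities[1], 0.807 - 0.165 - 0.330 - 0.280 - 0.170)
  expect_lt(tr$utilities[1], 0)
})
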