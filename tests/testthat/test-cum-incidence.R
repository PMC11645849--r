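test_that("hand-worked Aalen-Johansen example", {
  # 3 patients: event at t=1, death at t=2, censor at t=3
  tr <- tiny_trial(event_time = c(1, NA, NA), death_time = c(NA, 2, NA),
                   censor_time = c(3, 2, 3))
  cif <- observed_cif(tr, "MI", "no_history")
  expect_equal(cif$estimate[cif$time == 0], 0)
  expect_equal(cif$estimate[cif$time == 1], 1 / 3)
  expect_equal(max(cif$estimate), 1 / 3)
  expect_true(all(diff(cif$estimate) >= 0))
  expect_true(all(cif$lo <= cif$estimate & cif$estimate <= cif$hi))
})

test_that("without competing deaths the CIF equals 1 minus Kaplan-Meier", {
  set.seed(21)
  n <- 80
  etime <- sample(1:6, n, replace = TRUE)
  etime[runif(n) < 0.4] <- NA
  ctime <- runif(n, 1, 7)
  tr <- tiny_trial(event_time = etime, censor_time = ctime)
  cif <- observed_cif(tr, "MI", "no_history")
  has <- !is.na(etime)
  km <- survival::survfit(
    survival::Surv(ifelse(has, etime, ctime), as.integer(has)) ~ 1)
  at <- km$time[km$n.event > 0]
  expect_equal(cif$estimate[match(at, cif$time)], 1 - km$surv[km$n.event > 0],
               tolerance = 1e-12)
})

test_that("estimator equals the counting-process oracle on small samples", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    etime <- sample(1:4, n, replace = TRUE)
    etime[runif(n) < 0.5] <- NA
    dtime <- round(runif(n, 0.5, 5), 1)
    dtime[runif(n) < 0.6] <- NA
    ctime <- round(runif(n, 0.5, 5), 1)
    tr <- tiny_trial(event_time = etime, death_time = dtime,
                     censor_time = pmax(ctime, dtime, na.rm = TRUE))
    cif <- tryCatch(
      suppressWarnings(observed_cif(tr, "MI", "no_history")),
      error = function(e) NULL)
    if (is.null(cif)) next
    # reconstruct the (time, status) data exactly as the estimator defines it
    death <- ifelse(!is.na(dtime), dtime, NA)
    dcyc <- ceiling(death - 1e-9)
    event_wins <- !is.na(etime) & (is.na(death) | etime <= dcyc)
    death_first <- !is.na(death) & !event_wins
    time <- ifelse(event_wins, etime,
                   ifelse(death_first, death,
                          pmax(ctime, dtime, na.rm = TRUE)))
    status <- ifelse(event_wins, 1L, ifelse(death_first, 2L, 0L))
    if (sum(status == 1) == 0) next
    orc <- aj_oracle(time, status, eval_times = cif$time[cif$time > 0])
    expect_equal(cif$estimate[cif$time > 0], orc$cif1, tolerance = 1e-10)
    # probability conservation at every evaluated time
    expect_equal(orc$cif1 + orc$cif2 + orc$surv, rep(1, nrow(orc)),
                 tolerance = 1e-10)
  }
})

test_that("estimator agrees with cmprsk on a moderate sample", {
  skip_if_not_installed("cmprsk")
  set.seed(55)
  n <- 150
  etime <- sample(1:5, n, replace = TRUE)
  etime[runif(n) < 0.5] <- NA
  dtime <- round(runif(n, 0.5, 6), 2)
  dtime[runif(n) < 0.6] <- NA
  ctime <- round(runif(n, 0.5, 6), 2)
  ctime <- pmax(ctime, dtime, na.rm = TRUE)
  tr <- tiny_trial(event_time = etime, death_time = dtime, censor_time = ctime)
  cif <- observed_cif(tr, "MI", "no_history")
  death <- dtime
  dcyc <- ceiling(death - 1e-9)
  event_wins <- !is.na(etime) & (is.na(death) | etime <= dcyc)
  death_first <- !is.na(death) & !event_wins
  time <- ifelse(event_wins, etime, ifelse(death_first, death, ctime))
  status <- ifelse(event_wins, 1L, ifelse(death_first, 2L, 0L))
  ci <- cmprsk::cuminc(time, status, cencode = 0)
  at <- cif$time[cif$time > 0]
  ref <- cmprsk::timepoints(ci, at)$est["1 1", ]
  expect_equal(unname(cif$estimate[cif$time > 0]), unname(ref),
               tolerance = 1e-8)
})

test_that("subset rules split first and second event populations", {
  tr <- tiny_trial(event_time = c(1, 2, NA, NA), censor_time = rep(4, 4),
                   prior_flag = c(FALSE, TRUE, FALSE, TRUE))
  first <- observed_cif(tr, "MI", "no_history")
  second <- observed_cif(tr, "MI", "with_history")
  expect_equal(attr(first, "n"), 2)
  expect_equal(attr(second, "n"), 2)
  expect_equal(max(first$estimate), 0.5)   # event among the 2 no-history
  expect_equal(max(second$estimate), 0.5)  # event among the 2 with-history
  expect_error(observed_cif(tiny_trial(censor_time = 2), "MI", "with_history"),
               "empty")
  expect_warning(observed_cif(tr, "STROKE", "no_history"), "flat zero")
})

test_that("death and any-event composite curves are available", {
  tr <- tiny_trial(event_time = c(1, NA, NA, NA), death_time = c(NA, 1.5, NA, NA),
                   censor_time = c(4, 4, 4, 2))
  d <- observed_cif(tr, "DEATH", "all")
  expect_equal(d$estimate[d$time == 1.5], 0.25)
  any <- observed_cif(tr, "ANY_EVENT", "all")
  # first of any type: event at 1 (1/4), then death at 1.5 (1/4 * scaled)
  expect_equal(any$estimate[any$time == 1], 0.25)
  expect_equal(max(any$estimate), 0.5)
})

test_that("predicted incidence curves divide events by starting cohort", {
  expect_equal(predicted_cif(c(0, 0, 0))$estimate, rep(0, 4))
  pc <- predicted_cif(c(10, 18, 24), n_at_start = 100, event = "MI")
  expect_equal(pc$estimate, c(0, 0.1, 0.18, 0.24))
  expect_true(all(pc$estimate <= 1))
  expect_error(predicted_cif(c(2, 1)), "non-decreasing")
  expect_error(predicted_cif(c(1, 2), n_at_start = 0), "n_at_start")
})

test_that("curve comparison flags containment in the observed CI", {
  obs <- observed_cif(tiny_trial(event_time = c(1, 2, NA, NA, NA, NA),
                                 censor_time = rep(4, 6)),
                      "MI", "no_history")
  grid_est <- approx(obs$time, obs$estimate, xout = 1:4, method = "constant",
                     rule = 2)$y
  pred_same <- predicted_cif(grid_est[1:4] * 6 / 6, event = "MI")
  cmp <- compare_curves(obs, pred_same)
  expect_equal(cmp$fraction_in_ci, 1)
  pred_off <- predicted_cif(rep(0.999, 4), event = "MI")
  expect_equal(compare_curves(obs, pred_off)$fraction_in_ci, 0)
  pred_other <- predicted_cif(grid_est[1:4], event = "STROKE")
  expect_error(compare_curves(obs, pred_other), "different events")
})
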