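test_that("metric point values match hand computations", {
  p <- paired_predictions(M = c(1.1, 1.9, 3.2, 3.8), T = c(1, 2, 3, 4))
  expect_equal(bias(paired_predictions(M = c(2, 3), T = c(1, 1))), 1.5)
  expect_equal(bias(p), mean(c(0.1, -0.1, 0.2, -0.2)))
  expect_equal(mse(p), 0.025)
  expect_equal(mae(p), 0.15)
  expect_equal(q_squared(p), 1 - 0.025 / (5 / 3))
  expect_equal(r_squared(paired_predictions(M = c(1, 2, 3),
                                            T = c(1, 3, 2)))$r2, 0.25)
  ident <- paired_predictions(M = c(1, 2, 3), T = c(1, 2, 3))
  expect_equal(bias(ident), 0)
  expect_equal(mse(ident), 0)
  expect_equal(q_squared(ident), 1)
})

test_that("R-squared is affine-invariant and OLS-optimal", {
  set.seed(42)
  M <- rnorm(200); T_ <- 2 * M + 1 + rnorm(200, sd = 0.3)
  p <- paired_predictions(M, T_)
  r <- r_squared(p)
  # perfect affine relation gives r2 = 1
  expect_equal(r_squared(paired_predictions(M, 2 * M + 1))$r2, 1)
  # invariant to shifting and scaling the predictions
  expect_equal(r_squared(paired_predictions(M + 10, T_))$r2, r$r2)
  expect_equal(r_squared(paired_predictions(3 * M - 2, T_))$r2, r$r2)
  # agrees with lm()
  fit <- lm(T_ ~ M)
  expect_equal(r$r2, summary(fit)$r.squared)
  expect_equal(r$fit$slope, unname(coef(fit)[2]))
  expect_equal(r$fit$intercept, unname(coef(fit)[1]))
})

test_that("degenerate variance cases are handled as declared", {
  expect_warning(r0 <- r_squared(paired_predictions(M = c(1, 1, 1),
                                                    T = c(1, 2, 3))),
                 "zero variance")
  expect_equal(r0$r2, 0)
  expect_error(r_squared(paired_predictions(M = c(1, 2, 3), T = c(2, 2, 2))),
               "zero variance")
  expect_error(q_squared(paired_predictions(M = c(1, 2, 3), T = c(2, 2, 2))),
               "zero variance")
  expect_error(q_squared_from_summary(0.1, 0), "sd")
  expect_error(q_squared_from_summary(-0.1, 1), "mse")
})

test_that("Q-squared from summary statistics reduces correctly", {
  expect_equal(q_squared_from_summary(0, 2), 1)
  sd <- 1.3
  expect_equal(q_squared_from_summary(sd^2, sd), 0)
  # recomputing from a sample's own MSE and SD matches the sample Q2
  set.seed(7)
  M <- rnorm(50, 2); T_ <- rnorm(50, 2)
  p <- paired_predictions(M, T_)
  expect_equal(q_squared_from_summary(mse(p), sd(T_)), q_squared(p))
})

test_that("all five metrics agree with an elementwise loop oracle", {
  set.seed(123)
  for (rep in 1:5) {
    n <- sample(10:1000, 1)
    M <- rnorm(n, 2, 1.5); T_ <- rnorm(n, 2, 1.2)
    p <- paired_predictions(M, T_)
    b <- s <- a <- 0
    for (i in seq_len(n)) {
      b <- b + (M[i] - T_[i])
      s <- s + (M[i] - T_[i])^2
      a <- a + abs(M[i] - T_[i])
    }
    Tbar <- sum(T_) / n
    ss <- 0
    for (i in seq_len(n)) ss <- ss + (T_[i] - Tbar)^2
    expect_equal(bias(p), b / n, tolerance = 1e-12)
    expect_equal(mse(p), s / n, tolerance = 1e-12)
    expect_equal(mae(p), a / n, tolerance = 1e-12)
    expect_equal(q_squared(p), 1 - (s / n) / (ss / (n - 1)), tolerance = 1e-12)
    expect_equal(r_squared(p)$r2, cor(M, T_)^2, tolerance = 1e-12)
    # structural relations
    expect_lte(mae(p), sqrt(mse(p)))
    expect_equal(mse(p), bias(p)^2 + mean((M - T_ - bias(p))^2))
  }
})

test_that("a constant shift leaves R-squared but strictly lowers Q-squared", {
  set.seed(99)
  T_ <- rnorm(300, 3, 1)
  M <- T_ + rnorm(300, 0, 0.2)
  M <- M - mean(M - T_)  # exactly unbiased
  p0 <- paired_predictions(M, T_)
  p_shift <- paired_predictions(M + 0.5, T_)
  expect_equal(r_squared(p_shift)$r2, r_squared(p0)$r2)
  expect_lt(q_squared(p_shift), q_squared(p0))
  expect_equal(mse(p_shift), mse(p0) + 0.25)
})

test_that("duplicating the sample preserves N-denominator metrics", {
  set.seed(5)
  M <- rnorm(40); T_ <- rnorm(40)
  p <- paired_predictions(M, T_)
  p2 <- paired_predictions(c(M, M), c(T_, T_))
  expect_equal(bias(p2), bias(p))
  expect_equal(mse(p2), mse(p))
  expect_equal(mae(p2), mae(p))
  expect_equal(r_squared(p2)$r2, r_squared(p)$r2)
  # q2 differs only through the (N-1) variance denominator
  n <- 40
  expect_equal(1 - q_squared(p2),
               (1 - q_squared(p)) * (2 * n - 1) / (2 * (n - 1)))
})

test_that("evaluate reports overall plus per-subgroup metrics", {
  set.seed(11)
  n <- 200
  age_band <- rep(c("<65", ">=65"), each = n / 2)
  T_ <- rnorm(n, 3, 1)
  M <- T_ + rnorm(n, 0, 0.2) + ifelse(age_band == ">=65", -0.8, 0)
  p <- paired_predictions(M, T_, subgroups = data.frame(age_band = age_band))
  rep_ <- evaluate(p)
  overall <- rep_[rep_$subgroup_var == "overall", ]
  expect_equal(overall$n, n)
  expect_equal(overall$q2, q_squared(p))
  sub <- rep_[rep_$subgroup_var == "age_band", ]
  expect_equal(sum(sub$n), n)
  # the miscalibrated band has lower Q-squared
  expect_lt(sub$q2[sub$subgroup == ">=65"], sub$q2[sub$subgroup == "<65"])
  # single-level subgroup equals whole-sample metrics
  p_one <- paired_predictions(M, T_, subgroups = data.frame(g = rep("all", n)))
  r_one <- evaluate(p_one)
  expect_equal(r_one$q2[2], r_one$q2[1])
})

test_that("paired prediction construction validates", {
  expect_error(paired_predictions(1:3, 1:2), "equal length")
  expect_error(paired_predictions(1, 1), "at least 2")
  expect_error(paired_predictions(c(1, NA), c(1, 2)), "missing")
})
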