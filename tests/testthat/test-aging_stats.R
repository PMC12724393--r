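test_that("ols_fit recovers exact and degenerate fits", {
  age <- seq(20, 80, length.out = 30)
  fit <- ols_fit(3 + 2 * age, data.frame(age = age))
  expect_equal(unname(fit$coefficients["age"]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 3, tolerance = 1e-8)

  flat <- ols_fit(rep(5, 30), data.frame(age = age))
  expect_equal(unname(flat$coefficients["age"]), 0)
  expect_equal(unname(flat$p_values["age"]), 1)

  set.seed(1)
  y <- 5 - 0.8 * age + rnorm(30)
  fit2 <- ols_fit(y, data.frame(age = age))
  expect_lt(abs(fit2$coefficients["age"] + 0.8),
            3 * fit2$standard_errors["age"])

  expect_error(ols_fit(y, data.frame(age = age, const = 1)), "constant")
})

test_that("exp_regression is OLS on the log scale and inverts exactly", {
  age <- seq(1, 90, length.out = 40)
  metric <- exp(-3 + 0.04 * age) - 0.01
  fit <- exp_regression(metric, age)
  expect_equal(unname(fit$coefficients["age"]), 0.04, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["(Intercept)"]), -3, tolerance = 1e-8)
  expect_equal(fit$model_kind, "log_linear")

  # all-zero metric: response is the constant ln(0.01), slope 0
  fit0 <- exp_regression(rep(0, 40), age)
  expect_equal(unname(fit0$coefficients["age"]), 0)
  expect_error(exp_regression(c(-1, metric[-1]), age), "non-negative")

  # coefficient-for-coefficient equality with ols_fit on ln(y + 0.01)
  set.seed(2)
  noisy <- pmax(exp(-2 + 0.03 * age + rnorm(40, 0, 0.3)) - 0.01, 0)
  sex <- rep(c(0, 1), 20)
  a <- exp_regression(noisy, age, data.frame(sex = sex))
  b <- ols_fit(log(noisy + 0.01), data.frame(age = age, sex = sex))
  expect_equal(a$coefficients, b$coefficients)
  expect_equal(a$p_values, b$p_values)
})

test_that("bin_delta matches slope arithmetic and exponential convexity", {
  # linear: slope -12.882/yr over a 15-year bin
  age <- seq(0, 100, length.out = 50)
  fit <- ols_fit(1000 - 12.882 * age, data.frame(age = age))
  expect_equal(bin_delta(fit, 30, 15), -193.23, tolerance = 1e-6)

  # log-linear with zero slope: no change in any bin
  m <- rep(2, 50)
  fitz <- exp_regression(m + 0, age)
  expect_equal(bin_delta(fitz, 30, 15), 0, tolerance = 1e-9)

  # convexity: later bins change more when the slope is positive
  grow <- exp(-4 + 0.05 * age) - 0.01
  fitg <- exp_regression(grow, age)
  expect_gt(bin_delta(fitg, 60, 15), bin_delta(fitg, 30, 15))

  # covariate profile is required for log-linear fits with covariates
  fitc <- exp_regression(grow, age, data.frame(cov = rnorm(50)))
  expect_error(bin_delta(fitc, 30, 15), "missing covariate")
  expect_type(bin_delta(fitc, 30, 15, c(cov = 0)), "double")
})

test_that("rank_fit equals the Hodges-Lehmann estimator for a binary predictor", {
  set.seed(4)
  g <- rep(c(0, 1), c(12, 14))
  y <- c(rnorm(12, 0, 1), rnorm(14, 1.3, 1))
  hl <- median(outer(y[g == 1], y[g == 0], "-"))
  fit <- rank_fit(y, data.frame(g = g))
  expect_equal(unname(fit$coefficients["g"]), hl, tolerance = 1e-4)
})

test_that("rank_fit matches OLS on noiseless data and has shift/scale equivariance", {
  age <- seq(1, 50)
  y <- 2 + 0.5 * age
  fit <- rank_fit(y, data.frame(age = age))
  expect_equal(unname(fit$coefficients["age"]), 0.5, tolerance = 1e-6)

  set.seed(6)
  y2 <- 1 + 0.3 * age + rnorm(50)
  f1 <- rank_fit(y2, data.frame(age = age))
  f2 <- rank_fit(y2 + 100, data.frame(age = age))
  f3 <- rank_fit(y2 * 3, data.frame(age = age))
  expect_equal(unname(f1$coefficients["age"]), unname(f2$coefficients["age"]),
               tolerance = 1e-5)
  expect_equal(unname(f3$coefficients["age"]),
               3 * unname(f1$coefficients["age"]), tolerance = 1e-4)
  expect_error(rank_fit(y2[1:5], data.frame(age = age[1:5])), "n >= 10")
})

test_that("rank_fit resists gross outliers better than OLS", {
  set.seed(10)
  hits <- 0L
  for (r in 1:20) {
    age <- runif(200, 0, 100)
    y <- 1 + 0.2 * age + rnorm(200)
    out <- sample(200, 20)
    y[out] <- y[out] + sample(c(-1, 1), 20, TRUE) * runif(20, 30, 80)
    b_rank <- rank_fit(y, data.frame(age = age))$coefficients["age"]
    b_ols <- ols_fit(y, data.frame(age = age))$coefficients["age"]
    if (abs(b_rank - 0.2) < abs(b_ols - 0.2)) hits <- hits + 1L
  }
  expect_gte(hits, 15L)
})

test_that("kruskal_dunn handles identical groups and matches hand ranks", {
  same <- list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1))
  r <- kruskal_dunn(same)
  expect_equal(r$H_statistic, 0)
  expect_true(all(r$pairwise$adjusted_p == 1))

  two <- list(lo = c(1, 2, 3), hi = c(10, 11, 12))
  r2 <- kruskal_dunn(two)
  # pooled ranks 1..6: mean ranks 2 and 5; no ties
  z_hand <- (5 - 2) / sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(abs(r2$pairwise$z), z_hand, tolerance = 1e-12)
  expect_equal(r2$pairwise$adjusted_p, pmin(1, r2$pairwise$raw_p * 1))
  expect_error(kruskal_dunn(list(a = 1)), "two non-empty")
})

test_that("dunn adjustment controls the family-wise error on null groups", {
  set.seed(12)
  reject <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    groups <- split(rnorm(60), rep(1:4, each = 15))
    res <- kruskal_dunn(groups)
    if (any(res$pairwise$adjusted_p < 0.05)) reject <- reject + 1L
  }
  # binomial tolerance around alpha = 0.05 (Dunn tests are conservative)
  expect_lte(reject / reps, 0.05 + 2.5 * sqrt(0.05 * 0.95 / reps))
})

test_that("chisq_yates matches closed forms and is symmetric", {
  r <- chisq_yates(matrix(c(50, 0, 0, 50), 2))
  expect_equal(r$statistic, 96.04, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-20)

  flat <- chisq_yates(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  m <- matrix(c(73, 9, 6, 12), 2)
  expect_equal(chisq_yates(m)$statistic, chisq_yates(t(m))$statistic)
  expect_equal(chisq_yates(m)$statistic,
               chisq_yates(m[, 2:1][2:1, ])$statistic)
  expect_error(chisq_yates(matrix(c(1, 1, 0, 0), 2)), "zero margin")
})

test_that("bonferroni reproduces the scan thresholds", {
  expect_equal(signif(bonferroni(0.05, 38), 3), 1.32e-3)
  expect_equal(bonferroni(0.05, 2), 0.025)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(0, 5), "alpha")
  expect_error(bonferroni(0.05, 0), "m must be")
})
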