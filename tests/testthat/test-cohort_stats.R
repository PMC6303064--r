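test_that("percent change follows its definition and invariances", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(50, 75), 50)
  expect_equal(percent_change(798024.63, 780135.80), -2.2416,
               tolerance = 1e-4)
  # scale invariance
  set.seed(1)
  b <- runif(20, 10, 100); f <- runif(20, 10, 100)
  expect_equal(percent_change(3.7 * b, 3.7 * f), percent_change(b, f),
               tolerance = 1e-12)
  expect_error(percent_change(0, 5), "positive")
  expect_error(percent_change(-1, 5), "positive")
})

test_that("paired t-test matches the textbook formula", {
  b <- c(10, 12, 9)
  f <- c(11, 15, 9.5)
  res <- paired_t_test(b, f)
  want <- oracle_paired_t(b, f)
  expect_equal(res$t_statistic, want$t, tolerance = 1e-12)
  expect_equal(res$p_value, want$p, tolerance = 1e-12)
  expect_equal(res$mean_diff, mean(f - b))
  expect_equal(res$direction, "increase")
  expect_false(res$degenerate)

  # identical vectors: degenerate flag, no NaN propagation
  same <- paired_t_test(b, b)
  expect_true(same$degenerate)
  expect_equal(same$mean_diff, 0)
  expect_true(is.na(same$t_statistic))

  expect_error(paired_t_test(1:3, 1:4), "equal length")
  expect_error(paired_t_test(1, 2), "at least 2")
})

test_that("paired t-test detects the simulated GM decline reliably", {
  hits <- 0
  for (s in 1:100) {
    co <- simulate_cohort(20, seed = s)
    res <- paired_t_test(co$gm_baseline, co$gm_followup)
    if (res$p_value < 0.05 && res$direction == "decrease") hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("Spearman rho handles monotone, reversed and tied data", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, rev(x))$rho, -1)

  # tie handling against the explicit average-rank oracle
  xt <- c(1, 2, 2, 3, 5, 7)
  yt <- c(3, 1, 4, 4, 6, 8)
  res <- spearman_rho(xt, yt)
  want <- oracle_spearman(xt, yt)
  expect_equal(res$rho, want$rho, tolerance = 1e-12)
  expect_equal(res$p_value, want$p, tolerance = 1e-12)

  expect_true(spearman_rho(rep(1, 5), 1:5)$degenerate)
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("statistics agree with reference implementations on random data", {
  set.seed(2024)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    b <- rnorm(n); f <- rnorm(n)
    res <- paired_t_test(b, f)
    want <- oracle_paired_t(b, f)
    expect_equal(res$t_statistic, want$t, tolerance = 1e-8)
    expect_equal(res$p_value, want$p, tolerance = 1e-8)

    x <- sample(round(rnorm(n), 1), n)  # rounded values induce ties
    y <- rnorm(n)
    rs <- spearman_rho(x, y)
    if (!rs$degenerate) {
      ws <- oracle_spearman(x, y)
      expect_equal(rs$rho, ws$rho, tolerance = 1e-8)
      expect_equal(rs$p_value, ws$p, tolerance = 1e-8)
    }
  }
})

test_that("PBVC regression reproduces OLS exactly", {
  set.seed(7)
  n <- 50
  dat <- data.frame(pbvc = rnorm(n), age = rnorm(n, 40, 8),
                    disease_duration = runif(n, 1, 20),
                    t2_lesion_volume = rlnorm(n, 2, 0.5))

  # y identical to a covariate: slope 1, R^2 1
  dat1 <- dat; dat1$pbvc <- dat1$age
  # lm warns about the deliberately perfect fit
  fit1 <- suppressWarnings(regress_pbvc(dat1, "age")[["age"]])
  expect_equal(fit1$terms$coefficient, 1, tolerance = 1e-10)
  expect_equal(fit1$r_squared, 1, tolerance = 1e-10)

  # univariate R^2 equals the squared Pearson correlation
  fit_u <- regress_pbvc(dat, c("age", "disease_duration"))
  for (tm in c("age", "disease_duration")) {
    expect_equal(fit_u[[tm]]$r_squared, cor(dat$pbvc, dat[[tm]])^2,
                 tolerance = 1e-10)
  }

  # multivariate fit against the normal-equations oracle
  fit_m <- regress_pbvc(dat, c("age", "disease_duration",
                               "t2_lesion_volume"), multivariate = TRUE)[[1]]
  want <- oracle_ols(dat$pbvc,
                     as.matrix(dat[c("age", "disease_duration",
                                     "t2_lesion_volume")]))
  expect_equal(fit_m$terms$coefficient, unname(want$beta[-1]),
               tolerance = 1e-8)
  expect_equal(fit_m$terms$ci_low, unname(want$ci_low[-1]), tolerance = 1e-8)
  expect_equal(fit_m$terms$ci_high, unname(want$ci_high[-1]),
               tolerance = 1e-8)
  expect_equal(fit_m$terms$p_value, unname(want$p[-1]), tolerance = 1e-8)
  expect_equal(fit_m$r_squared, want$r2, tolerance = 1e-10)
  expect_true(all(fit_m$terms$ci_low <= fit_m$terms$coefficient &
                    fit_m$terms$coefficient <= fit_m$terms$ci_high))
})

test_that("regression validates its design", {
  set.seed(3)
  dat <- data.frame(pbvc = rnorm(20), age = rnorm(20, 40, 8))
  dat$age2 <- 2 * dat$age
  expect_error(regress_pbvc(dat, c("age", "age2"), multivariate = TRUE),
               "collinear")
  expect_error(regress_pbvc(dat, "weight"), "missing covariate")
  expect_error(regress_pbvc(dat[1:2, ], "age"), "too few")
})

test_that("race covariates are coded against the largest category", {
  set.seed(8)
  co <- simulate_cohort(60, seed = 8)
  fit <- regress_pbvc(co, "race")[["race"]]
  biggest <- names(which.max(table(co$race)))
  expect_false(any(grepl(biggest, fit$terms$name, fixed = TRUE)))
  expect_equal(nrow(fit$terms), length(unique(co$race)) - 1L)
})

test_that("CI coverage of a null coefficient is nominal", {
  covers <- 0
  for (s in 1:100) {
    set.seed(s + 500)
    n <- 200
    x <- rnorm(n)
    y <- rnorm(n)                       # independent of x: true slope 0
    fit <- regress_pbvc(data.frame(pbvc = y, x = x), "x")[["x"]]
    if (fit$terms$ci_low <= 0 && 0 <= fit$terms$ci_high) covers <- covers + 1
  }
  expect_gte(covers, 90)               # ~95% nominal
  expect_lte(covers, 100)
})

test_that("a configured age effect on PBVC is recovered by regression", {
  co <- simulate_cohort(150, seed = 42)
  truth <- cohort_effects()$pbvc_age_slope
  fit <- regress_pbvc(co, "age")[["age"]]
  expect_true(fit$terms$ci_low <= truth && truth <= fit$terms$ci_high)
})
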