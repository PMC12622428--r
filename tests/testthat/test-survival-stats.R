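test_that("product-limit estimator matches hand calculations", {
  km <- km_estimate(survival_records(1:3, rep(TRUE, 3)))
  expect_equal(km$table$surv, c(2 / 3, 1 / 3, 0))
  # censored at 1, event at 2: S(1) = 1, S(2) = 0
  km2 <- km_estimate(survival_records(c(1, 2), c(FALSE, TRUE)))
  expect_equal(km_survival_at(km2, c(1, 2)), c(1, 0))
  # all censored: S identically 1
  km3 <- km_estimate(survival_records(c(3, 7, 9), rep(FALSE, 3)))
  expect_true(all(km3$table$surv == 1))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(13)
  times <- round(rexp(40, 0.1) + 0.5, 1)
  km <- km_estimate(survival_records(times, rep(TRUE, 40)))
  for (t in c(2, 5, 10, 20))
    expect_equal(km_survival_at(km, t), empirical_surv(times, t))
})

test_that("KM agrees with the reference implementation under censoring", {
  skip_if_not_installed("survival")
  set.seed(14)
  rec <- simulate_survival_cohort(50, hr = 2, followup = 30, seed = 14)
  km <- km_estimate(rec)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
  ref <- summary(sf, times = km$table$time)
  expect_equal(km_survival_at(km, ref$time), ref$surv, tolerance = 1e-10)
})

test_that("log-rank behaves on constructed two-group data", {
  a <- survival_records(c(1, 2, 3), rep(TRUE, 3))
  b <- survival_records(c(10, 20, 30), rep(TRUE, 3))
  lr <- logrank_test(a, b)
  expect_lt(lr$p_value, 0.05)
  # identical groups: statistic 0, p = 1
  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # a single shared event time split evenly: statistic 0 by symmetry
  c1 <- survival_records(c(5, 5), c(TRUE, FALSE))
  c2 <- survival_records(c(5, 5), c(TRUE, FALSE))
  expect_equal(logrank_test(c1, c2)$statistic, 0)
  expect_error(logrank_test(survival_records(1, FALSE),
                            survival_records(2, FALSE)), "no events")
})

test_that("log-rank matches the reference implementation", {
  skip_if_not_installed("survival")
  rec <- simulate_survival_cohort(80, hr = 2.5, followup = 40, seed = 3)
  sp <- median_split(rec)
  mine <- logrank_test(sp$high, sp$low)
  df <- data.frame(time = rec$time, event = rec$event,
                   hi = rec$marker >= median(rec$marker))
  ref <- survival::survdiff(survival::Surv(time, event) ~ hi, data = df)
  expect_equal(mine$statistic, ref$chisq, tolerance = 1e-8)
})

test_that("Cox score test equals the log-rank statistic on tie-free data", {
  rec <- simulate_survival_cohort(60, hr = 3, seed = 7)   # continuous times
  expect_equal(anyDuplicated(rec$time), 0)
  sp <- median_split(rec)
  lr <- logrank_test(sp$high, sp$low)
  cx <- cox_univariate(rec, binary = TRUE)
  expect_equal(cx$score_stat, lr$statistic, tolerance = 1e-6)
})

test_that("Cox regression recovers known hazard ratios", {
  # null covariate: HR near 1
  rec0 <- simulate_survival_cohort(200, hr = 1, seed = 42)
  cx0 <- cox_univariate(rec0, binary = TRUE)
  expect_true(cx0$converged)
  expect_gt(cx0$hr, 0.8); expect_lt(cx0$hr, 1.25)
  # binary covariate with true HR 2, n = 500, all events observed
  rec2 <- simulate_survival_cohort(500, hr = 2, seed = 43)
  cx2 <- cox_univariate(rec2, binary = TRUE)
  expect_true(cx2$converged)
  expect_lt(abs(cx2$hr - 2) / 2, 0.15)
})

test_that("Cox estimates match the reference implementation", {
  skip_if_not_installed("survival")
  rec <- simulate_survival_cohort(120, hr = 2, followup = 60, seed = 8)
  for (bin in c(TRUE, FALSE)) {
    mine <- cox_univariate(rec, binary = bin)
    x <- if (bin) as.numeric(rec$marker >= median(rec$marker)) else rec$marker
    ref <- survival::coxph(survival::Surv(rec$time, rec$event) ~ x,
                           ties = "breslow")
    expect_equal(mine$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(mine$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-6)
  }
})

test_that("monotone likelihood is flagged, not silently reported", {
  # perfect separation: high marker dies first, always
  rec <- survival_records(c(1, 2, 3, 10, 20, 30), rep(TRUE, 6),
                          marker = c(9, 8, 7, 1, 2, 3))
  cx <- cox_univariate(rec, binary = TRUE)
  expect_false(cx$converged)
  expect_equal(abs(cx$beta), 20)
  expect_error(cox_univariate(survival_records(1:3, c(TRUE, FALSE, FALSE),
                                               marker = 1:3)),
               ">= 2 events")
})

test_that("survival record validation", {
  expect_error(survival_records(c(1, -2), c(TRUE, TRUE)), "positive")
  expect_error(survival_records(c(1, Inf), c(TRUE, TRUE)), "finite")
})
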