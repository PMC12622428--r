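test_that("enrichment ratio is a guarded quotient", {
  expect_equal(enrichment_ratio(2, 1), 2)
  expect_equal(enrichment_ratio(1.5, 1.5), 1)
  expect_equal(enrichment_ratio(1.64, 1.01), 1.64 / 1.01)
  expect_error(enrichment_ratio(1, 0), "positive")
  expect_error(enrichment_ratio(-1, 1), "non-negative")
})

test_that("KS normality gate separates normal from skewed samples", {
  set.seed(101)
  expect_gt(ks_normality(rnorm(1000))$p_value, 0.05)
  expect_lt(ks_normality(rexp(1000))$p_value, 0.001)
  expect_error(ks_normality(rnorm(4)), "n >= 5")
  expect_error(ks_normality(rep(3, 10)), "degenerate")
  # agrees with the reference implementation
  x <- rlnorm(80)
  mine <- ks_normality(x)
  ref <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), sd(x),
                                         exact = FALSE))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("exact Mann-Whitney p-values match brute-force enumeration", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  set.seed(55)
  for (i in 1:8) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- sample(1:200, n1 + n2)   # tie-free
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    expect_equal(mann_whitney_u(a, b)$p_value, brute_mwu_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney approximation tracks the reference", {
  set.seed(56)
  a <- rnorm(40); b <- rnorm(45, 0.4)
  mine <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
  # tie correction path
  a2 <- sample(1:5, 40, replace = TRUE); b2 <- sample(2:6, 40, replace = TRUE)
  ref2 <- suppressWarnings(stats::wilcox.test(a2, b2, correct = TRUE))
  expect_equal(mann_whitney_u(a2, b2)$p_value, ref2$p.value, tolerance = 1e-6)
})

test_that("the comparison gate picks the right test", {
  set.seed(77)
  a <- rnorm(60); b <- rnorm(60, 0.2)
  expect_equal(compare_groups(a, b)$test_name, "t")
  expect_equal(compare_groups(a, b)$p_value,
               stats::t.test(a, b)$p.value, tolerance = 1e-10)
  # heavy-tailed force-like samples route to Mann-Whitney
  h1 <- rlnorm(100, 6, 1); h2 <- rlnorm(100, 6.5, 1)
  expect_equal(compare_groups(h1, h2)$test_name, "mann_whitney")
  # identical degenerate samples: p = 1
  expect_equal(compare_groups(rep(1, 5), rep(1, 5))$p_value, 1)
  expect_error(compare_groups(1:2, 1:5), "n >= 3")
})

test_that("empirical AUC equals the brute-force pairwise probability", {
  expect_equal(empirical_auc(c(4, 5), c(1, 2, 3)), 1)
  expect_equal(empirical_auc(c(1, 2), c(1, 2)), 0.5)
  expect_equal(empirical_auc(c(2, 4), c(1, 3)), 0.75)
  set.seed(91)
  for (i in 1:6) {
    pos <- sample(1:30, sample(3:25, 1), replace = TRUE)
    neg <- sample(5:35, sample(3:25, 1), replace = TRUE)
    expect_equal(empirical_auc(pos, neg), brute_auc(pos, neg))
    # complement and monotone-transform invariance
    expect_equal(empirical_auc(pos, neg), 1 - empirical_auc(neg, pos))
    expect_equal(empirical_auc(exp(pos / 10), exp(neg / 10)),
                 empirical_auc(pos, neg))
  }
  expect_error(empirical_auc(numeric(0), 1:3), "non-empty")
})

test_that("median split applies the documented tie rule", {
  rec <- survival_records(rep(10, 4), rep(TRUE, 4), marker = c(1, 2, 3, 4))
  sp <- median_split(rec)
  expect_equal(sort(sp$high$marker), c(3, 4))
  expect_equal(sort(sp$low$marker), c(1, 2))
  # odd n: the median value itself goes high
  rec2 <- survival_records(rep(10, 5), rep(TRUE, 5), marker = 1:5)
  expect_true(3 %in% median_split(rec2)$high$marker)
  # 15 records split 8 / 7
  rec3 <- survival_records(rep(10, 15), rep(TRUE, 15), marker = 1:15)
  sp3 <- median_split(rec3)
  expect_equal(c(nrow(sp3$high), nrow(sp3$low)), c(8, 7))
  expect_error(median_split(survival_records(c(1, 2), c(TRUE, TRUE),
                                             marker = c(5, 5))),
               "identical")
})

test_that("Schoenfeld power matches the closed form and is monotone", {
  expect_equal(schoenfeld_power(1, d = 100),
               pnorm(-qnorm(0.975)), tolerance = 1e-12)
  expect_equal(round(schoenfeld_power(8.861, d = 5), 2), 0.68)
  expect_equal(round(schoenfeld_power(8.861, d = 6), 2), 0.76)
  d <- 1:30
  pw <- schoenfeld_power(3, d)
  expect_true(all(diff(pw) > 0))
  hrs <- seq(1.1, 10, by = 0.5)
  expect_true(all(diff(schoenfeld_power(hrs, d = 10)) > 0))
  # inverse HR gives the same power (|ln HR|)
  expect_equal(schoenfeld_power(0.5, 20), schoenfeld_power(2, 20))
  expect_error(schoenfeld_power(-1, 5), "positive")
  expect_error(schoenfeld_power(2, 0), "d must")
  expect_error(schoenfeld_power(2, 5, p_alloc = 1), "p_alloc")
})
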