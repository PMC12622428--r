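test_that("plateau extraction recovers staircase levels", {
  sg <- simulate_sensorgram(0.005, 0, 10^(2:6), noise_sd = 0, seed = 1)
  pts <- extract_plateaus(sg, 30)
  expect_equal(pts$conc_per_ml, c(0, 10^(2:6)))
  expect_equal(pts$d_psi[-1], 0.005 * (2:6), tolerance = 1e-12)
  expect_error(extract_plateaus(sg, 1e5), "longer than step")
  one <- sensorgram(0:100, rep(0, 101),
                    data.frame(start_s = 0, conc_per_ml = 0))
  expect_error(extract_plateaus(one, 10), ">= 2 steps")
  # noisy staircase: levels within 3 SE of truth
  set.seed(5)
  ok <- TRUE
  for (i in 1:20) {
    sgn <- simulate_sensorgram(0.005, 0, 10^(2:6), noise_sd = 0.002, seed = i)
    ptsn <- extract_plateaus(sgn, 30)
    se <- 0.002 / sqrt(30)
    ok <- ok && all(abs(ptsn$d_psi[-1] - 0.005 * (2:6)) < 3 * se + 1e-12)
  }
  expect_gt(mean(ok), 0.9)
})

test_that("dose-response fit matches the OLS closed form", {
  pts <- data.frame(conc_per_ml = 10^c(2, 4, 6), d_psi = c(0.01, 0.02, 0.03))
  fit <- fit_dose_response(pts)
  expect_equal(fit$slope, 0.005)
  expect_equal(fit$r_squared, 1)
  # perturb one point: closed-form OLS on log10(conc)
  pts2 <- pts; pts2$d_psi[2] <- 0.025
  fit2 <- fit_dose_response(pts2)
  x <- log10(pts2$conc_per_ml); y <- pts2$d_psi
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit2$slope, slope_hand)
  expect_lt(fit2$r_squared, 1)
  expect_error(fit_dose_response(pts[1:2, ]), ">= 3")
  expect_error(fit_dose_response(data.frame(conc_per_ml = c(-1, 10, 100),
                                            d_psi = 1:3)),
               "non-negative")
})

test_that("the 3-sigma LOD inverts the calibration line", {
  fit <- structure(list(slope = 0.005, intercept = 0, r_squared = 1,
                        baseline_mean = 0, baseline_sd = 0.001,
                        n_points = 5, lod = NA_real_),
                   class = "calibration_fit")
  expect_equal(compute_lod(fit)$lod, 10^0.6)
  # degenerate sigma: inversion at the baseline mean itself
  fit$baseline_sd <- 0; fit$baseline_mean <- 0.01
  expect_equal(compute_lod(fit)$lod, 10^2)
  # monotonicity: decreasing in slope, increasing in baseline SD
  lod_at <- function(slope, bsd) {
    f <- fit; f$slope <- slope; f$baseline_sd <- bsd; f$baseline_mean <- 0
    compute_lod(f)$lod
  }
  expect_true(all(diff(sapply(c(0.002, 0.005, 0.01), lod_at, bsd = 0.001)) < 0))
  expect_true(all(diff(sapply(c(0.0005, 0.001, 0.002), function(b)
    lod_at(0.005, b))) > 0))
  fit$slope <- -1
  expect_error(compute_lod(fit), "positive slope")
})

test_that("simulate-extract-fit closes the loop", {
  # zero noise: exact recovery
  sg <- simulate_sensorgram(0.0095, -0.02, 10^(2:8), noise_sd = 0, seed = 2)
  fit <- fit_dose_response(extract_plateaus(sg, 30))
  expect_equal(fit$slope, 0.0095, tolerance = 1e-10)
  expect_equal(fit$intercept, -0.02, tolerance = 1e-10)
  # determinism
  sgb <- simulate_sensorgram(0.0095, -0.02, 10^(2:8), noise_sd = 1e-3, seed = 2)
  sgc <- simulate_sensorgram(0.0095, -0.02, 10^(2:8), noise_sd = 1e-3, seed = 2)
  expect_identical(sgb$d_psi, sgc$d_psi)
  # modest noise over 7 decades: slope within 10% of truth
  set.seed(31)
  slopes <- vapply(1:25, function(s) {
    g <- simulate_sensorgram(0.0095, -0.02, 10^(2:8), noise_sd = 5e-4, seed = s)
    fit_dose_response(extract_plateaus(g, 30))$slope
  }, numeric(1))
  expect_true(all(abs(slopes - 0.0095) / 0.0095 < 0.10))
})

test_that("sensorgram validation enforces the serial schedule", {
  expect_error(sensorgram(c(0, 1, 1), 1:3,
                          data.frame(start_s = 0, conc_per_ml = 0)),
               "strictly increasing")
  expect_error(sensorgram(0:10, rep(0, 11),
                          data.frame(start_s = c(0, 5),
                                     conc_per_ml = c(10, 1))),
               "non-decreasing")
  expect_error(simulate_sensorgram(0.01, 0, c(100, 10)), "increasing")
})
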