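test_that("sawtooth fixtures are scored exactly", {
  fx <- canonical_fixtures()
  expect_equal(nrow(detect_rupture_events(fx$S0)), 0)
  ev <- detect_rupture_events(fx$S1)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$separation, c(20, 50))
  # the discrete recovery misses at most one ramp step (13.4 pN at 0.5 nm)
  expect_equal(ev$magnitude, c(500, 800), tolerance = 0.03)
  expect_equal(max_adhesion_force(fx$S1), 800)
  expect_equal(adhesion_energy(fx$S1, noise_sd = 0), 17000, tolerance = 1e-3)
  # sub-threshold dip yields nothing
  expect_equal(nrow(detect_rupture_events(fx$S2)), 0)
  expect_equal(max_adhesion_force(fx$S2), 250)
})

test_that("single triangle energy matches the analytic area", {
  z <- seq(0, 30, by = 0.1)
  f <- -400 * pmax(0, 1 - abs(z - 5) / 5)  # depth 400 pN, base 10 nm
  tri <- fd_curve(z, f, "retract")
  expect_equal(adhesion_energy(tri, noise_sd = 0), 2000, tolerance = 1e-3)
  flat <- fd_curve(z, numeric(length(z)), "retract")
  expect_equal(adhesion_energy(flat, noise_sd = 0), 0)
  expect_equal(max_adhesion_force(flat), 0)
})

test_that("binding classification follows the event count", {
  expect_equal(classify_binding(data.frame()), "no_binding")
  expect_equal(classify_binding(1), "single")
  fx <- canonical_fixtures()
  expect_equal(classify_binding(detect_rupture_events(fx$S1)), "multiple")
})

test_that("detector is exact on noise-free simulated curves", {
  p <- surface_profile(name = "nf", noise_sd = 0)
  hits <- 0L; total <- 0L
  for (seed in 1:60) {
    cv <- simulate_curve(p, seed)
    truth <- attr(cv, "bonds")
    ev <- detect_rupture_events(correct_baseline(cv))
    expect_equal(nrow(ev), nrow(truth))
    if (nrow(truth)) {
      expect_equal(ev$separation, truth$separation, tolerance = p$sample_spacing)
      expect_equal(ev$magnitude, truth$magnitude, tolerance = 1)
      hits <- hits + nrow(ev)
    }
    total <- total + nrow(truth)
  }
  expect_gt(total, 50)         # the sweep actually exercised events
  expect_equal(hits, total)    # recall and precision 1.0
})

test_that("scoring is invariant under stored trace direction", {
  p <- surface_profile(name = "dir", noise_sd = 0)
  cv <- simulate_curve(p, 12)
  rev_cv <- fd_curve(rev(cv$separation), rev(cv$force), "retract",
                     surface_label = "dir")
  expect_equal(max_adhesion_force(rev_cv), max_adhesion_force(cv))
  expect_equal(detect_rupture_events(correct_baseline(rev_cv)),
               detect_rupture_events(correct_baseline(cv)))
})

test_that("surface summaries equal a brute-force recomputation", {
  p <- builtin_presets()[["pPDL1"]]
  g <- simulate_grid(p, 5, 8, seed = 33)
  m <- score_grid(g)
  s <- summarize_surface(g, m)
  expect_equal(s$n_curves, 40)
  expect_equal(s$prevalence_multiple, sum(m$binding_class == "multiple") / 40)
  expect_equal(s$prevalence_single, sum(m$binding_class == "single") / 40)
  expect_lte(s$prevalence_single + s$prevalence_multiple, 1)
  expect_equal(s$f_max_mean, sum(m$f_max_pN) / 40)
  expect_equal(s$f_max_sd, sqrt(sum((m$f_max_pN - mean(m$f_max_pN))^2) / 39))
  expect_equal(s$e_adh_mean, sum(m$e_adh_pN_nm) / 40)
  fm <- m$f_max_pN[m$binding_class == "multiple"]
  expect_equal(s$f_multiple_mean, mean(fm))
  expect_error(summarize_surface(g, m[0, ]), "no metrics")
})

test_that("energy is non-negative and zero without contact", {
  p <- builtin_presets()[["G7-pPDL1-scr"]]
  g <- simulate_grid(p, 4, 10, seed = 77)
  m <- score_grid(g)
  expect_true(all(m$e_adh_pN_nm >= 0))
  expect_true(all(m$e_adh_pN_nm[is.na(m$contact_nm)] == 0))
  expect_true(all(m$f_max_pN >= 0))
})

test_that("heatmaps arrange metrics on the raster", {
  z <- seq(0, 10, by = 0.5)
  mk <- function(gi, f0) fd_curve(z, rep(0, length(z)) - f0 * (z < 1),
                                  grid_index = gi)
  # checkerboard of deep/shallow adhesion
  curves <- list(); k <- 0
  for (r in 0:1) for (cc in 0:1) {
    k <- k + 1
    curves[[k]] <- mk(c(r, cc), if ((r + cc) %% 2 == 0) 400 else 100)
  }
  g <- fd_grid(curves, 2, 2)
  m <- score_grid(g)
  maps <- build_heatmaps(g, m)
  expect_equal(maps$f_max > 200,
               matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  # single curve in a 2x2 grid leaves 3 NA cells
  g1 <- fd_grid(curves[1], 2, 2)
  maps1 <- build_heatmaps(g1, score_grid(g1))
  expect_equal(sum(is.na(maps1$f_max)), 3)
  # uniform metrics give constant matrices
  gu <- fd_grid(lapply(1:4, function(i)
    mk(c((i - 1) %/% 2, (i - 1) %% 2), 400)), 2, 2)
  mu <- build_heatmaps(gu, score_grid(gu))
  expect_equal(max(mu$f_max) - min(mu$f_max), 0)
})
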