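#' Simulator parameterization of a capture surface
#'
#' A `surface_profile` describes how retraction curves are generated for one
#' functionalized surface: how many molecular bonds form per tip contact,
#' how strong each rupture is, where along the retraction the ruptures
#' occur, how steep the loading ramp into each rupture is, and the
#' measurement noise.
#'
#' Rupture magnitudes are drawn as `force_floor + lognormal`, capped at
#' `force_cap`. The floor keeps every simulated bond above the 300 pN event
#' threshold — ruptures below the threshold are not identifiable as events,
#' so the generator only produces identifiable ones and the scored event
#' count equals the generated bond count on noise-free data. The lognormal
#' tail reproduces the strongly right-skewed force distributions seen on
#' avidity surfaces (SDs of the same order as, or larger than, the means).
#' Single-bond contacts draw from their own lognormal so the class-stratified
#' force statistics can be calibrated independently of multivalent contacts.
#'
#' @param name surface label.
#' @param bond_count_pmf named numeric vector of probabilities over bond
#'   counts m = 0, 1, 2, ... per contact; must sum to 1.
#' @param rupture_force_logmean,rupture_force_logsd log-scale parameters of
#'   the per-bond rupture magnitude (pN) for multivalent (m >= 2) contacts.
#' @param rupture_force_logmean_single,rupture_force_logsd_single same for
#'   single-bond contacts.
#' @param force_floor additive offset (pN) under the lognormal (default 450).
#' @param force_cap upper truncation of drawn magnitudes (pN, default 8000,
#'   the working range of a stiff mapping cantilever).
#' @param rupture_sep_range interval (nm) the ordered rupture separations
#'   are drawn from, uniformly with a minimum spacing of `min_bond_gap`.
#' @param min_bond_gap minimum spacing between rupture separations (nm).
#' @param loading_stiffness slope (pN/nm) of the linear loading ramp into
#'   each rupture; sets the ramp width F/k and thereby the adhesion energy.
#' @param noise_sd Gaussian force noise SD (pN, default 30, putting the
#'   300 pN threshold at 10 sigma).
#' @param nonspecific_depth depth (pN) of the shallow sub-threshold adhesion
#'   dip near contact applied to every curve (default 50).
#' @param nonspecific_width width (nm) of that dip (default 3).
#' @param z_max retraction length (nm, default 70).
#' @param sample_spacing separation grid spacing (nm, default 0.025).
#' @param fixed_separations,fixed_magnitudes optional fixed bond positions
#'   and magnitudes (test fixtures); when set they override the random draws
#'   and `bond_count_pmf` must be degenerate at their length.
#' @return An object of class `surface_profile`.
#' @export
surface_profile <- function(name = "surface",
                            bond_count_pmf = c("0" = 0.2, "1" = 0.3, "2" = 0.3, "3" = 0.2),
                            rupture_force_logmean = log(500),
                            rupture_force_logsd = 1.1,
                            rupture_force_logmean_single = log(200),
                            rupture_force_logsd_single = 1.3,
                            force_floor = 450, force_cap = 8000,
                            rupture_sep_range = c(5, 45), min_bond_gap = 3,
                            loading_stiffness = 2000, noise_sd = 30,
                            nonspecific_depth = 50, nonspecific_width = 3,
                            z_max = 70, sample_spacing = 0.025,
                            fixed_separations = NULL, fixed_magnitudes = NULL) {
  pmf <- bond_count_pmf
  if (is.null(names(pmf))) names(pmf) <- seq_along(pmf) - 1L
  if (abs(sum(pmf) - 1) > 1e-8) stop("bond_count_pmf must sum to 1", call. = FALSE)
  if (any(pmf < 0)) stop("bond_count_pmf must be non-negative", call. = FALSE)
  if (rupture_force_logsd < 0 || rupture_force_logsd_single < 0)
    stop("log-sd must be >= 0", call. = FALSE)
  if (length(rupture_sep_range) != 2L || diff(rupture_sep_range) <= 0 ||
      rupture_sep_range[1] <= 0)
    stop("rupture_sep_range must be a positive ordered interval", call. = FALSE)
  if (loading_stiffness <= 0) stop("loading_stiffness must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(fixed_separations) &&
      length(fixed_separations) != length(fixed_magnitudes))
    stop("fixed separations and magnitudes must have equal length", call. = FALSE)
  structure(list(
    name = name, bond_count_pmf = pmf,
    rupture_force_logmean = rupture_force_logmean,
    rupture_force_logsd = rupture_force_logsd,
    rupture_force_logmean_single = rupture_force_logmean_single,
    rupture_force_logsd_single = rupture_force_logsd_single,
    force_floor = force_floor, force_cap = force_cap,
    rupture_sep_range = rupture_sep_range, min_bond_gap = min_bond_gap,
    loading_stiffness = loading_stiffness, noise_sd = noise_sd,
    nonspecific_depth = nonspecific_depth,
    nonspecific_width = nonspecific_width,
    z_max = z_max, sample_spacing = sample_spacing,
    fixed_separations = fixed_separations,
    fixed_magnitudes = fixed_magnitudes), class = "surface_profile")
}

#' @export
print.surface_profile <- function(x, ...) {
  pm <- sum(x$bond_count_pmf[as.integer(names(x$bond_count_pmf)) >= 2])
  cat(sprintf(
    "<surface_profile> %s: P(m>=2) = %.3f, F ~ %g + LN(%.3f, %.2f) pN, k = %.0f pN/nm, noise %g pN\n",
    x$name, pm, x$force_floor, x$rupture_force_logmean,
    x$rupture_force_logsd, x$loading_stiffness, x$noise_sd))
  invisible(x)
}

# ordered rupture separations with minimum spacing, by rejection
draw_separations <- function(m, range, gap) {
  for (i in 1:1000) {
    s <- sort(stats::runif(m, range[1], range[2]))
    if (m == 1L || all(diff(s) >= gap)) return(s)
  }
  seq(range[1], range[2], length.out = m)  # evenly spread fallback
}

#' Simulate one retraction curve
#'
#' Draws a bond count m from the profile's pmf, m ordered rupture
#' separations and m rupture magnitudes, and builds a sequential sawtooth:
#' ahead of each rupture the force ramps linearly down at the loading
#' stiffness (never reaching back past the previous rupture), reaches its
#' most attractive value at the rupture separation, and recovers
#' instantaneously. A shallow sub-threshold nonspecific dip near contact and
#' Gaussian noise are added. Identical seed, identical curve.
#'
#' @param profile a [surface_profile()].
#' @param seed integer seed; the curve is a pure function of
#'   `(profile, seed)`.
#' @param grid_index grid position passed through to the curve.
#' @param force_m optional fixed bond count overriding the pmf draw (used by
#'   [simulate_grid()] for stratified class allocation).
#' @param force_u optional vector of `force_m` probability quantiles in
#'   (0, 1) used in place of fresh lognormal draws for the rupture
#'   magnitudes (used by [simulate_grid()] for stratified force sampling).
#' @return An [fd_curve()] (retract segment only) with the generated bond
#'   list attached as `attr(curve, "bonds")` (a data.frame with
#'   `separation` and `magnitude`), the ground truth for detector oracles.
#' @export
simulate_curve <- function(profile, seed, grid_index = c(0L, 0L),
                           force_m = NULL, force_u = NULL) {
  stopifnot(inherits(profile, "surface_profile"))
  set.seed(as.integer(seed %% 2147483647))
  z <- seq(0, profile$z_max, by = profile$sample_spacing)
  f <- numeric(length(z))
  if (profile$nonspecific_depth > 0) {
    i <- z <= profile$nonspecific_width
    f[i] <- -profile$nonspecific_depth * (1 - z[i] / profile$nonspecific_width)
  }
  counts <- as.integer(names(profile$bond_count_pmf))
  m <- if (!is.null(force_m)) as.integer(force_m)
  else counts[sample.int(length(counts), 1L, prob = profile$bond_count_pmf)]
  bonds <- data.frame(separation = numeric(0), magnitude = numeric(0))
  if (m > 0L) {
    if (!is.null(profile$fixed_separations)) {
      zb <- profile$fixed_separations
      fb <- profile$fixed_magnitudes
    } else {
      zb <- draw_separations(m, profile$rupture_sep_range, profile$min_bond_gap)
      lm_ <- if (m == 1L) profile$rupture_force_logmean_single else
        profile$rupture_force_logmean
      ls_ <- if (m == 1L) profile$rupture_force_logsd_single else
        profile$rupture_force_logsd
      ln <- if (is.null(force_u)) stats::rlnorm(m, lm_, ls_)
      else stats::qlnorm(force_u, lm_, ls_)
      fb <- profile$force_floor + pmin(ln, profile$force_cap)
    }
    zb <- round(zb / profile$sample_spacing) * profile$sample_spacing
    prev <- 0
    for (i in seq_len(m)) {
      a <- max(prev, zb[i] - fb[i] / profile$loading_stiffness)
      ramp <- z > a + 1e-12 & z <= zb[i] + 1e-12
      if (any(ramp)) f[ramp] <- f[ramp] - fb[i] * (z[ramp] - a) / (zb[i] - a)
      prev <- zb[i]
    }
    bonds <- data.frame(separation = zb, magnitude = fb)
  }
  if (profile$noise_sd > 0) f <- f + stats::rnorm(length(z), 0, profile$noise_sd)
  cv <- fd_curve(z, f, "retract", grid_index = grid_index,
                 surface_label = profile$name,
                 sample_spacing = profile$sample_spacing)
  attr(cv, "bonds") <- bonds
  cv
}

# per-curve seed derived from the root seed and the raster position;
# reproducible and independent of acquisition order
derive_curve_seed <- function(seed, row, col) {
  as.integer((as.numeric(seed) + 100003 * row + 197 * col) %% 2147483629) + 1L
}

# quota allocation of bond counts over N curves: largest-remainder rounding
# of pmf * N, so the realized class composition matches the pmf exactly up
# to integer rounding
quota_bond_counts <- function(pmf, n) {
  target <- pmf * n
  base <- floor(target)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  rep(as.integer(names(pmf)), base)
}

#' Simulate a force-volume grid
#'
#' `n_rows * n_cols` curves (the mapping experiments use 20 x 20 per
#' surface), each built from a seed derived from the root seed and its
#' raster position, so the grid is reproducible and order-independent. Bond
#' counts are allocated to grid positions by stratified (quota) sampling of
#' the profile's bond-count pmf in a seeded random arrangement: the realized
#' class composition of a grid equals the pmf up to integer rounding, so
#' the binding prevalences a grid exhibits are those the profile was
#' calibrated to, by construction, while bond positions, magnitudes and
#' noise remain independent across curves.
#'
#' Rupture magnitudes are likewise quota-sampled: within each binding class
#' the per-bond lognormal quantiles are a stratified, seeded-random
#' arrangement of an equispaced grid on (0, 1), so each bond's marginal
#' force law is unchanged while the grid-level force and energy means
#' concentrate near the values the profile was calibrated to. Bond
#' positions and measurement noise stay fully independent. Use
#' [simulate_curve()] directly for unconditionally independent draws.
#'
#' @param profile a [surface_profile()].
#' @param n_rows,n_cols raster dimensions (default 20 x 20).
#' @param seed root integer seed.
#' @return An [fd_grid()].
#' @export
simulate_grid <- function(profile, n_rows = 20L, n_cols = 20L, seed = 1L) {
  n <- n_rows * n_cols
  ms <- quota_bond_counts(profile$bond_count_pmf, n)
  set.seed(as.integer(seed %% 2147483647))
  ms <- ms[sample.int(n)]
  # stratified force quantiles, separately for the single-bond class and
  # the multivalent class (they follow different lognormals)
  us <- vector("list", n)
  strat_u <- function(b) ((seq_len(b) - 0.5) / b)[sample.int(b)]
  singles <- which(ms == 1L)
  if (length(singles)) {
    u1 <- strat_u(length(singles))
    for (j in seq_along(singles)) us[[singles[j]]] <- u1[j]
  }
  multis <- which(ms >= 2L)
  if (length(multis)) {
    u2 <- strat_u(sum(ms[multis]))
    at <- 1L
    for (k in multis) {
      us[[k]] <- u2[at:(at + ms[k] - 1L)]
      at <- at + ms[k]
    }
  }
  curves <- vector("list", n)
  k <- 0L
  for (r in seq_len(n_rows) - 1L) {
    for (cl in seq_len(n_cols) - 1L) {
      k <- k + 1L
      curves[[k]] <- simulate_curve(profile, derive_curve_seed(seed, r, cl),
                                    grid_index = c(r, cl), force_m = ms[k],
                                    force_u = us[[k]])
    }
  }
  fd_grid(curves, n_rows = n_rows, n_cols = n_cols,
          surface_label = profile$name)
}

#' Deterministic canonical fixtures
#'
#' Three noise-free piecewise-linear retraction curves with analytically
#' known scoring results, used as detector and energy oracles:
#' * `S0` — flat zero curve (0-100 nm, 0.5 nm spacing): no contact, no
#'   events, zero force and energy.
#' * `S1` — two-event sawtooth: linear ramp to -500 pN over 0-20 nm,
#'   instantaneous rupture, ramp to -800 pN over 20-50 nm, rupture, flat to
#'   100 nm. Events of 500 and 800 pN at 20 and 50 nm; F_max = 800 pN;
#'   adhesion energy = 1/2*20*500 + 1/2*30*800 = 17,000 pN nm.
#' * `S2` — single triangular dip of 250 pN depth (below the 300 pN
#'   threshold) over 0-10 nm: no events, F_max = 250 pN.
#'
#' @return Named list of [fd_curve()]s: `S0`, `S1`, `S2`.
#' @export
canonical_fixtures <- function() {
  z <- seq(0, 100, by = 0.5)
  s0 <- fd_curve(z, numeric(length(z)), "retract", surface_label = "S0")
  f1 <- numeric(length(z))
  i1 <- z <= 20; f1[i1] <- -25 * z[i1]
  i2 <- z > 20 & z <= 50; f1[i2] <- -(800 / 30) * (z[i2] - 20)
  s1 <- fd_curve(z, f1, "retract", surface_label = "S1")
  f2 <- numeric(length(z))
  j <- z <= 10; f2[j] <- -250 * (1 - abs(z[j] - 5) / 5)
  s2 <- fd_curve(z, f2, "retract", surface_label = "S2")
  list(S0 = s0, S1 = s1, S2 = s2)
}

#' Published per-surface summary targets
#'
#' The reference surface-level summary values the built-in presets are
#' calibrated against: prevalence of multiple binding, mean maximum adhesion
#' force (pN), mean adhesion energy (pN nm) and, for the G7-pPDL1 surface,
#' the class-stratified force means, for the four capture surfaces of the
#' mapping comparison (G7-pPDL1, aPD-L1, pPDL1, scrambled-peptide control).
#' Single-binding prevalences are not reported for the comparison surfaces
#' and are the package's own preset choice.
#'
#' @return Named list (one entry per surface) of target lists as accepted by
#'   [calibrate_profile()].
#' @export
reference_surface_targets <- function() {
  list(
    "G7-pPDL1" = list(prevalence_multiple = 0.890, prevalence_single = 0.110,
                      f_max_mean = 1470.8, e_adh_mean = 106.4,
                      f_single_mean = 654.9, f_multiple_mean = 1558.3),
    "aPD-L1" = list(prevalence_multiple = 0.710, prevalence_single = 0.20,
                    f_max_mean = 790.5, e_adh_mean = 66.8),
    "pPDL1" = list(prevalence_multiple = 0.360, prevalence_single = 0.40,
                   f_max_mean = 594.0, e_adh_mean = 51.5),
    "G7-pPDL1-scr" = list(prevalence_multiple = 0.075, prevalence_single = 0.25,
                          f_max_mean = 350.9, e_adh_mean = NA_real_))
}

# split a multiple-binding prevalence over bond counts 2..4 (fixed shape)
make_bond_pmf <- function(prev_multiple, prev_single) {
  p0 <- 1 - prev_multiple - prev_single
  if (p0 < -1e-9) stop("prevalences exceed 1", call. = FALSE)
  pmf <- c("0" = max(p0, 0), "1" = prev_single,
           "2" = 0.5 * prev_multiple, "3" = 0.3 * prev_multiple,
           "4" = 0.2 * prev_multiple)
  pmf / sum(pmf)
}

# mean scored summary of a profile at n curves (common-random-number seed)
scored_summary <- function(profile, n_curves, seed, pre_cfg, ev_cfg) {
  n_rows <- max(1L, floor(sqrt(n_curves)))
  n_cols <- ceiling(n_curves / n_rows)
  grid <- simulate_grid(profile, n_rows, n_cols, seed = seed)
  grid$curves <- grid$curves[seq_len(n_curves)]
  metrics <- score_grid(grid, pre_cfg, ev_cfg)
  summarize_surface(profile$name, metrics)
}

#' Calibrate a surface profile against summary targets
#'
#' Moment matching so that the *scored* pipeline output (simulate, baseline
#' correct, detect, score) reproduces a target surface summary. The binding
#' prevalences are matched exactly by construction (the bond-count pmf mass
#' on m >= 2 is set to the multiple-binding prevalence, and on m = 1 to the
#' single prevalence when provided). Force means are matched by a damped
#' fixed-point rescaling of the lognormal log-means (stratified when
#' class-stratified targets are given, otherwise jointly); the adhesion
#' energy is then matched by bisection on the loading stiffness, which sets
#' the rupture ramp width F/k and hence the force-distance integral, while
#' leaving rupture positions (and so the prevalence and force calibration)
#' untouched. All iterations score freshly simulated grids under a common
#' random-number seed, so the fixed point is deterministic.
#'
#' @param targets list with `prevalence_multiple`, `f_max_mean`, and
#'   optionally `prevalence_single`, `e_adh_mean`, `f_single_mean`,
#'   `f_multiple_mean` (see [reference_surface_targets()]).
#' @param base a [surface_profile()] to start from.
#' @param n_curves curves simulated per iteration (default 400).
#' @param seed integer seed for the calibration simulations.
#' @param rel_tol relative tolerance on the matched means (default 0.02).
#' @param max_iter maximum fixed-point iterations (default 20).
#' @param pre_cfg,ev_cfg scoring configuration.
#' @return The calibrated [surface_profile()], with the achieved summary and
#'   relative residuals attached as `attr(profile, "achieved")`.
#' @export
calibrate_profile <- function(targets, base = surface_profile(),
                              n_curves = 400L, seed = 1L, rel_tol = 0.02,
                              max_iter = 20L,
                              pre_cfg = preprocess_config(),
                              ev_cfg = event_config()) {
  prof <- base
  ps <- if (!is.null(targets$prevalence_single)) targets$prevalence_single
  else (1 - targets$prevalence_multiple) / 2
  prof$bond_count_pmf <- make_bond_pmf(targets$prevalence_multiple, ps)
  stratified <- !is.null(targets$f_single_mean) &&
    !is.null(targets$f_multiple_mean)
  fl <- prof$force_floor
  rel_err <- function(a, t) abs(a - t) / t
  # --- force means: damped multiplicative fixed point on the lognormal part
  resid <- Inf
  for (it in seq_len(max_iter)) {
    sm <- scored_summary(prof, n_curves, seed, pre_cfg, ev_cfg)
    if (stratified) {
      resid <- max(rel_err(sm$f_single_mean, targets$f_single_mean),
                   rel_err(sm$f_multiple_mean, targets$f_multiple_mean))
      if (resid < rel_tol) break
      prof$rupture_force_logmean_single <- prof$rupture_force_logmean_single +
        0.8 * log(max(targets$f_single_mean - fl, 1) /
                  max(sm$f_single_mean - fl, 1))
      prof$rupture_force_logmean <- prof$rupture_force_logmean +
        0.8 * log(max(targets$f_multiple_mean - fl, 1) /
                  max(sm$f_multiple_mean - fl, 1))
    } else {
      resid <- rel_err(sm$f_max_mean, targets$f_max_mean)
      if (resid < rel_tol) break
      d <- 0.8 * log(targets$f_max_mean / sm$f_max_mean)
      prof$rupture_force_logmean <- prof$rupture_force_logmean + d
      prof$rupture_force_logmean_single <-
        prof$rupture_force_logmean_single + d
    }
  }
  if (resid >= rel_tol)
    stop(sprintf("force calibration did not converge: residual %.3f", resid),
         call. = FALSE)
  # --- adhesion energy: bisection on log10(loading_stiffness)
  if (!is.null(targets$e_adh_mean) && is.finite(targets$e_adh_mean)) {
    e_at <- function(log10k) {
      p <- prof; p$loading_stiffness <- 10^log10k
      scored_summary(p, n_curves, seed, pre_cfg, ev_cfg)$e_adh_mean
    }
    lo <- 1.5; hi <- 6
    e_lo <- e_at(lo); e_hi <- e_at(hi)
    if (targets$e_adh_mean > e_lo || targets$e_adh_mean < e_hi * 0.95)
      stop(sprintf(
        "energy calibration target %.1f outside attainable range [%.1f, %.1f]",
        targets$e_adh_mean, e_hi, e_lo), call. = FALSE)
    for (it in seq_len(40L)) {
      mid <- (lo + hi) / 2
      e_mid <- e_at(mid)
      if (rel_err(e_mid, targets$e_adh_mean) < rel_tol) break
      if (e_mid > targets$e_adh_mean) lo <- mid else hi <- mid
    }
    if (rel_err(e_mid, targets$e_adh_mean) >= rel_tol)
      stop(sprintf("energy calibration did not converge: %.1f vs target %.1f",
                   e_mid, targets$e_adh_mean), call. = FALSE)
    prof$loading_stiffness <- 10^mid
  }
  achieved <- scored_summary(prof, n_curves, seed, pre_cfg, ev_cfg)
  attr(prof, "achieved") <- achieved
  prof
}

#' Built-in calibrated surface presets
#'
#' Four [surface_profile()]s — `G7-pPDL1`, `aPD-L1`, `pPDL1`,
#' `G7-pPDL1-scr` — pre-calibrated with [calibrate_profile()] against
#' [reference_surface_targets()] (calibration run at package build time
#' with `n_curves = 400`, seed 20260401; the numeric parameters below are
#' the converged values). Closed-loop scoring of a 20 x 20 grid from each
#' preset reproduces the corresponding surface summary within sampling
#' error.
#'
#' @param recalibrate if `TRUE`, rerun [calibrate_profile()] from scratch
#'   instead of using the stored parameters (slower; used for auditing).
#' @param seed seed for `recalibrate = TRUE`.
#' @return Named list of four [surface_profile()]s.
#' @export
builtin_presets <- function(recalibrate = FALSE, seed = 20260401) {
  targets <- reference_surface_targets()
  if (recalibrate) {
    out <- lapply(names(targets), function(nm)
      calibrate_profile(targets[[nm]],
                        base = surface_profile(name = nm), seed = seed))
    names(out) <- names(targets)
    return(out)
  }
  params <- list(
    "G7-pPDL1" = list(logmean = 5.831130, logmean_single = 4.560646,
                      stiffness = 20535.2503),
    "aPD-L1" = list(logmean = 5.004791, logmean_single = 4.088500,
                    stiffness = 9910.4586),
    "pPDL1" = list(logmean = 5.006953, logmean_single = 4.090663,
                   stiffness = 7773.6503),
    "G7-pPDL1-scr" = list(logmean = 5.618119, logmean_single = 4.701829,
                          stiffness = 2000))
  out <- lapply(names(targets), function(nm) {
    tg <- targets[[nm]]; pp <- params[[nm]]
    surface_profile(
      name = nm,
      bond_count_pmf = make_bond_pmf(tg$prevalence_multiple,
                                     tg$prevalence_single),
      rupture_force_logmean = pp$logmean,
      rupture_force_logmean_single = pp$logmean_single,
      loading_stiffness = pp$stiffness)
  })
  names(out) <- names(targets)
  out
}
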