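#' Construct a sensorgram
#'
#' A sensorgram is the differential ellipsometric angle signal dPsi recorded
#' over time while analyte concentrations are introduced serially (each step
#' at least as concentrated as the previous).
#'
#' @param time strictly increasing times (s).
#' @param d_psi dPsi signal (degrees, arbitrary baseline).
#' @param schedule data.frame with columns `start_s` and `conc_per_ml`
#'   (non-negative, non-decreasing): when each concentration step begins. A
#'   step with concentration 0 is the running-buffer baseline.
#' @return An object of class `sensorgram`.
#' @export
sensorgram <- function(time, d_psi, schedule) {
  time <- as.numeric(time); d_psi <- as.numeric(d_psi)
  if (length(time) != length(d_psi))
    stop("time and d_psi must have equal length", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing", call. = FALSE)
  stopifnot(is.data.frame(schedule),
            all(c("start_s", "conc_per_ml") %in% names(schedule)))
  if (any(schedule$conc_per_ml < 0) || is.unsorted(schedule$conc_per_ml))
    stop("concentrations must be >= 0 and non-decreasing", call. = FALSE)
  if (is.unsorted(schedule$start_s, strictly = TRUE))
    stop("schedule start times must be strictly increasing", call. = FALSE)
  structure(list(time = time, d_psi = d_psi, schedule = schedule),
            class = "sensorgram")
}

#' Extract plateau levels from a sensorgram
#'
#' Mean dPsi over the trailing `window` seconds of each concentration step
#' (the equilibrated plateau), turning a staircase sensorgram into
#' dose-response points.
#'
#' @param gram a [sensorgram()] whose schedule has >= 2 steps.
#' @param window trailing averaging window in seconds.
#' @return data.frame with `conc_per_ml` and `d_psi` (one row per step).
#' @export
extract_plateaus <- function(gram, window) {
  stopifnot(inherits(gram, "sensorgram"))
  sched <- gram$schedule
  if (nrow(sched) < 2) stop("schedule needs >= 2 steps", call. = FALSE)
  ends <- c(sched$start_s[-1], max(gram$time) + 1e-9)
  out <- lapply(seq_len(nrow(sched)), function(i) {
    if (ends[i] - sched$start_s[i] < window)
      stop("window longer than step ", i, call. = FALSE)
    sel <- gram$time >= ends[i] - window & gram$time < ends[i]
    data.frame(conc_per_ml = sched$conc_per_ml[i],
               d_psi = mean(gram$d_psi[sel]))
  })
  do.call(rbind, out)
}

#' Fit a log-linear dose-response calibration
#'
#' Ordinary least squares of the plateau signal on log10(concentration):
#' `d_psi = intercept + slope * log10(conc)`, slope in dPsi per decade of
#' concentration, with the R-squared of the fit. Zero-concentration rows
#' (running buffer) are used as the baseline (mean and SD of their signal)
#' and excluded from the regression; otherwise the baseline defaults to the
#' lowest-concentration point's signal with `baseline_sd`.
#'
#' @param points data.frame with `conc_per_ml` and `d_psi`; >= 3 distinct
#'   positive concentrations required.
#' @param baseline_mean,baseline_sd baseline dPsi statistics; when `NULL`
#'   they are taken from zero-concentration rows (or 0 if none).
#' @return An object of class `calibration_fit`: `slope`, `intercept`,
#'   `r_squared`, `baseline_mean`, `baseline_sd`, `n_points`, and `lod`
#'   (filled by [compute_lod()], `NA` until then).
#' @export
fit_dose_response <- function(points, baseline_mean = NULL, baseline_sd = NULL) {
  stopifnot(is.data.frame(points),
            all(c("conc_per_ml", "d_psi") %in% names(points)))
  base <- points[points$conc_per_ml == 0, , drop = FALSE]
  pts <- points[points$conc_per_ml != 0, , drop = FALSE]
  if (any(pts$conc_per_ml < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (length(unique(pts$conc_per_ml)) < 3)
    stop("need >= 3 distinct positive concentrations", call. = FALSE)
  if (is.null(baseline_mean))
    baseline_mean <- if (nrow(base)) mean(base$d_psi) else 0
  if (is.null(baseline_sd))
    baseline_sd <- if (nrow(base) >= 2) stats::sd(base$d_psi) else 0
  fit <- stats::lm(d_psi ~ log10(conc_per_ml), data = pts)
  tss <- sum((pts$d_psi - mean(pts$d_psi))^2)
  r2 <- if (tss <= 0) 1 else max(0, 1 - sum(stats::resid(fit)^2) / tss)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 n_points = nrow(pts), lod = NA_real_),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> slope %.4g dPsi/decade, intercept %.4g, R^2 = %.4f%s\n",
    x$slope, x$intercept, x$r_squared,
    if (is.na(x$lod)) "" else sprintf(", LOD = %.3g mL^-1", x$lod)))
  invisible(x)
}

#' Limit of detection by the three-sigma rule
#'
#' The LOD is the concentration whose calibrated signal equals the baseline
#' mean plus three baseline standard deviations: the calibration line is
#' inverted at `signal = baseline_mean + 3 * baseline_sd`, i.e.
#' `LOD = 10^((baseline_mean + 3 * baseline_sd - intercept) / slope)`.
#'
#' @param fit a `calibration_fit` from [fit_dose_response()] with positive
#'   slope and baseline statistics.
#' @return The fit with `lod` filled in (vesicles mL^-1).
#' @export
compute_lod <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope <= 0) stop("LOD requires a positive slope", call. = FALSE)
  fit$lod <- 10^((fit$baseline_mean + 3 * fit$baseline_sd - fit$intercept) /
                   fit$slope)
  fit
}

#' Simulate a staircase sensorgram
#'
#' Plateau levels follow the log-linear law
#' `intercept + slope * log10(conc)` plus Gaussian noise per sample; the
#' schedule starts with a zero-concentration running-buffer baseline step.
#'
#' @param slope dPsi per decade of concentration.
#' @param intercept dPsi at log10(conc) = 0.
#' @param concentrations positive increasing concentrations (vesicles
#'   mL^-1), one step each.
#' @param noise_sd Gaussian noise SD in dPsi units.
#' @param seed integer seed (same seed, identical trace).
#' @param step_s seconds per step (default 120).
#' @param dt sampling interval in seconds (default 1).
#' @param baseline dPsi level of the buffer step (default 0).
#' @return A [sensorgram()].
#' @export
simulate_sensorgram <- function(slope, intercept, concentrations,
                                noise_sd = 0, seed = 1L, step_s = 120,
                                dt = 1, baseline = 0) {
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be positive and increasing", call. = FALSE)
  set.seed(as.integer(seed %% 2147483647))
  conc <- c(0, concentrations)
  levels <- c(baseline, intercept + slope * log10(concentrations))
  time <- seq(0, by = dt, length.out = length(conc) * round(step_s / dt))
  step_of <- pmin(length(conc), time %/% step_s + 1)
  d_psi <- levels[step_of]
  if (noise_sd > 0) d_psi <- d_psi + stats::rnorm(length(time), 0, noise_sd)
  sensorgram(time, d_psi,
             data.frame(start_s = (seq_along(conc) - 1) * step_s,
                        conc_per_ml = conc))
}
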