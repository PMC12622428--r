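#' Event-detection configuration
#'
#' @param threshold rupture-jump force threshold in pN (default 300). A
#'   candidate rupture counts as an event only when the force recovers toward
#'   baseline by at least this much; the value follows the observation that
#'   jumps of this size essentially never occur on the scrambled-peptide
#'   negative-control surface.
#' @param min_event_gap minimum separation (nm) between distinct events;
#'   closer candidates are merged keeping the larger magnitude (default 1.0).
#' @param within_window separation window (nm) ahead of a candidate minimum
#'   within which the recovery must occur (default 2.0).
#' @return An object of class `event_config`.
#' @export
event_config <- function(threshold = 300, min_event_gap = 1.0,
                         within_window = 2.0) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (min_event_gap <= 0 || within_window <= 0)
    stop("gaps must be positive", call. = FALSE)
  structure(list(threshold = threshold, min_event_gap = min_event_gap,
                 within_window = within_window),
            class = "event_config")
}

# forward rolling max: out[i] = max(f[i+1], ..., f[i+w]) (window beyond i),
# -Inf padded past the end; O(n log w) via doubling
forward_window_max <- function(f, w) {
  n <- length(f)
  lead <- function(x, s) c(x[(s + 1L):n], rep(-Inf, min(s, n)))[seq_len(n)]
  m <- f   # m[i] = max f[i .. i+L-1]
  L <- 1L
  while (L < w) {
    s <- min(L, w - L)
    m <- pmax(m, lead(m, s))
    L <- L + s
  }
  lead(m, 1L)
}

#' Detect rupture events on a retraction trace
#'
#' Scans the baseline-corrected retract trace outward. A candidate event is
#' a local force minimum (most-attractive point) followed by a recovery
#' toward baseline of at least `threshold` pN within `within_window` nm of
#' separation. Candidates closer than `min_event_gap` nm are merged, keeping
#' the larger magnitude (a noisy descent into one adhesion well produces a
#' chain of sub-minima that all belong to the same rupture). The threshold
#' applies to the rupture *jump* (pre- to post-rupture force change), not to
#' the absolute force, so a second rupture riding on a deep first adhesion
#' well is still resolved.
#'
#' @param curve a baseline-corrected [fd_curve()].
#' @param cfg an [event_config()].
#' @return A data.frame with one row per event, sorted by separation:
#'   `separation` (nm), `magnitude` (pN, recovery size), `pre_level` (pN,
#'   force just before rupture), `post_level` (pN, recovered level).
#' @export
detect_rupture_events <- function(curve, cfg = event_config()) {
  r <- retract_of(curve)
  z <- r$separation; f <- r$force
  n <- length(f)
  if (is.unsorted(z, strictly = TRUE))
    stop("retract separation must be strictly increasing", call. = FALSE)
  spacing <- stats::median(diff(z))
  w <- max(1L, as.integer(round(cfg$within_window / spacing)))
  fwd <- forward_window_max(f, w)
  is_min <- c(FALSE, f[2:(n - 1)] < f[1:(n - 2)] & f[2:(n - 1)] <= f[3:n], FALSE)
  recovery <- fwd - f
  cand <- which(is_min & recovery >= cfg$threshold & is.finite(fwd))
  empty <- data.frame(separation = numeric(0), magnitude = numeric(0),
                      pre_level = numeric(0), post_level = numeric(0))
  if (!length(cand)) return(empty)
  # a candidate is a genuine rupture only if the trace does not dip below it
  # between the minimum and its recovery crossing (a noisy sub-minimum on the
  # loading ramp of a deeper rupture recovers only via that rupture and is
  # disqualified here)
  genuine <- vapply(cand, function(i) {
    hi <- min(n, i + w)
    jj <- i + which(f[(i + 1):hi] - f[i] >= cfg$threshold)
    j <- jj[1]
    between <- seq.int(i + 1L, j)[-(j - i)]
    !length(between) || min(f[between]) >= f[i]
  }, logical(1))
  cand <- cand[genuine]
  if (!length(cand)) return(empty)
  ev <- data.frame(separation = z[cand], magnitude = recovery[cand],
                   pre_level = f[cand], post_level = fwd[cand])
  # merge chains of candidates closer than min_event_gap, keep largest jump
  cluster <- cumsum(c(1, diff(ev$separation) >= cfg$min_event_gap))
  keep <- vapply(split(seq_len(nrow(ev)), cluster),
                 function(ii) ii[which.max(ev$magnitude[ii])], integer(1))
  ev <- ev[sort(keep), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Classify a curve by its rupture-event count
#'
#' Zero events is no binding, one is single binding, two or more abrupt
#' force changes mark multivalent (multiple) binding.
#'
#' @param events event data.frame from [detect_rupture_events()], or an
#'   event count.
#' @return One of `"no_binding"`, `"single"`, `"multiple"`.
#' @export
classify_binding <- function(events) {
  n <- if (is.data.frame(events)) nrow(events) else as.integer(events)
  if (n >= 2L) "multiple" else if (n == 1L) "single" else "no_binding"
}

#' Maximum adhesion force of a retraction trace
#'
#' Magnitude of the most attractive force excursion, `max(-F)` over the
#' whole baseline-corrected retract trace, floored at 0. Computed over the
#' full trace (not only at detected events) so that sub-threshold adhesion
#' still yields a nonzero value.
#'
#' @param curve a baseline-corrected [fd_curve()].
#' @return Maximum adhesion force in pN (>= 0).
#' @export
max_adhesion_force <- function(curve) {
  r <- retract_of(curve)
  max(0, -min(r$force))
}

#' Adhesion energy of a retraction trace
#'
#' The cumulative product of adhesive force and separation distance:
#' trapezoidal integral of `|F(z)| dz` over the adhesive region of the
#' baseline-corrected retract trace. The region comprises the samples, from
#' the contact point to the last return into the noise band, where the force
#' lies below `-noise_k * sigma`; pairs of adjacent samples whose force step
#' exceeds the rupture threshold (the rupture discontinuity itself, where
#' the integrand is undefined) are excluded. Returns 0 when the trace never
#' leaves the noise band ("no contact"). Exact up to one-sample rupture
#' discretization on piecewise-linear traces.
#'
#' @param curve a baseline-corrected [fd_curve()].
#' @param cfg a [preprocess_config()] supplying `noise_k`.
#' @param noise_sd baseline noise SD in pN; estimated with [estimate_noise()]
#'   when `NULL`.
#' @param rupture_threshold force step (pN) treated as a rupture
#'   discontinuity and excluded from the integral (default 300, matching
#'   [event_config()]).
#' @return Adhesion energy in pN nm (>= 0).
#' @export
adhesion_energy <- function(curve, cfg = preprocess_config(), noise_sd = NULL,
                            rupture_threshold = 300) {
  r <- retract_of(curve)
  if (is.null(noise_sd)) noise_sd <- estimate_noise(curve, cfg)
  z <- r$separation; f <- r$force
  adhesive <- f < -cfg$noise_k * noise_sd
  if (!any(adhesive)) return(0)
  n <- length(f)
  both <- adhesive[-n] & adhesive[-1]
  jump <- (f[-1] - f[-n]) >= rupture_threshold
  use <- both & !jump
  if (!any(use)) return(0)
  sum((abs(f[-n]) + abs(f[-1]))[use] / 2 * diff(z)[use])
}

#' Score one curve
#'
#' Runs the full per-curve pipeline: baseline correction, noise estimation,
#' contact-point finding, rupture-event detection, binding classification,
#' maximum adhesion force and adhesion energy.
#'
#' @param curve an [fd_curve()] (raw; baseline correction is applied here).
#' @param pre_cfg a [preprocess_config()].
#' @param ev_cfg an [event_config()].
#' @param smooth apply [smooth_curve()] before detection (default `FALSE`).
#' @return A one-row data.frame: `n_events`, `binding_class`, `f_max_pN`,
#'   `e_adh_pN_nm`, `contact_nm` (NA for no contact).
#' @export
score_curve <- function(curve, pre_cfg = preprocess_config(),
                        ev_cfg = event_config(), smooth = FALSE) {
  cv <- correct_baseline(curve, pre_cfg)
  if (smooth) cv <- smooth_curve(cv, pre_cfg)
  sigma <- estimate_noise(cv, pre_cfg)
  contact <- find_contact_point(cv, pre_cfg, noise_sd = sigma)
  ev <- detect_rupture_events(cv, ev_cfg)
  e <- if (is.na(contact)) 0 else
    adhesion_energy(cv, pre_cfg, noise_sd = sigma,
                    rupture_threshold = ev_cfg$threshold)
  data.frame(n_events = nrow(ev), binding_class = classify_binding(ev),
             f_max_pN = max_adhesion_force(cv), e_adh_pN_nm = e,
             contact_nm = contact)
}

#' Score every curve of a grid
#'
#' @param grid an [fd_grid()].
#' @inheritParams score_curve
#' @return A data.frame of per-curve metrics with a leading `curve_id`
#'   column, one row per curve in grid order.
#' @export
score_grid <- function(grid, pre_cfg = preprocess_config(),
                       ev_cfg = event_config(), smooth = FALSE) {
  stopifnot(inherits(grid, "fd_grid"))
  rows <- lapply(grid$curves, score_curve, pre_cfg = pre_cfg,
                 ev_cfg = ev_cfg, smooth = smooth)
  out <- do.call(rbind, rows)
  cbind(data.frame(curve_id = fd_curve_ids(grid)), out)
}

#' Summarize scored curves of one surface
#'
#' Aggregates per-curve metrics into the surface-level quantities used to
#' compare capture chemistries: prevalence of single and multiple binding,
#' mean and sample SD (n-1) of the maximum adhesion force and adhesion
#' energy over all curves, and class-stratified maximum-adhesion-force
#' statistics (single- versus multiple-binding curves).
#'
#' @param grid an [fd_grid()] (supplies the surface label and curve count),
#'   or a plain surface label string.
#' @param metrics metrics data.frame from [score_grid()], one row per curve.
#' @return An object of class `surface_summary` (a list of named scalars).
#' @export
summarize_surface <- function(grid, metrics) {
  label <- if (inherits(grid, "fd_grid")) grid$surface_label else as.character(grid)
  if (!nrow(metrics)) stop("no metrics to summarize", call. = FALSE)
  if (inherits(grid, "fd_grid") && nrow(metrics) != length(grid$curves))
    stop("one metrics row per curve required", call. = FALSE)
  cls <- metrics$binding_class
  fs <- metrics$f_max_pN[cls == "single"]
  fm <- metrics$f_max_pN[cls == "multiple"]
  sd0 <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_
  mean0 <- function(x) if (length(x)) mean(x) else NA_real_
  structure(list(
    surface_label = label, n_curves = nrow(metrics),
    prevalence_multiple = mean(cls == "multiple"),
    prevalence_single = mean(cls == "single"),
    f_max_mean = mean(metrics$f_max_pN), f_max_sd = sd0(metrics$f_max_pN),
    e_adh_mean = mean(metrics$e_adh_pN_nm), e_adh_sd = sd0(metrics$e_adh_pN_nm),
    f_single_mean = mean0(fs), f_single_sd = sd0(fs),
    f_multiple_mean = mean0(fm), f_multiple_sd = sd0(fm)),
    class = "surface_summary")
}

#' @export
print.surface_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<surface_summary> %s (n = %d)\n",
           "  multiple binding: %.1f%%   single: %.1f%%\n",
           "  F_max: %.1f +/- %.1f pN   E_adh: %.1f +/- %.1f pN nm\n",
           "  F_max | single: %.1f pN   | multiple: %.1f pN\n"),
    x$surface_label, x$n_curves, 100 * x$prevalence_multiple,
    100 * x$prevalence_single, x$f_max_mean, x$f_max_sd, x$e_adh_mean,
    x$e_adh_sd, x$f_single_mean, x$f_multiple_mean))
  invisible(x)
}

#' Force and energy heatmaps of a scored grid
#'
#' Arranges the per-curve maximum adhesion force and adhesion energy on the
#' acquisition raster, as in adhesion force mapping over the scan area.
#'
#' @param grid an [fd_grid()].
#' @param metrics metrics data.frame from [score_grid()] (grid order).
#' @return A list with `f_max` and `e_adh`: `n_rows` x `n_cols` matrices in
#'   pN and pN nm, `NA` at unmeasured positions.
#' @export
build_heatmaps <- function(grid, metrics) {
  stopifnot(inherits(grid, "fd_grid"))
  if (nrow(metrics) != length(grid$curves))
    stop("one metrics row per curve required", call. = FALSE)
  idx <- t(vapply(grid$curves, function(cv) cv$grid_index, integer(2)))
  if (anyDuplicated(idx))
    stop("duplicate grid_index", call. = FALSE)
  fmap <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  emap <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  pos <- cbind(idx[, 1] + 1L, idx[, 2] + 1L)
  fmap[pos] <- metrics$f_max_pN
  emap[pos] <- metrics$e_adh_pN_nm
  list(f_max = fmap, e_adh = emap)
}
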