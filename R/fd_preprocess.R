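#' Preprocessing configuration
#'
#' Controls baseline correction, noise estimation, contact-point finding and
#' optional smoothing of retraction traces before event scoring.
#'
#' @param baseline_fraction fraction of the far-separation end of the retract
#'   trace used for the linear baseline fit and noise estimate (default 0.20).
#' @param smooth_window odd Savitzky-Golay window length in samples
#'   (default 11).
#' @param smooth_order polynomial order of the smoother (default 2); must be
#'   smaller than `smooth_window`.
#' @param noise_k multiplier defining the baseline noise band used to bound
#'   the adhesion-energy integration region (default 3). The band plays no
#'   role in event calling, which uses the fixed force threshold of
#'   [event_config()].
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_fraction = 0.20, smooth_window = 11L,
                              smooth_order = 2L, noise_k = 3) {
  if (!(baseline_fraction > 0 && baseline_fraction <= 0.5))
    stop("baseline_fraction must be in (0, 0.5]", call. = FALSE)
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 3L || smooth_window %% 2L == 0L)
    stop("smooth_window must be odd and >= 3", call. = FALSE)
  if (smooth_order >= smooth_window)
    stop("smooth_order must be < smooth_window", call. = FALSE)
  if (noise_k <= 0) stop("noise_k must be positive", call. = FALSE)
  structure(list(baseline_fraction = baseline_fraction,
                 smooth_window = smooth_window,
                 smooth_order = as.integer(smooth_order),
                 noise_k = noise_k),
            class = "preprocess_config")
}

# indices of the far-field baseline window of a retract trace
baseline_window_idx <- function(n, baseline_fraction) {
  nb <- max(0L, floor(n * baseline_fraction))
  if (nb < 4L) stop("baseline window has fewer than 4 samples", call. = FALSE)
  seq.int(n - nb + 1L, n)
}

#' Subtract a linear far-field baseline from the retract trace
#'
#' Fits a straight line to the farthest `baseline_fraction` of the retract
#' segment (where no specific tip-surface interaction persists) and subtracts
#' it from the whole retract trace, so that the far-field force is zero up to
#' noise. All scoring quantities (the 300 pN event threshold, the maximum
#' adhesion force, the adhesion energy) are defined against this zero
#' baseline. Idempotent up to numerical precision.
#'
#' @param curve an [fd_curve()] with a retract segment.
#' @param cfg a [preprocess_config()].
#' @return The curve with baseline-corrected retract forces.
#' @export
correct_baseline <- function(curve, cfg = preprocess_config()) {
  r <- retract_of(curve)
  idx <- baseline_window_idx(length(r$force), cfg$baseline_fraction)
  z <- r$separation[idx]; f <- r$force[idx]
  zc <- z - mean(z)
  slope <- sum(zc * f) / sum(zc^2)
  intercept <- mean(f) - slope * mean(z)
  corrected <- r$force - (intercept + slope * r$separation)
  replace_retract_force(curve, corrected)
}

#' Robust baseline noise estimate
#'
#' Median-absolute-deviation estimate (scaled by 1.4826 for consistency with
#' the Gaussian SD) of the force noise in the far-field baseline window of a
#' baseline-corrected retract trace. Robust against an occasional rupture
#' tail or spike reaching into the window.
#'
#' @inheritParams correct_baseline
#' @return Noise standard deviation in pN.
#' @export
estimate_noise <- function(curve, cfg = preprocess_config()) {
  r <- retract_of(curve)
  idx <- baseline_window_idx(length(r$force), cfg$baseline_fraction)
  f <- r$force[idx]
  stats::median(abs(f - stats::median(f))) * 1.4826
}

#' Find the contact point of a retract trace
#'
#' The contact point is the inner limit of the adhesive region: scanning the
#' baseline-corrected retract trace outward from zero separation, it is the
#' separation of the first sample whose force lies outside the noise band
#' `|F| > noise_k * sigma`. A trace that starts outside the band at z = 0
#' yields 0; a trace lying entirely inside the band carries no adhesion and
#' yields `NA` (the "no contact" signal — not an error; callers treat the
#' adhesion energy as 0).
#'
#' @inheritParams correct_baseline
#' @param noise_sd baseline noise SD in pN; estimated with [estimate_noise()]
#'   when `NULL`.
#' @return Contact-point separation in nm, or `NA_real_` for no contact.
#' @export
find_contact_point <- function(curve, cfg = preprocess_config(),
                               noise_sd = NULL) {
  r <- retract_of(curve)
  if (is.null(noise_sd)) noise_sd <- estimate_noise(curve, cfg)
  out <- which(abs(r$force) > cfg$noise_k * noise_sd)
  if (!length(out)) return(NA_real_)
  r$separation[out[1]]
}

#' Savitzky-Golay smoothing of the force channel
#'
#' Local polynomial smoothing (order `smooth_order`, window `smooth_window`)
#' of the retract force trace; the separation grid is untouched and the
#' sample count preserved. Polynomial smoothing reproduces constants and
#' straight lines exactly. Smoothing is optional in the scoring pipeline and
#' off by default: the event threshold sits far above the baseline noise, and
#' a window comparable to the rupture ramp width would attenuate genuine
#' rupture jumps.
#'
#' @inheritParams correct_baseline
#' @return The curve with smoothed retract forces.
#' @export
smooth_curve <- function(curve, cfg = preprocess_config()) {
  r <- retract_of(curve)
  if (cfg$smooth_window > length(r$force))
    stop("smooth_window exceeds retract trace length", call. = FALSE)
  sm <- signal::sgolayfilt(r$force, p = cfg$smooth_order, n = cfg$smooth_window)
  replace_retract_force(curve, sm)
}
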