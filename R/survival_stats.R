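#' Construct survival records
#'
#' A survival record is a (time, event, marker) triple: follow-up time in
#' months, an event flag (`TRUE` = death observed, `FALSE` = censored) and a
#' biomarker value (e.g. the PD-L1+ exosome enrichment efficiency).
#'
#' @param time positive finite follow-up times (months).
#' @param event logical (or 0/1) event indicators.
#' @param marker numeric biomarker values (default `NA`).
#' @return A data.frame of class `survival_records`.
#' @export
survival_records <- function(time, event, marker = NA_real_) {
  time <- as.numeric(time)
  event <- as.logical(event)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("time must be finite and positive", call. = FALSE)
  if (any(is.na(event))) stop("event flags must not be NA", call. = FALSE)
  out <- data.frame(time = time, event = event, marker = marker)
  class(out) <- c("survival_records", "data.frame")
  out
}

as_survival_records <- function(x) {
  if (inherits(x, "survival_records")) return(x)
  stopifnot(is.data.frame(x), all(c("time", "event") %in% names(x)))
  survival_records(x$time, x$event,
                   if ("marker" %in% names(x)) x$marker else NA_real_)
}

#' Kaplan-Meier product-limit estimator
#'
#' Survival step function with risk table. At each distinct event time t,
#' the survival probability is multiplied by `1 - d_t / n_t`; censored
#' times reduce the risk set without a step.
#'
#' @param records a [survival_records()] data.frame.
#' @return An object of class `km_fit`: a list with `table` (data.frame with
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv` at each distinct
#'   observed time) and `n`.
#' @export
km_estimate <- function(records) {
  records <- as_survival_records(records)
  if (!nrow(records)) stop("km_estimate needs n >= 1", call. = FALSE)
  tt <- sort(unique(records$time))
  n_risk <- vapply(tt, function(t) sum(records$time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(records$time == t & records$event),
                    numeric(1))
  n_censor <- vapply(tt, function(t) sum(records$time == t & !records$event),
                     numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(table = data.frame(time = tt, n_risk = n_risk,
                                    n_event = n_event, n_censor = n_censor,
                                    surv = surv),
                 n = nrow(records)),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier fit at given times
#'
#' @param fit a `km_fit` from [km_estimate()].
#' @param times numeric times.
#' @return Survival probabilities (1 before the first observed time).
#' @export
km_survival_at <- function(fit, times) {
  stopifnot(inherits(fit, "km_fit"))
  vapply(times, function(t) {
    i <- which(fit$table$time <= t)
    if (!length(i)) 1 else fit$table$surv[max(i)]
  }, numeric(1))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d, %d events over %d distinct times, S(max) = %.3f\n",
              x$n, sum(x$table$n_event), nrow(x$table),
              x$table$surv[nrow(x$table)]))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square on 1 degree of freedom with
#' hypergeometric variance at each distinct event time; two-sided p.
#'
#' @param group_a,group_b [survival_records()] data.frames.
#' @return A `test_result` with `test_name = "logrank"`; `statistic` is the
#'   chi-square.
#' @export
logrank_test <- function(group_a, group_b) {
  group_a <- as_survival_records(group_a)
  group_b <- as_survival_records(group_b)
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  grp <- rep(1:2, c(nrow(group_a), nrow(group_b)))
  if (!any(event)) stop("no events in either group", call. = FALSE)
  tt <- sort(unique(time[event]))
  o1 <- e1 <- v <- 0
  for (t in tt) {
    at_risk <- time >= t
    n_t <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d_t <- sum(time == t & event); d1 <- sum(time == t & event & grp == 1)
    o1 <- o1 + d1
    e1 <- e1 + d_t * n1 / n_t
    if (n_t > 1)
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  test_result("logrank", stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
              nrow(group_a), nrow(group_b))
}

# Breslow partial-likelihood derivatives for a single covariate at beta:
# returns log-likelihood, score U and information I (and the event count)
cox_derivs <- function(time, event, x, beta) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ebx <- exp(beta * x)
  s0 <- rev(cumsum(rev(ebx)))          # sum over {time >= t_i} (ascending)
  s1 <- rev(cumsum(rev(x * ebx)))
  s2 <- rev(cumsum(rev(x^2 * ebx)))
  # first index of each tied time block = risk-set boundary
  first <- !duplicated(time)
  block <- cumsum(first)
  f_idx <- which(first)[block]          # map each row to its block start
  ev <- which(event)
  S0 <- s0[f_idx[ev]]; S1 <- s1[f_idx[ev]]; S2 <- s2[f_idx[ev]]
  list(loglik = sum(beta * x[ev] - log(S0)),
       score = sum(x[ev] - S1 / S0),
       info = sum(S2 / S0 - (S1 / S0)^2),
       n_events = length(ev))
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the Breslow partial likelihood for a single covariate by
#' Newton-Raphson (at most 50 iterations, score tolerance 1e-8). The
#' covariate is the raw marker (`binary = FALSE`, the non-categorical
#' model) or the high/low indicator of the median split (`binary = TRUE`).
#' Monotone likelihoods (complete separation of the event order by the
#' covariate) are flagged non-converged with `|beta|` capped at 20. The
#' score test statistic at beta = 0 equals the log-rank chi-square on
#' tie-free two-group data and is returned for cross-checking.
#'
#' @param records a [survival_records()] data.frame with markers.
#' @param binary use the median-split indicator as covariate (default
#'   `FALSE`).
#' @return An object of class `cox_fit`: `beta`, `hr = exp(beta)`, `se`,
#'   `p_value` (Wald), `score_stat`, `converged`, `n_events`, `n`.
#' @export
cox_univariate <- function(records, binary = FALSE) {
  records <- as_survival_records(records)
  if (sum(records$event) < 2)
    stop("cox_univariate needs >= 2 events", call. = FALSE)
  x <- if (binary) as.numeric(records$marker >= stats::median(records$marker))
  else as.numeric(records$marker)
  if (any(is.na(x))) stop("marker values required", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant covariate", call. = FALSE)
  x <- x - mean(x)   # centering: numerical stability, beta unchanged
  beta <- 0; converged <- FALSE
  cap <- 20
  for (it in seq_len(50L)) {
    d <- cox_derivs(records$time, records$event, x, beta)
    if (abs(d$score) < 1e-8) { converged <- TRUE; break }
    step <- d$score / d$info
    beta <- beta + sign(step) * min(abs(step), 2)   # damped step
    if (abs(beta) >= cap) { beta <- sign(beta) * cap; break }
  }
  d <- cox_derivs(records$time, records$event, x, beta)
  d0 <- cox_derivs(records$time, records$event, x, 0)
  se <- if (d$info > 0) 1 / sqrt(d$info) else Inf
  z <- if (is.finite(se) && se > 0) beta / se else 0
  structure(list(beta = beta, hr = exp(beta), se = se,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 score_stat = d0$score^2 / d0$info,
                 converged = converged, n_events = d$n_events,
                 n = nrow(records)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "<cox_fit> HR = %.3f (beta = %.3f, se = %.3f), Wald p = %.4g, %d events%s\n",
    x$hr, x$beta, x$se, x$p_value, x$n_events,
    if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}
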