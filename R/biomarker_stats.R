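#' Enrichment ratio between a target and a control signal
#'
#' Captured-signal ratio between a targeting surface and its negative
#' control (e.g. total exosomal protein on the avidity surface versus the
#' scrambled-peptide surface), the quantity used as the "PD-L1+ exosome
#' enrichment efficiency" biomarker.
#'
#' @param target_signal non-negative signal on the targeting surface.
#' @param control_signal positive signal on the control surface.
#' @return `target_signal / control_signal`.
#' @export
enrichment_ratio <- function(target_signal, control_signal) {
  if (any(control_signal <= 0))
    stop("control signal must be positive", call. = FALSE)
  if (any(target_signal < 0))
    stop("target signal must be non-negative", call. = FALSE)
  target_signal / control_signal
}

test_result <- function(test_name, statistic, p_value, n1, n2 = NA_integer_) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n1 = n1, n2 = n2),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (n1 = %d%s)\n",
              x$test_name, x$statistic, x$p_value, x$n1,
              if (is.na(x$n2)) "" else sprintf(", n2 = %d", x$n2)))
  invisible(x)
}

# asymptotic Kolmogorov distribution tail Q(t) = 2 sum (-1)^(k-1) exp(-2 k^2 t^2)
kolmogorov_tail <- function(t) {
  if (t < 0.2) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' KS statistic of the sample against a normal distribution with the
#' sample's own mean and SD, with the asymptotic p-value. This is the
#' normality gate used before choosing between the t-test and the
#' Mann-Whitney U test. (Estimating the reference parameters from the same
#' sample makes the test conservative; a sample that fails it is decidedly
#' non-normal.)
#'
#' @param sample numeric vector, n >= 5, non-degenerate.
#' @return A `test_result` with `test_name = "ks"`.
#' @export
ks_normality <- function(sample) {
  n <- length(sample)
  if (n < 5) stop("ks_normality needs n >= 5", call. = FALSE)
  s <- stats::sd(sample)
  if (!is.finite(s) || s == 0)
    stop("degenerate (zero-variance) sample", call. = FALSE)
  x <- sort(sample)
  p <- stats::pnorm(x, mean(sample), s)
  d <- max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
  test_result("ks", d, kolmogorov_tail(sqrt(n) * d), n)
}

# exact null distribution of the Mann-Whitney U statistic:
# counts[u + 1] = number of rank allocations with U = u, u in 0..n1*n2,
# by the recurrence f(u; n, m) = f(u - m; n-1, m) + f(u; n, m-1)
mwu_null_counts <- function(n1, n2) {
  prev <- rep(list(1), n2 + 1)            # n = 0: U is always 0
  for (n in seq_len(n1)) {
    cur <- vector("list", n2 + 1)
    cur[[1]] <- 1                          # m = 0
    for (m in seq_len(n2)) {
      a <- prev[[m + 1]]                   # (n-1, m), shifted by m
      b <- cur[[m]]                        # (n, m-1)
      len <- n * m + 1
      av <- numeric(len); av[(m + 1):(m + length(a))] <- a
      bv <- numeric(len); bv[seq_along(b)] <- b
      cur[[m + 1]] <- av + bv
    }
    prev <- cur
  }
  prev[[n2 + 1]]
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test implemented from first principles. With no ties and
#' `n1 + n2 <= 30` the p-value is exact (two-sided doubled tail of the
#' enumerated null distribution of U); otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param a,b numeric samples.
#' @return A `test_result` with `test_name = "mann_whitney"`; `statistic` is
#'   U for the first sample.
#' @export
mann_whitney_u <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && n1 + n2 <= 30) {
    counts <- mwu_null_counts(n1, n2)
    total <- sum(counts)
    lower <- sum(counts[seq_len(u + 1)]) / total          # P(U <= u)
    upper <- sum(counts[(u + 1):length(counts)]) / total  # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1))
    v <- n1 * n2 / 12 * (n1 + n2 + 1 - tie_term)
    if (v <= 0) stop("degenerate samples (all values tied)", call. = FALSE)
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  test_result("mann_whitney", u, p, n1, n2)
}

#' Welch two-sample t-test (two-sided)
#'
#' Unequal-variance t-test from the closed form; used when both groups pass
#' the normality gate. Welch rather than pooled because the group variances
#' of the force data differ by orders of magnitude.
#'
#' @param a,b numeric samples.
#' @return A `test_result` with `test_name = "t"`.
#' @export
welch_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a) / n1; v2 <- stats::var(b) / n2
  if (v1 + v2 <= 0) stop("degenerate samples", call. = FALSE)
  tstat <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  test_result("t", tstat, min(1, 2 * stats::pt(-abs(tstat), df)), n1, n2)
}

#' Normality-gated two-group comparison
#'
#' The comparison rule applied throughout: assess each group's distribution
#' with the Kolmogorov-Smirnov test; when both groups are consistent with
#' normality at level `alpha`, compare them with the two-sided Welch t-test,
#' otherwise with the two-sided Mann-Whitney U test. The returned result
#' labels which test ran.
#'
#' @param a,b numeric samples, each n >= 3.
#' @param alpha level of the normality gate (default 0.05).
#' @return A `test_result`; `test_name` is `"t"` or `"mann_whitney"`.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3)
    stop("compare_groups needs n >= 3 per group", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(test_result("mann_whitney", length(a) * length(b) / 2, 1,
                       length(a), length(b)))
  normal_ok <- function(x) {
    if (length(x) < 5 || stats::sd(x) == 0) return(FALSE)
    ks_normality(x)$p_value > alpha
  }
  if (normal_ok(a) && normal_ok(b)) welch_t(a, b) else mann_whitney_u(a, b)
}

#' Empirical ROC AUC
#'
#' Probability that a randomly drawn positive score exceeds a randomly
#' drawn negative one, ties counted one half — the Mann-Whitney identity
#' AUC = U / (n_pos * n_neg), computed from midranks.
#'
#' @param pos scores of the positive class.
#' @param neg scores of the negative class.
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  if (!n1 || !n2) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Median split of survival records
#'
#' Splits records at the median biomarker value; records with marker at or
#' above the median go to the high group (the tie rule is fixed for
#' reproducibility). The median is the standard midpoint
#' (`stats::median`).
#'
#' @param records a survival data.frame with columns `time`, `event`,
#'   `marker` (see [survival_records()]).
#' @return List with `high` and `low` data.frames.
#' @export
median_split <- function(records) {
  records <- as_survival_records(records)
  if (nrow(records) < 2) stop("median_split needs n >= 2", call. = FALSE)
  if (length(unique(records$marker)) == 1L)
    stop("all marker values identical; split undefined", call. = FALSE)
  med <- stats::median(records$marker)
  list(high = records[records$marker >= med, , drop = FALSE],
       low = records[records$marker < med, , drop = FALSE])
}

#' Power of a two-group survival comparison (Schoenfeld formula)
#'
#' `power = Phi( sqrt(d * p * (1 - p)) * |ln HR| - z_(1 - alpha/2) )` for a
#' log-rank / Cox comparison with `d` observed events and allocation
#' fraction `p`.
#'
#' @param hr hazard ratio (> 0).
#' @param d total number of observed events (>= 1).
#' @param p_alloc allocation fraction of one group, in (0, 1) (default 0.5).
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @examples
#' schoenfeld_power(hr = 8.861, d = 5)  # ~0.68
#' schoenfeld_power(hr = 8.861, d = 6)  # ~0.76
#' @export
schoenfeld_power <- function(hr, d, p_alloc = 0.5, alpha = 0.05) {
  if (any(hr <= 0)) stop("hr must be positive", call. = FALSE)
  if (any(d < 1)) stop("d must be >= 1", call. = FALSE)
  if (any(p_alloc <= 0 | p_alloc >= 1))
    stop("p_alloc must be in (0,1)", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0,1)", call. = FALSE)
  stats::pnorm(sqrt(d * p_alloc * (1 - p_alloc)) * abs(log(hr)) -
                 stats::qnorm(1 - alpha / 2))
}

#' Simulate a two-group survival cohort with a median-split hazard contrast
#'
#' Synthetic stand-in for a biomarker cohort: markers are lognormal;
#' subjects with marker at or above the cohort median have exponential
#' survival with hazard `hr` times the baseline; follow-up is censored
#' administratively at `followup` months.
#'
#' @param n cohort size.
#' @param hr true hazard ratio of the high-marker group (default 2).
#' @param baseline_median_months median survival of the low-marker group
#'   (default 24).
#' @param followup administrative censoring time in months (default `Inf`,
#'   i.e. all events observed).
#' @param seed integer seed.
#' @return A survival data.frame (`time`, `event`, `marker`); see
#'   [survival_records()].
#' @export
simulate_survival_cohort <- function(n, hr = 2, baseline_median_months = 24,
                                     followup = Inf, seed = 1L) {
  set.seed(as.integer(seed %% 2147483647))
  marker <- stats::rlnorm(n, 0, 0.5)
  high <- marker >= stats::median(marker)
  lambda0 <- log(2) / baseline_median_months
  t_true <- stats::rexp(n, rate = lambda0 * ifelse(high, hr, 1))
  time <- pmin(t_true, followup)
  survival_records(time = time, event = t_true <= followup, marker = marker)
}
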