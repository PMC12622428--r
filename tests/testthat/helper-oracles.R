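# independent brute-force oracles used across the suite

# two-sided exact Mann-Whitney p by enumerating every allocation of the
# pooled sample into groups of the observed sizes
brute_mwu_p <- function(a, b) {
  n1 <- length(a)
  x <- c(a, b)
  r <- rank(x)
  combs <- utils::combn(length(x), n1)
  us <- apply(combs, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# AUC as the literal pairwise probability, ties counted one half
brute_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# empirical survival function (no censoring): fraction still alive after t
empirical_surv <- function(times, t) mean(times > t)

# a pure-noise profile: no bonds, no nonspecific dip
noise_only_profile <- function(noise_sd = 30, sample_spacing = 0.05) {
  surface_profile(name = "noise", bond_count_pmf = c("0" = 1),
                  noise_sd = noise_sd, nonspecific_depth = 0,
                  sample_spacing = sample_spacing)
}
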