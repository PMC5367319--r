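# Shared fixtures and moment-comparison helpers.

# Reference parameter sets used across tests (two-island distance trajectory
# regime and the standard waiting-time regimes).
fig2a_params <- function(zc = 0.8)
  island_params(u = 2e-4, m = 0.015, eps = 0.01, l = 20, zc = zc)

# z-scores of empirical moments of iid draws (n x 5 matrix) against an
# analytic mean vector and covariance matrix. SEs are estimated from the
# draws themselves (including the SE of each variance/covariance entry via
# the fourth moments), so each z is approximately standard normal when the
# analytic moments are correct.
moment_zscores <- function(draws, mean_ref, cov_ref) {
  n <- nrow(draws)
  mu <- colMeans(draws)
  se_mu <- apply(draws, 2L, stats::sd) / sqrt(n)
  z_mean <- (mu - mean_ref) / ifelse(se_mu > 0, se_mu, Inf)
  ctr <- sweep(draws, 2L, mu)
  z_cov <- matrix(NA_real_, 5L, 5L)
  for (i in 1:5) for (j in i:5) {
    prod_ij <- ctr[, i] * ctr[, j]
    se <- stats::sd(prod_ij) / sqrt(n)
    z <- (mean(prod_ij) - cov_ref[i, j]) / ifelse(se > 0, se, Inf)
    # entries that are exactly zero in both should not register
    if (se == 0 && abs(cov_ref[i, j]) < 1e-15) z <- 0
    z_cov[i, j] <- z_cov[j, i] <- z
  }
  list(mean = z_mean, cov = z_cov)
}

# Family-wise critical value at the 3-sigma confidence level for n_checks
# simultaneous two-sided comparisons (Bonferroni).
zcrit_family <- function(n_checks) {
  alpha <- 2 * stats::pnorm(-3)
  stats::qnorm(1 - alpha / (2 * n_checks))
}
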