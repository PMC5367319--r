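# Exact per-locus jump process: rates, event application, Gillespie runs and
# the moment probe.

test_that("event rates follow the per-locus and per-bond bookkeeping", {
  p <- island_params(u = 2e-4, m = 0.01, eps = 0.01, l = 20, zc = 1)
  st <- locus_state(20, 3L)
  r <- event_rates(st, p)
  expect_equal(sum(r$mutation), 3 * 2e-4 * 20)  # 0.012
  expect_equal(sum(r$migration), 6 * 0.01)
  # closed bonds drop out
  r2 <- event_rates(st, p, open = c(AB = FALSE, BC = TRUE, CA = TRUE))
  expect_equal(unname(r2$migration[c("AB", "BA")]), c(0, 0))
  # no migration at all
  p0 <- island_params(u = 2e-4, m = 0, l = 20)
  expect_equal(sum(event_rates(st, p0)$migration), 0)
})

test_that("mutation events relabel a single locus", {
  st <- locus_state(5, 3L, init = c(1L, 2L, 3L, 4L, 5L))
  st2 <- apply_mutation(st, "A", 1L)
  expect_equal(as.integer(st2), c(2L, 2L, 3L, 4L, 5L))
  expect_equal(as.integer(apply_mutation(st, "A", 5L)), as.integer(st))
})

test_that("migration events flip eligible loci with probability eps", {
  st <- locus_state(30, 3L, init = 2L)
  expect_equal(as.integer(apply_migration(st, "AB", eps = 0)), rep(2L, 30))
  expect_equal(as.integer(apply_migration(st, "AB", eps = 1)), rep(4L, 30))
  # expected flipped count is l * z_i * eps
  set.seed(41)
  flips <- replicate(2000, sum(unclass(
    apply_migration(st, "AB", eps = 0.2)) == 4L))
  se <- stats::sd(flips) / sqrt(length(flips))
  expect_lt(abs(mean(flips) - 30 * 0.2), 3 * se)
})

test_that("the jump process conserves locus counts and stays flat without rates", {
  p <- island_params(u = 0, m = 0, l = 15, zc = 1)
  run <- jump_simulate(p, t_max = 100, record_stride = 10, seed = 42)
  expect_true(all(run$z1 == 1))
  p2 <- island_params(u = 1e-3, m = 0.05, eps = 0.05, l = 15, zc = 1)
  run2 <- jump_simulate(p2, t_max = 2000, record_stride = 10, seed = 43)
  sums <- rowSums(run2[, paste0("z", 1:5)])
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the two-island reduction fluctuates around u/(u + m*eps)", {
  p <- island_params(u = 2e-4, m = 0.015, eps = 0.05, l = 50, zc = 1)
  run <- jump_simulate(p, t_max = 6e4, record_stride = 20, seed = 44,
                       n_islands = 2L)
  zbar <- mean(run$z[run$t > 1.5e4])
  zstar <- two_island_equilibrium(p)
  expect_lt(abs(zbar - zstar), 0.08)
})

test_that("moment probe rejects fractional locus counts", {
  p <- island_params(u = 1e-4, m = 0.01, l = 10, zc = 1)
  expect_error(moment_probe(c(0.25, 0.25, 0.25, 0.15, 0.10), p),
               "whole numbers")
})

test_that("oracle one-interval moments match the SDE coefficients", {
  # the exact jump process is the ground truth for the drift, the variance
  # and the within-bond covariance of the five increments
  # u is set so that mutation events are not ultra-rare at dt = 1: the
  # empirical covariance estimator (and its SE) for the mutation cross terms
  # is only well behaved when coincident events have appreciable probability
  # at the replicate counts used
  p <- suppressWarnings(
    island_params(u = 2e-3,
                  m = c(AB = 0.03, BA = 0.015, AC = 0.01, CA = 0.02,
                        BC = 0.025, CB = 0.01),
                  eps = 0.08, l = 20, zc = 1))
  # all five configurations populated in every state (at a strict boundary
  # several entries have no first-order moment and the comparison against
  # instantaneous coefficients is ill-posed)
  states <- list(c(0.60, 0.10, 0.10, 0.10, 0.10),
                 c(0.25, 0.25, 0.25, 0.15, 0.10),
                 c(0.05, 0.30, 0.30, 0.30, 0.05),
                 c(0.10, 0.10, 0.20, 0.30, 0.30),
                 c(0.10, 0.15, 0.15, 0.10, 0.50))
  n_checks <- 5 * (5 + 15)
  crit <- zcrit_family(n_checks)
  for (s in seq_along(states)) {
    mp <- moment_probe(states[[s]], p, dt = 1, reps = 2e4,
                       seed = 45 + s)
    an <- three_island_moments(states[[s]], p, dt = 1)
    zz <- moment_zscores(mp$draws, an$mean, an$cov)
    expect_lt(max(abs(zz$mean)), crit)
    expect_lt(max(abs(zz$cov), na.rm = TRUE), crit)
  }
})

test_that("oracle and SDE waiting times are statistically compatible", {
  # moderate regime (the diffusion approximation needs many loci; at small l
  # the Gaussian step distorts the early dynamics near z1 = 1)
  p <- island_params(u = 2e-4, m = 0.01, eps = 0.03, l = 50, zc = 0.35)
  reps <- 30
  sde <- three_island_waiting_times(p, reps = reps, t_max = 2e5, seed = 46)
  tau_o <- vapply(seq_len(reps), function(r) {
    run <- jump_simulate(p, t_max = 2e5, record_stride = 2e5,
                         seed = replicate_seed(47, r),
                         stop_at_speciation = TRUE)
    attr(run, "record")$tau2
  }, numeric(1))
  expect_true(all(!is.na(sde$tau2)))
  expect_true(all(!is.na(tau_o)))
  # two-sample location test at alpha = 0.01
  pv <- stats::wilcox.test(sde$tau2, tau_o, exact = FALSE)$p.value
  expect_gt(pv, 0.01)
})
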