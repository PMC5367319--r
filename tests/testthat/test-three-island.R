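# Three-island GC dynamics: transition maps, increment operators, stepping,
# trajectories.

test_that("mutation transitions strip the mutated island from its group", {
  expect_equal(mutation_transition(1, "A"), 2)  # (ABC) -> (A)(BC)
  expect_equal(mutation_transition(1, "B"), 3)
  expect_equal(mutation_transition(1, "C"), 4)
  expect_equal(mutation_transition(2, "B"), 5)  # (A)(BC) -> (A)(B)(C)
  expect_equal(mutation_transition(2, "C"), 5)
  expect_equal(mutation_transition(2, "A"), 2)  # already private: no change
  expect_equal(mutation_transition(3, "A"), 5)
  expect_equal(mutation_transition(4, "A"), 5)
  expect_equal(mutation_transition(5, "C"), 5)
  expect_error(mutation_transition(6, "A"), "1..5")
})

test_that("migration transitions reproduce the full bond table", {
  # 18 transitions, three per directed bond; configurations in which source
  # and destination share the allele are fixed points (NA)
  tbl <- list(AB = c("2" = 4, "3" = 1, "5" = 4),
              BA = c("2" = 1, "3" = 4, "5" = 4),
              AC = c("2" = 3, "4" = 1, "5" = 3),
              CA = c("2" = 1, "4" = 3, "5" = 3),
              BC = c("3" = 2, "4" = 1, "5" = 2),
              CB = c("3" = 1, "4" = 2, "5" = 2))
  for (bond in names(tbl)) {
    for (cfg in 1:5) {
      expected <- tbl[[bond]][as.character(cfg)]
      got <- migration_transition(cfg, bond)
      if (is.na(expected)) expect_true(is.na(got)) else
        expect_equal(got, unname(expected))
    }
  }
})

test_that("mutation increments conserve mass and have the right mean", {
  p <- island_params(u = 2e-4, m = 0, l = 50, zc = 1)
  # configuration 5 is absorbing under mutation
  expect_equal(mutation_increment(c(0, 0, 0, 0, 1), p), rep(0, 5))
  # from z1 = 1 the mean loss of z1 is 3*u*dt; checked in the regime where
  # the Gaussian flows are valid (u*dt*l >> 1, so the boundary caps almost
  # never bind)
  pv <- island_params(u = 2e-4, m = 0, l = 1000, zc = 1)
  set.seed(31)
  reps <- 3000
  dt <- 50
  dz1 <- replicate(reps,
                   mutation_increment(c(1, 0, 0, 0, 0), pv, dt = dt)[1])
  se <- stats::sd(dz1) / sqrt(reps)
  expect_lt(abs(mean(dz1) - (-3 * pv$u * dt)), 3 * se)
  # exact conservation of each draw
  for (i in 1:20) {
    gc <- normalize_gc(stats::runif(5))
    expect_equal(sum(mutation_increment(gc, p)), 0, tolerance = 1e-15)
  }
  # infinite l: deterministic increments equal to the mean terms
  pinf <- island_params(u = 2e-4, m = 0, l = Inf, zc = 1)
  gc <- c(0.4, 0.3, 0.1, 0.1, 0.1)
  expect_equal(mutation_increment(gc, pinf),
               three_island_moments(gc, pinf)$mean, ignore_attr = TRUE)
})

test_that("migration increments conserve mass and respect the bond table", {
  p <- suppressWarnings(
    island_params(u = 0, m = 0.4, eps = 0.3, l = 25, zc = 1))
  # configuration 1 has no outgoing transition
  set.seed(32)
  expect_equal(migration_increment(c(1, 0, 0, 0, 0), p), rep(0, 5))
  for (i in 1:20) {
    gc <- normalize_gc(stats::runif(5))
    dz <- migration_increment(gc, p)
    expect_equal(sum(dz), 0, tolerance = 1e-15)
    expect_true(all(unclass(gc) + dz >= -1e-12))  # outflow caps hold
  }
  # closed bonds contribute nothing
  dz <- migration_increment(c(0.2, 0.2, 0.2, 0.2, 0.2), p,
                            open = c(FALSE, FALSE, FALSE))
  expect_equal(dz, rep(0, 5))
})

test_that("one A->B migration event cannot move the B-C distance in case 1", {
  # gc = (1/3, 0, 0, 0, 2/3): the only enabled transition under bond AB is
  # 5 -> 4, which shuffles mass inside the zBC = z3+z4+z5 sum
  pab <- island_params(u = 0, m = c(AB = 0.5, BA = 0, AC = 0, CA = 0,
                                    BC = 0, CB = 0), eps = 0.1, l = 30,
                       zc = 1)
  gc1 <- c(1 / 3, 0, 0, 0, 2 / 3)
  set.seed(33)
  for (i in 1:200) {
    dz <- migration_increment(gc1, pab)
    expect_equal(sum(dz[3:5]), 0, tolerance = 1e-15)
  }
  # while in case 2 the same event does perturb zBC
  gc2 <- c(0, 1 / 3, 1 / 3, 1 / 3, 0)
  dzBC <- replicate(200, sum(migration_increment(gc2, pab)[3:5]))
  expect_gt(stats::sd(dzBC), 0)
})

test_that("stepping preserves the unit sum and is inert without rates", {
  p0 <- island_params(u = 0, m = 0, l = 20, zc = 1)
  st <- list(t = 0, gc = gc_fractions(c(0.2, 0.2, 0.2, 0.2, 0.2)),
             graph = bond_graph())
  st2 <- step_three_island(st, p0)
  expect_equal(unclass(st2$gc), unclass(st$gc), ignore_attr = TRUE)
  expect_equal(st2$t, 1)
  p <- island_params(u = 5e-4, m = 0.05, eps = 0.05, l = 10, zc = 1)
  set.seed(34)
  for (i in 1:50) {
    st <- step_three_island(st, p)
    expect_equal(sum(st$gc), 1, tolerance = 1e-12)
  }
})

test_that("symmetric migration keeps the three distances statistically equal", {
  p <- island_params(u = 1e-4, m = 0.005, eps = 0.01, l = 100, zc = 1)
  tr <- simulate_three_island(p, t_max = 4e4, record_stride = 10L,
                              seed = 35)
  post <- tr[tr$t > 1e4, ]
  means <- colMeans(post[, c("zAB", "zBC", "zCA")])
  expect_lt(max(means) - min(means), 0.12)
  expect_equal(rowSums(post[, paste0("z", 1:5)]), rep(1, nrow(post)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("an isolated island accumulates the largest distances", {
  # island A nearly cut off: its private configuration dominates and the
  # distances involving A exceed the B-C distance on average
  p <- island_params(u = 1e-4, eps = 0.01, l = 100, zc = 1,
                     m = c(AB = 0.001, BC = 0.01, CA = 0.001))
  tr <- simulate_three_island(p, t_max = 6e4, record_stride = 10L,
                              seed = 36)
  post <- tr[tr$t > 2e4, ]
  expect_gt(mean(post$z2), mean(post$z3))
  expect_gt(mean(post$z2), mean(post$z4))
  expect_gt(mean(post$zAB), mean(post$zBC))
  expect_gt(mean(post$zCA), mean(post$zBC))
})

test_that("a zero threshold splits the islands immediately", {
  p <- island_params(u = 1e-3, m = 0, l = 10, zc = 0)
  wt <- three_island_waiting_times(p, reps = 10, t_max = 1e3, seed = 37)
  expect_true(all(wt$tau2 <= 50))
  expect_true(all(wt$tau3 >= wt$tau2))
})

test_that("waiting times are reproducible and tau3 never precedes tau2", {
  p <- island_params(u = 7.5e-5, m = 0.01, eps = 0.01, l = 20, zc = 0.3)
  a <- three_island_waiting_times(p, reps = 8, t_max = 1e5, seed = 38)
  b <- three_island_waiting_times(p, reps = 8, t_max = 1e5, seed = 38)
  expect_identical(a, b)
  done <- !a$censored3
  expect_true(all(a$tau3[done] >= a$tau2[done]))
})
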