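# GC algebra, distance mapping and the speciation predicate.

test_that("pairwise distances follow the configuration sums", {
  # two GC vectors with identical distance triplets (2/3, 2/3, 2/3)
  expect_equal(unname(gc_distances(c(1 / 3, 0, 0, 0, 2 / 3))),
               rep(2 / 3, 3))
  expect_equal(unname(gc_distances(c(0, 1 / 3, 1 / 3, 1 / 3, 0))),
               rep(2 / 3, 3))
  expect_equal(unname(gc_distances(c(1, 0, 0, 0, 0))), c(0, 0, 0))
  expect_equal(unname(gc_distances(c(0, 0, 0, 0, 1))), c(1, 1, 1))
  expect_error(gc_distances(c(-0.1, 0.4, 0.4, 0.3, 0)), "\\[0, 1\\]")
  expect_error(gc_distances(c(0.3, 0.3, 0.3, 0.3, 0.3)), "sum to 1")
})

test_that("distance map is linear and satisfies the triangle bound", {
  set.seed(11)
  for (i in 1:50) {
    a <- normalize_gc(stats::runif(5))
    b <- normalize_gc(stats::runif(5))
    w <- stats::runif(1)
    mix <- w * unclass(a) + (1 - w) * unclass(b)
    expect_equal(gc_distances(mix),
                 w * gc_distances(a) + (1 - w) * gc_distances(b))
    d <- gc_distances(a)
    expect_lte(d[["zAB"]], d[["zBC"]] + d[["zCA"]] + 1e-12)
    expect_lte(d[["zBC"]], d[["zAB"]] + d[["zCA"]] + 1e-12)
    expect_lte(d[["zCA"]], d[["zAB"]] + d[["zBC"]] + 1e-12)
  }
})

test_that("normalize_gc clips then rescales to unit sum", {
  expect_equal(unclass(normalize_gc(c(0.5, 0.5, 0, 0, 0))),
               c(0.5, 0.5, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(unclass(normalize_gc(c(-0.01, 0.51, 0.5, 0, 0))),
               c(0, 0.51, 0.5, 0, 0) / 1.01, ignore_attr = TRUE)
  expect_equal(unclass(normalize_gc(c(0, 0, 0, 0, 2))),
               c(0, 0, 0, 0, 1), ignore_attr = TRUE)
  expect_error(normalize_gc(c(-1, -2, 0, 0, 0)), "degenerate")
})

test_that("speciation is read off the open-bond graph", {
  p <- island_params(u = 1e-4, m = 0.01, zc = 0.8)
  # A isolated: bonds AB and CA closed, BC open
  s <- speciation_state(c(0.9, 0.1, 0.9), p, bond_graph(), t = 10)
  expect_identical(s$state, "two_species")
  expect_equal(s$graph$tau2, 10)
  expect_equal(unname(s$graph$severed), c(TRUE, FALSE, TRUE))
  # all bonds closed at once: tau2 = tau3
  s <- speciation_state(c(0.9, 0.9, 0.9), p, bond_graph(), t = 5)
  expect_identical(s$state, "three_species")
  expect_equal(s$graph$tau2, 5)
  expect_equal(s$graph$tau3, 5)
  # chain B-C-A keeps one species even with bond AB closed
  s <- speciation_state(c(0.9, 0.1, 0.1), p, bond_graph(), t = 1)
  expect_identical(s$state, "one_species")
  expect_true(is.na(s$graph$tau2))
  # a distance exactly at the threshold leaves the bond open
  s <- speciation_state(c(0.8, 0.8, 0.8), p, bond_graph(), t = 1)
  expect_identical(s$state, "one_species")
})

test_that("bond closure is reversible before a split, latched after", {
  p <- island_params(u = 1e-4, m = 0.01, zc = 0.5)
  g <- speciation_state(c(0.6, 0.1, 0.1), p, bond_graph(), t = 1)$graph
  expect_false(g$open[["AB"]])
  g <- speciation_state(c(0.4, 0.1, 0.1), p, g, t = 2)$graph
  expect_true(g$open[["AB"]])  # reopened: distance dropped back
  # irreversible policy latches the closure
  pi <- island_params(u = 1e-4, m = 0.01, zc = 0.5,
                      irreversible_bonds = TRUE)
  g <- speciation_state(c(0.6, 0.1, 0.1), pi, bond_graph(), t = 1)$graph
  g <- speciation_state(c(0.4, 0.1, 0.1), pi, g, t = 2)$graph
  expect_false(g$open[["AB"]])
  # after a split, severed bonds stay severed whatever the distances do
  g <- speciation_state(c(0.9, 0.1, 0.9), p, bond_graph(), t = 3)$graph
  g2 <- speciation_state(c(0.1, 0.1, 0.1), p, g, t = 4)$graph
  expect_identical(g2$state, "two_species")
  expect_equal(unname(g2$severed), c(TRUE, FALSE, TRUE))
})

test_that("raising the threshold never closes a bond that was open", {
  set.seed(12)
  for (i in 1:25) {
    d <- gc_distances(normalize_gc(stats::runif(5)))
    zcs <- sort(stats::runif(2))
    lo <- speciation_state(d, island_params(u = 1e-4, zc = zcs[1]),
                           bond_graph())
    hi <- speciation_state(d, island_params(u = 1e-4, zc = zcs[2]),
                           bond_graph())
    expect_true(all(hi$graph$open >= lo$graph$open))
  }
})

test_that("parameter validation enforces ranges and warns on large eps", {
  expect_error(island_params(u = -1), "nonnegative")
  expect_error(island_params(u = 1e-4, eps = 1.5), "\\(0, 1\\]")
  expect_error(island_params(u = 1e-4, zc = 2), "\\[0, 1\\]")
  expect_error(island_params(u = 1e-4, l = 2.5), "whole number")
  expect_error(island_params(u = 1e-4, m = -0.1), "nonnegative")
  expect_warning(island_params(u = 1e-4, eps = 0.3), "eps")
  expect_error(island_params(u = 1e-4, m = c(1, 2)), "length 1, 3 or 6")
  m6 <- expand_migration(c(AB = 0.1, BC = 0.2, CA = 0.3))
  expect_equal(unname(m6), c(0.1, 0.1, 0.3, 0.3, 0.2, 0.2))
})
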