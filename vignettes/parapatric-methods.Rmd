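---
title: "Stochastic dynamics of allele sharing and the waiting time to parapatric speciation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic dynamics of allele sharing and the waiting time to parapatric speciation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parapatric)
```

## The model

A sexual haploid species lives on two or three islands, each population
effectively monomorphic: population sizes are assumed small relative to
`1/(u l)` and `1/m`, so fixation after a mutation or a migration event is
effectively instantaneous on the time scale we track. Reproductive
compatibility is controlled by `l` unlinked loci; two individuals cannot
produce viable, fecund offspring when the fraction of these loci at which
they differ exceeds a threshold `z_c`. Three processes move the system:

* **Mutation accumulation.** A novel allele arises and fixes on one island at
  rate `u` per locus per generation, increasing divergence from islands that
  shared the previous allele.
* **Successful migration.** Migrant groups arrive along each directed island
  pair as a Poisson process with rate `m_ab` per generation. After a
  successful event, each locus at which migrants and residents differ fixes
  the migrant allele independently with probability `eps` (the migrant
  fraction `N'/(N+N')` of the merged population). Migration therefore
  homogenizes the pair — and correlates loci, because one event gives many
  loci a simultaneous chance to flip.
* **Speciation.** A migration bond is closed while the pairwise genetic
  distance strictly exceeds `z_c` (no gene flow: hybrids are inviable).
  Speciation is a property of the *graph* of open bonds: two islands whose
  direct bond is closed still belong to one species while a chain of open
  bonds connects them. The first disconnection of the graph defines the
  waiting time `tau2` to two species; `tau3` is reached when all three bonds
  are closed.

### Two islands

For two islands the state is the genetic distance `z` (fraction of differing
loci). Its drift and variance-generating rates are

    M(z) = 2 u (1 - z) - 2 m eps z
    V(z) = 2 u (1 - z) / l  +  2 m [ (eps z)^2 + z eps (1 - eps) / l ]

with three noise sources: Poisson timing of fixations, Poisson timing of
migration events, and binomial sampling of which differing loci fix the
migrant allele. The `1/l` terms vanish as `l -> Inf`. The deterministic
equilibrium is the drift root `z* = u / (u + m eps)`: divergence balances
homogenization. When `z_c > z*`, the deterministic flow never speciates, but
the stochastic path crosses `z_c` in finite time — the size of `V` then
controls the waiting time, which is why the finite-`l` and
fixed-`m*eps` experiments behave the way they do.

### Three islands: geographical configurations

With three islands, the three pairwise distances are not a closed state
space: two different allele-sharing arrangements can give identical distance
triplets yet different fluctuation structure. The package therefore tracks,
per locus, the *geographical configuration* (GC) — the partition of islands
by shared allele: `(ABC)`, `(A)(BC)`, `(B)(CA)`, `(C)(AB)`, `(A)(B)(C)`,
labelled 1–5 — and models the fractions `z1..z5` of loci in each
configuration (summing to one). Distances are linear read-outs:

    zAB = z2 + z3 + z5,  zBC = z3 + z4 + z5,  zCA = z2 + z4 + z5.

The classic two-vector example: `(1/3, 0, 0, 0, 2/3)` and
`(0, 1/3, 1/3, 1/3, 0)` share the distance triplet `(2/3, 2/3, 2/3)`, but a
single A→B migration event cannot move `zBC` at all in the first (the only
enabled transition shuffles mass within the `zBC` sum) while it adds variance
`z eps (1 - eps) / l` in the second. `gc_distances()`, `moment_probe()` and
`three_island_moments()` reproduce this exactly; it is the reason the
five-dimensional state is necessary.

Mutation on island X removes X from its sharing group
(`mutation_transition()`); migration along a directed bond can flip exactly
three configurations (`migration_transition()`), e.g. bond A→B enables
2→4, 3→1 and 5→4, while configurations 1 and 4 (A and B already share) are
fixed points. Each realized flow is subtracted from its source fraction and
added to its target with the *same* realization, so the unit sum is conserved
identically.

Per step, a mutation flow `g(X, i)` is Gaussian with mean `u z_i dt` and
variance `u z_i dt / l`; a migration flow for transition i→j under bond
`ab` has mean `m_ab z_i eps dt` and variance
`m_ab dt [ (z_i eps)^2 + z_i eps (1 - eps)/l ]`, with the `(z_i eps)^2`
timing part driven by one noise term per bond *shared* by that bond's three
transitions. This reproduces the compound-Poisson covariance
`m_ab dt (z_i eps)(z_k eps)` between co-transiting configurations — the
signature of migrants arriving as a group — while the binomial
fixation-sampling part stays independent per transition.

## The jump-process oracle

`jump_simulate()` and `moment_probe()` implement the process the SDE
approximates, exactly: per-locus labels, exponential waiting times,
per-event binomial thinning with probability `eps`. It is the ground truth
used by the tests — single-interval means, variances and covariances of the
five increments from the oracle are compared against the analytic
coefficients (`three_island_moments()`) state by state, and waiting-time
distributions from both simulators are compared by a two-sample test.
`moment_probe()` runs on configuration counts rather than per-locus labels;
loci are exchangeable, so the two representations are distributionally
identical, and counts vectorize to `1e5` replicates comfortably.

## Numerical choices

* **Step size.** `dt = 1` generation by default (all rates are per
  generation and well below one in the regimes of interest); a warning is
  issued when `rate * dt > 0.1`.
* **Boundaries.** Gaussian increments can push fractions outside `[0, 1]`.
  Per step, the flows leaving any configuration are capped at its current
  mass (scaled down proportionally, preserving the shared realizations and
  hence the exact unit sum), then the vector is clipped and renormalized
  (`normalize_gc()`). In one dimension (two islands) the distance is simply
  clipped.
* **Bond policy.** Before any split, a closed bond reopens if its distance
  drops back below `z_c` (closure is a pure function of the current state);
  `irreversible_bonds = TRUE` selects the alternative reading in which any
  closure latches. Either way, once the graph disconnects the severed bonds
  carry `m = 0` forever. A distance exactly equal to `z_c` counts as open
  (strict exceedance). If two bonds close in the same step, both carry the
  same timestamp and `tau2 = tau3` when all three close at once.
* **Seeding.** All drivers accept a master seed; replicate `k` runs on the
  stream `replicate_seed(master, k)`, so any replicate is reproducible in
  isolation.

## Known limitations

The diffusion step is only as good as its Gaussian increments. Near the
all-shared state `z1 = 1` with few loci, flows have standard deviation
`sqrt(u dt / l)` much larger than their mean `u dt`; the boundary caps then
truncate half of each Gaussian and the early divergence is overestimated
(measured: `tau2` roughly 2.4x shorter than the exact jump process at
`l = 10, eps = 0.05`, but consistent within sampling error at
`l = 50, eps = 0.03`). This is intrinsic to Euler–Maruyama with boundary
handling, not a property of the model; the diffusion construction itself
assumes many loci. Analyses that need small-`l` fidelity near the boundary
should use the jump-process backend (`backend = "oracle"` in
`sweep_threshold()`, or `jump_simulate()` directly). Likewise, at a strict
boundary state several increment moments vanish at first order while the
true process leaks mass through two-event chains (order `dt^2`); moment
comparisons against the instantaneous coefficients are therefore run on
states where every configuration has positive mass.

The per-locus oracle takes the free-recombination assumption literally:
fixation outcomes of different loci within one migration event are
independent given the event. Linkage, selection, gradual (non-threshold)
incompatibility and more than three islands are outside the scope of the
model.

## Experiment defaults and problem sizes

The waiting-time drivers default to the standard parameter sets:
`sweep_threshold()` uses `u = 7.5e-5`, `m = 0.01`, `eps = 0.025` across
`l` in {10, 20, 50, 100, Inf} (deterministic equilibrium 0.23, so thresholds
straddling it probe both the deterministic-crossing and
fluctuation-driven regimes); `sweep_epsilon()` fixes `m * eps = 2.5e-4`
with pairs (0.1, 0.0025), (0.005, 0.05), (0.001, 0.25) at `l = 100`;
`ratio_vs_migration_sd()` uses `z_c = 0.3`, `l = 20`, `u = 7.5e-5`,
`eps = 0.01` over combinations of the three symmetric bond rates, reporting
`sigma(m)` as the sample standard deviation (`sd()`) of the three rates —
the population form differs only by the constant `sqrt(2/3)` and cannot
change the sign of the regression slope. The ratio per parameter set is
`mean(tau3)/mean(tau2)` (the per-replicate-ratio mean is also reported);
the regression of ratio on `sigma(m)` is unweighted ordinary least squares
with intercept. Full-scale replication is 200 runs per cell (50 for the
ratio experiment); the package's test suite scales these to 20 replicates
per cell and to threshold grids of three points, which is sufficient for
the monotonicity and sign checks it asserts while keeping a desk-scale run
in minutes.

```{r example, eval = FALSE}
params <- island_params(u = 7.5e-5, m = 0.01, eps = 0.01, l = 20, zc = 0.3)
wt <- three_island_waiting_times(params, reps = 50, t_max = 1e6, seed = 1)
mean(wt$tau3) / mean(wt$tau2)
```
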