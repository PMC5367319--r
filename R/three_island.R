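# Three-island model: SDE for the five GC fractions. Mutation accumulation
# moves mass down the lattice of configurations; migration moves it along the
# transitions of the bond table, with noise shared across the transitions of
# one bond (one Poisson clock of successful migration events per bond).

# Mutation transitions: fixation of a novel allele on island `isl` removes
# that island from any sharing group. Nine (island, source) pairs change the
# configuration; self-maps (e.g. a new allele on A when A is already alone)
# are never drawn because they do not move mass.
.MUT_SRC <- c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L)
.MUT_TGT <- c(2L, 3L, 4L, 5L, 5L, 5L, 5L, 5L, 5L)
.MUT_ISL <- c("A", "B", "C", "B", "C", "A", "C", "A", "B")

# full mutation map, rows = configuration 1..5, cols = island A, B, C
.MUT_MAP <- matrix(c(2L, 3L, 4L,
                     2L, 5L, 5L,
                     5L, 3L, 5L,
                     5L, 5L, 4L,
                     5L, 5L, 5L), nrow = 5L, byrow = TRUE,
                   dimnames = list(NULL, c("A", "B", "C")))

# Migration transition table: per directed bond, the three configurations in
# which the destination island differs from the source, and the configuration
# reached when the migrant allele fixes on the destination. Configurations in
# which source and destination already share the allele are fixed points.
.MIG_SRC18 <- c(2L, 3L, 5L,  2L, 3L, 5L,  2L, 4L, 5L,
                2L, 4L, 5L,  3L, 4L, 5L,  3L, 4L, 5L)
.MIG_TGT18 <- c(4L, 1L, 4L,  1L, 4L, 4L,  3L, 1L, 3L,
                1L, 3L, 3L,  2L, 1L, 2L,  1L, 2L, 2L)
.MIG_BOND18 <- rep(1:6, each = 3L)

# full migration map, rows = configuration, cols = directed bond
.MIG_MAP <- matrix(c(1L, 1L, 1L, 1L, 1L, 1L,
                     4L, 1L, 3L, 1L, 2L, 2L,
                     1L, 4L, 3L, 3L, 2L, 1L,
                     4L, 4L, 1L, 3L, 1L, 2L,
                     4L, 4L, 3L, 3L, 2L, 2L), nrow = 5L, byrow = TRUE,
                   dimnames = list(NULL, .DIRECTED_BONDS))

# combined flow bookkeeping: 9 mutation + 18 migration flows per step
.SRC27 <- c(.MUT_SRC, .MIG_SRC18)
.TGT27 <- c(.MUT_TGT, .MIG_TGT18)
.SRC_IDX <- lapply(1:5, function(k) which(.SRC27 == k))
.TGT_IDX <- lapply(1:5, function(k) which(.TGT27 == k))

#' Configuration reached when a novel allele fixes on one island
#'
#' @param config Configuration label(s) in 1..5.
#' @param island `"A"`, `"B"` or `"C"`.
#' @return Configuration label(s) after fixation. A configuration in which the
#'   island already carries a private allele maps to itself.
#' @examples
#' mutation_transition(1, "A") # (ABC) -> (A)(BC)
#' mutation_transition(2, "B") # (A)(BC) -> (A)(B)(C)
#' @export
mutation_transition <- function(config, island) {
  .check_config(config)
  island <- match.arg(island, c("A", "B", "C"))
  .MUT_MAP[cbind(as.integer(config), match(island, c("A", "B", "C")))]
}

#' Configuration reached when a migrant allele fixes on the destination island
#'
#' @param config Configuration label(s) in 1..5.
#' @param bond Directed bond, one of `"AB"`, `"BA"`, `"AC"`, `"CA"`, `"BC"`,
#'   `"CB"` (source then destination island).
#' @return Configuration after fixation, or `NA` when source and destination
#'   already share the allele (migration cannot change the configuration).
#' @examples
#' migration_transition(2, "AB") # (A)(BC) -> (C)(AB)
#' migration_transition(3, "AB") # (B)(CA) -> (ABC)
#' migration_transition(1, "AB") # NA: nothing to change
#' @export
migration_transition <- function(config, bond) {
  .check_config(config)
  bond <- match.arg(bond, .DIRECTED_BONDS)
  out <- .MIG_MAP[cbind(as.integer(config), match(bond, .DIRECTED_BONDS))]
  out[out == as.integer(config)] <- NA_integer_
  out
}

.check_config <- function(config) {
  if (anyNA(config) || !all(config %in% 1:5))
    stop("configuration labels must be integers in 1..5")
  invisible(config)
}

# ---- increment engines -----------------------------------------------------

# Mutation flows for a 5 x n matrix of GC columns. Returns a 9 x n matrix of
# realized g(alpha, i) values (mean u*z_i*dt, variance u*z_i*dt/l).
.mutation_flows <- function(Z, u, l, dt) {
  n <- ncol(Z)
  G <- u * Z[.MUT_SRC, , drop = FALSE] * dt
  if (is.finite(l) && u > 0)
    G <- G + sqrt(G / l) * matrix(stats::rnorm(9L * n), 9L, n)
  G
}

# Migration flows for a 5 x n matrix. meff18: 18 x n effective directed rates
# (zero across closed bonds). One timing-noise draw per bond per column is
# shared by that bond's three transitions; the binomial fixation-sampling
# noise is independent per transition.
.migration_flows <- function(Z, meff18, eps, l, dt) {
  n <- ncol(Z)
  zsrc <- Z[.MIG_SRC18, , drop = FALSE]
  f <- meff18 * zsrc * eps * dt
  W0 <- matrix(stats::rnorm(6L * n), 6L, n)
  f <- f + zsrc * eps * sqrt(meff18 * dt) * W0[.MIG_BOND18, , drop = FALSE]
  if (is.finite(l))
    f <- f + sqrt(meff18 * zsrc * eps * (1 - eps) * dt / l) *
      matrix(stats::rnorm(18L * n), 18L, n)
  f
}

# Cap flows so no configuration is drained below zero within one step: each
# flow leaves its source (or, when the Gaussian made it negative, its target);
# if the absolute flows leaving a configuration exceed its current mass they
# are scaled down proportionally. The same realization is applied on both
# sides of every flow, so the increments sum to zero exactly.
.assemble_increments <- function(Z, FLOWS, src = .SRC27, tgt = .TGT27) {
  n <- ncol(Z)
  eff_src <- matrix(ifelse(as.vector(FLOWS) >= 0,
                           rep(src, n), rep(tgt, n)),
                    nrow(FLOWS), n)
  absF <- abs(FLOWS)
  scale <- matrix(1, 5L, n)
  for (k in 1:5) {
    out_k <- .colSums(absF * (eff_src == k), nrow(FLOWS), n)
    pos <- out_k > 0
    if (any(pos))
      scale[k, pos] <- pmin(1, Z[k, pos] / out_k[pos])
  }
  idx <- cbind(as.vector(eff_src), rep(seq_len(n), each = nrow(FLOWS)))
  FLOWS <- FLOWS * matrix(scale[idx], nrow(FLOWS), n)
  FLOWS
}

.flows_to_dZ <- function(FLOWS, src_idx, tgt_idx) {
  n <- ncol(FLOWS)
  dZ <- matrix(0, 5L, n)
  for (k in 1:5) {
    si <- src_idx[[k]]; ti <- tgt_idx[[k]]
    if (length(ti))
      dZ[k, ] <- .colSums(FLOWS[ti, , drop = FALSE], length(ti), n)
    if (length(si))
      dZ[k, ] <- dZ[k, ] -
        .colSums(FLOWS[si, , drop = FALSE], length(si), n)
  }
  dZ
}

#' One-step mutation-accumulation increment of the GC fractions
#'
#' Draws the nine Gaussian terms g(island, config) — mean `u*z_i*dt`, variance
#' `u*z_i*dt/l` — and assembles the five increments, subtracting each realized
#' term from its source configuration and adding it to its target, so the
#' increments sum to zero exactly. With `l = Inf` the terms are deterministic.
#'
#' @param gc GC fractions (length-5 vector).
#' @param params An [island_params()] object.
#' @param dt Time step in generations.
#' @return Numeric length-5 increment vector (sums to 0).
#' @export
mutation_increment <- function(gc, params, dt = 1) {
  params <- .check_params(params)
  Z <- matrix(gc_fractions(unclass(gc)), 5L, 1L)
  G <- .mutation_flows(Z, params$u, params$l, dt)
  G <- .assemble_increments(Z, G, .MUT_SRC, .MUT_TGT)
  drop(.flows_to_dZ(G, lapply(1:5, function(k) which(.MUT_SRC == k)),
                    lapply(1:5, function(k) which(.MUT_TGT == k))))
}

#' One-step migration increment of the GC fractions
#'
#' For each open bond and each of its three table transitions i -> j, draws
#' the flow f with mean `m*z_i*eps*dt` and variance
#' `m*dt*((z_i*eps)^2 + z_i*eps*(1-eps)/l)`. The `(z_i*eps)^2` timing part is
#' driven by one noise term per bond, shared across that bond's transitions
#' (covariance `m*dt*z_i*eps*z_k*eps` within a bond); the fixation-sampling
#' part is independent per transition. Outflows are capped at the source's
#' current mass. Closed bonds contribute nothing.
#'
#' @inheritParams mutation_increment
#' @param open Logical length-3 vector (pairs AB, BC, CA): which bonds are
#'   open.
#' @return Numeric length-5 increment vector (sums to 0).
#' @export
migration_increment <- function(gc, params, dt = 1,
                                open = c(AB = TRUE, BC = TRUE, CA = TRUE)) {
  params <- .check_params(params)
  Z <- matrix(gc_fractions(unclass(gc)), 5L, 1L)
  open <- rep_len(as.logical(open), 3L)
  meff18 <- matrix(params$m[.MIG_BOND18] * open[.PAIR_OF_BOND][.MIG_BOND18],
                   18L, 1L)
  f <- .migration_flows(Z, meff18, params$eps, params$l, dt)
  f <- .assemble_increments(Z, f, .MIG_SRC18, .MIG_TGT18)
  drop(.flows_to_dZ(f, lapply(1:5, function(k) which(.MIG_SRC18 == k)),
                    lapply(1:5, function(k) which(.MIG_TGT18 == k))))
}

#' Analytic single-step moments of the three-island SDE
#'
#' Mean vector and covariance matrix of the one-step increment of the five GC
#' fractions implied by the SDE coefficients (the quantities the jump-process
#' oracle must reproduce). Mutation contributes variance `u*z_i*dt/l` along
#' each transition direction; each open bond contributes its compound-Poisson
#' covariance `m*dt * v v'` with `v = sum_i z_i eps (e_tgt - e_src)` plus the
#' independent binomial terms `m*z_i*eps*(1-eps)*dt/l`.
#'
#' @inheritParams migration_increment
#' @return List with `mean` (length 5) and `cov` (5 x 5 matrix).
#' @export
three_island_moments <- function(gc, params, dt = 1,
                                 open = c(AB = TRUE, BC = TRUE, CA = TRUE)) {
  params <- .check_params(params)
  z <- gc_fractions(unclass(gc))
  open <- rep_len(as.logical(open), 3L)
  u <- params$u; eps <- params$eps; l <- params$l
  mu <- numeric(5L)
  S <- matrix(0, 5L, 5L)
  for (k in seq_along(.MUT_SRC)) {
    inc <- numeric(5L)
    inc[.MUT_SRC[k]] <- -1; inc[.MUT_TGT[k]] <- 1
    mu <- mu + u * z[[.MUT_SRC[k]]] * dt * inc
    if (is.finite(l))
      S <- S + (u * z[[.MUT_SRC[k]]] * dt / l) * tcrossprod(inc)
  }
  for (b in 1:6) {
    if (!open[.PAIR_OF_BOND[b]]) next
    mb <- params$m[[b]]
    if (mb <= 0) next
    vshared <- numeric(5L)
    rows <- which(.MIG_BOND18 == b)
    for (k in rows) {
      inc <- numeric(5L)
      inc[.MIG_SRC18[k]] <- -1; inc[.MIG_TGT18[k]] <- 1
      zi <- z[[.MIG_SRC18[k]]]
      mu <- mu + mb * zi * eps * dt * inc
      if (is.finite(l))
        S <- S + mb * zi * eps * (1 - eps) * dt / l * tcrossprod(inc)
      vshared <- vshared + zi * eps * inc
    }
    S <- S + mb * dt * tcrossprod(vshared)
  }
  list(mean = stats::setNames(mu, paste0("z", 1:5)), cov = S)
}

# ---- stepping and trajectories --------------------------------------------

#' One combined Euler-Maruyama step of the three-island model
#'
#' Applies the mutation-accumulation and migration increments, renormalizes
#' the GC vector (clip to \[0,1\], rescale to unit sum) and refreshes the
#' speciation state of the bond graph.
#'
#' @param state List with elements `t` (time), `gc` (GC fractions) and
#'   `graph` (a [bond_graph()]), as returned by this function.
#' @param params An [island_params()] object.
#' @param dt Time step in generations.
#' @return Updated state list, with `state$state` the current species count
#'   label.
#' @export
step_three_island <- function(state, params, dt = 1) {
  params <- .check_params(params)
  .check_dt(dt, max(params$u, params$m))
  Z <- matrix(gc_fractions(unclass(state$gc)), 5L, 1L)
  graph <- if (is.null(state$graph)) bond_graph() else state$graph
  open <- graph$open
  dz <- mutation_increment(drop(Z), params, dt) +
    migration_increment(drop(Z), params, dt, open = open)
  gc <- normalize_gc(drop(Z) + dz)
  t_new <- state$t + dt
  sp <- speciation_state(gc_distances(gc), params, graph, t = t_new)
  list(t = t_new, gc = gc, graph = sp$graph, state = sp$state)
}

# Vectorized engine: reps independent replicates stepped as the columns of a
# 5 x n matrix. Bond status is tracked per replicate; when the open-bond graph
# first disconnects, the closed bonds are severed for good (migration zero).
# Assumes the RNG has been seeded by the caller.
.three_island_engine <- function(params, gc0, dt, t_max, reps,
                                 record_stride = NULL) {
  u <- params$u; eps <- params$eps; l <- params$l; zc <- params$zc
  irr <- params$irreversible_bonds
  m18base <- params$m[.MIG_BOND18]
  Z <- matrix(gc_fractions(unclass(gc0)), 5L, reps)
  SEVER <- matrix(FALSE, 3L, reps)
  LATCH <- matrix(FALSE, 3L, reps)
  OPEN <- matrix(TRUE, 3L, reps)
  SPLIT <- rep(FALSE, reps)
  tau2 <- rep(NA_real_, reps)
  tau3 <- rep(NA_real_, reps)
  closed_at <- matrix(NA_real_, 3L, reps)

  dist3 <- function(Z)
    rbind(Z[2L, ] + Z[3L, ] + Z[5L, ],
          Z[3L, ] + Z[4L, ] + Z[5L, ],
          Z[2L, ] + Z[4L, ] + Z[5L, ])

  # speciation bookkeeping on the active columns at time t
  refresh <- function(idx, t) {
    D <- dist3(Z[, idx, drop = FALSE])
    over <- D > zc
    if (irr) LATCH[, idx] <<- LATCH[, idx, drop = FALSE] | over
    closed <- SEVER[, idx, drop = FALSE] | over | LATCH[, idx, drop = FALSE]
    n_open <- 3L - .colSums(closed, 3L, length(idx))
    new2 <- !SPLIT[idx] & n_open <= 1L
    if (any(new2)) {
      j <- idx[new2]
      SPLIT[j] <<- TRUE
      tau2[j] <<- t
      newly <- closed[, new2, drop = FALSE] & !SEVER[, j, drop = FALSE]
      ca <- closed_at[, j, drop = FALSE]; ca[newly] <- t
      closed_at[, j] <<- ca
      SEVER[, j] <<- closed[, new2, drop = FALSE]
    }
    new3 <- n_open == 0L & is.na(tau3[idx])
    if (any(new3)) {
      j <- idx[new3]
      tau3[j] <<- t
      ca <- closed_at[, j, drop = FALSE]; ca[is.na(ca)] <- t
      closed_at[, j] <<- ca
      SEVER[, j] <<- TRUE
    }
    OPEN[, idx] <<- !closed
    idx[is.na(tau3[idx])]
  }

  record <- !is.null(record_stride)
  rec <- NULL
  if (record) {
    nrec <- floor(t_max / (dt * record_stride)) + 2L
    rec <- matrix(NA_real_, nrec, 10L)
    colnames(rec) <- c("t", paste0("z", 1:5), "zAB", "zBC", "zCA",
                       "bonds_open")
    irec <- 0L
    snap <- function(t) {
      irec <<- irec + 1L
      rec[irec, ] <<- c(t, Z[, 1L], dist3(Z[, 1L, drop = FALSE]),
                        sum(OPEN[, 1L]))
    }
  }

  t <- 0
  active <- refresh(seq_len(reps), t)
  if (record) snap(t)
  step_i <- 0L
  while (length(active) > 0L && t < t_max - 1e-9) {
    Za <- Z[, active, drop = FALSE]
    n <- length(active)
    G <- .mutation_flows(Za, u, l, dt)
    meff18 <- m18base *
      (OPEN[, active, drop = FALSE])[.PAIR_OF_BOND, ,
                                     drop = FALSE][.MIG_BOND18, ,
                                                   drop = FALSE]
    f <- .migration_flows(Za, meff18, eps, l, dt)
    FLOWS <- .assemble_increments(Za, rbind(G, f))
    Zn <- Za + .flows_to_dZ(FLOWS, .SRC_IDX, .TGT_IDX)
    Zn[Zn < 0] <- 0
    Zn[Zn > 1] <- 1
    s <- .colSums(Zn, 5L, n)
    if (any(s <= 0)) stop("degenerate GC state during simulation")
    Z[, active] <- Zn / rep(s, each = 5L)
    t <- t + dt
    step_i <- step_i + 1L
    active <- refresh(active, t)
    if (record && step_i %% record_stride == 0L) snap(t)
  }
  if (record) rec <- rec[seq_len(irec), , drop = FALSE]
  list(tau2 = tau2, tau3 = tau3, closed_at = closed_at,
       Z = Z, record = rec, t_end = t)
}

#' Simulate a three-island GC trajectory
#'
#' Integrates the five-dimensional GC SDE from `gc0`, tracking pairwise
#' distances and the speciation state of the bond graph. The first time the
#' open-bond graph disconnects defines `tau2`; the first time all three bonds
#' are closed defines `tau3`; migration across severed bonds is zero from the
#' split onward.
#'
#' @param params An [island_params()] object.
#' @param gc0 Initial GC fractions (default: all loci shared, `z1 = 1`).
#' @param dt Step size in generations.
#' @param t_max Final time (the run is censored there if `tau3` has not
#'   occurred).
#' @param record_stride Record every `record_stride`-th step.
#' @param seed Optional integer seed.
#' @return A data frame of class `island_trajectory` with columns `t`,
#'   `z1..z5`, `zAB`, `zBC`, `zCA`, `bonds_open` (number of open bonds);
#'   attribute `record` is the speciation record (list with `tau2`, `tau3`,
#'   `closed_at`).
#' @export
simulate_three_island <- function(params, gc0 = c(1, 0, 0, 0, 0), dt = 1,
                                  t_max = 1e4, record_stride = 1L,
                                  seed = NULL) {
  params <- .check_params(params)
  .check_dt(dt, max(params$u, params$m))
  if (!is.null(seed)) set.seed(seed)
  out <- .three_island_engine(params, gc0, dt, t_max, reps = 1L,
                              record_stride = record_stride)
  traj <- as.data.frame(out$record)
  structure(traj, class = c("island_trajectory", "data.frame"),
            model = "three_island", params = params, seed = seed,
            record = list(tau2 = out$tau2[1L], tau3 = out$tau3[1L],
                          closed_at = stats::setNames(out$closed_at[, 1L],
                                                      .PAIRS)))
}

#' Replicate waiting times to two and three species
#'
#' Runs `reps` independent three-island SDE trajectories and records, per
#' replicate, the waiting time `tau2` until the island set first splits into
#' two species (open-bond graph disconnects) and `tau3` until all three bonds
#' are closed. Replicates that do not reach the event by `t_max` are censored
#' (`NA`).
#'
#' @inheritParams simulate_three_island
#' @param reps Number of replicates.
#' @return Data frame with columns `tau2`, `tau3`, `censored2`, `censored3`.
#' @export
three_island_waiting_times <- function(params, gc0 = c(1, 0, 0, 0, 0),
                                       dt = 1, t_max = 1e6, reps = 50L,
                                       seed = NULL) {
  params <- .check_params(params)
  if (reps < 1L) stop("'reps' must be >= 1")
  .check_dt(dt, max(params$u, params$m))
  if (!is.null(seed)) set.seed(seed)
  out <- .three_island_engine(params, gc0, dt, t_max, reps = reps)
  data.frame(tau2 = out$tau2, tau3 = out$tau3,
             censored2 = is.na(out$tau2), censored3 = is.na(out$tau3))
}

#' @export
print.island_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d records, t in [%g, %g]\n",
              attr(x, "model"), nrow(x), x$t[1L], x$t[nrow(x)]))
  rec <- attr(x, "record")
  if (!is.null(rec))
    cat(sprintf("  tau2 = %s, tau3 = %s\n",
                format(rec$tau2), format(rec$tau3)))
  tau <- attr(x, "tau")
  if (!is.null(tau) && !is.na(tau)) cat(sprintf("  tau = %g\n", tau))
  utils::str(as.data.frame(utils::head(x, 3L)))
  invisible(x)
}

#' @export
plot.island_trajectory <- function(x, ...) {
  if (identical(attr(x, "model"), "two_island")) {
    graphics::plot(x$t, x$z, type = "l", xlab = "generations",
                   ylab = "genetic distance z", ...)
  } else {
    graphics::matplot(x$t, as.matrix(x[, c("zAB", "zBC", "zCA")]),
                      type = "l", lty = 1, xlab = "generations",
                      ylab = "pairwise distance", ...)
    graphics::legend("topleft", legend = c("zAB", "zBC", "zCA"),
                     col = 1:3, lty = 1, bty = "n")
  }
  invisible(x)
}
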