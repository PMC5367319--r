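# Exact per-locus continuous-time jump process (Gillespie-style). This is the
# ground truth the diffusion approximation must reproduce: mutation-fixation
# events arrive at rate u per locus per island; successful migration events
# arrive per directed bond as a Poisson process, and each locus at which the
# destination differs from the source fixes the migrant allele independently
# with probability eps.

#' Per-locus state vector
#'
#' @param l Number of loci (finite).
#' @param n_islands 2 or 3.
#' @param init Initial configuration label for every locus: for three islands
#'   a label in 1..5; for two islands 1 (same allele) or 2 (different).
#'   Alternatively a full length-`l` vector of labels.
#' @return Integer vector of class `locus_state` with attribute `n_islands`.
#' @export
locus_state <- function(l, n_islands = 3L, init = 1L) {
  if (!is.finite(l) || l < 1L) stop("the oracle needs a finite l >= 1")
  n_islands <- as.integer(n_islands)
  if (!n_islands %in% c(2L, 3L)) stop("'n_islands' must be 2 or 3")
  labels <- if (length(init) == l) as.integer(init)
            else rep(as.integer(init), l)
  maxlab <- if (n_islands == 3L) 5L else 2L
  if (anyNA(labels) || any(labels < 1L) || any(labels > maxlab))
    stop("invalid configuration labels")
  structure(labels, n_islands = n_islands, class = "locus_state")
}

#' Event rates of the jump process
#'
#' Mutation-fixation events occur at rate `u` per locus per island (total
#' `n_islands * u * l`, irrespective of configuration: replacements that do
#' not change the configuration still happen, they just have no effect).
#' Each open directed bond carries migration events at its rate; closed bonds
#' are excluded.
#'
#' @param state A [locus_state()].
#' @param params An [island_params()] object.
#' @param open Logical vector over pairs (AB, BC, CA for three islands; a
#'   single value for two): which bonds are open.
#' @return List with `mutation` (named per-island rates) and `migration`
#'   (named per directed bond), plus `total`.
#' @export
event_rates <- function(state, params,
                        open = c(AB = TRUE, BC = TRUE, CA = TRUE)) {
  params <- .check_params(params)
  l <- length(state)
  if (attr(state, "n_islands") == 3L) {
    open <- rep_len(as.logical(open), 3L)
    mut <- stats::setNames(rep(params$u * l, 3L), c("A", "B", "C"))
    mig <- params$m * open[.PAIR_OF_BOND]
  } else {
    open <- rep_len(as.logical(open), 1L)
    mut <- stats::setNames(rep(params$u * l, 2L), c("A", "B"))
    mig <- params$m[c("AB", "BA")] * open
  }
  list(mutation = mut, migration = mig, total = sum(mut) + sum(mig))
}

#' Apply one mutation-fixation event to a locus
#'
#' @param state A [locus_state()].
#' @param island `"A"`, `"B"` or `"C"` (for two islands, `"A"` or `"B"`).
#' @param locus Locus index.
#' @return Updated state.
#' @export
apply_mutation <- function(state, island, locus) {
  n_isl <- attr(state, "n_islands")
  if (locus < 1L || locus > length(state)) stop("invalid locus index")
  if (n_isl == 3L) {
    state[locus] <- mutation_transition(state[locus], island)
  } else {
    island <- match.arg(island, c("A", "B"))
    state[locus] <- 2L  # a novel allele always makes the islands differ
  }
  state
}

#' Apply one successful migration event to all loci
#'
#' Every locus whose configuration has a transition under the bond (i.e. at
#' which source and destination islands differ) fixes the migrant allele
#' independently with probability `eps`; other loci are untouched. This is the
#' mechanism that makes transitions of different loci correlated: one event,
#' many loci.
#'
#' @param state A [locus_state()].
#' @param bond Directed bond name (`"AB"` etc.; `"AB"`/`"BA"` for two
#'   islands).
#' @param eps Per-locus fixation probability of the migrant allele.
#' @return Updated state.
#' @export
apply_migration <- function(state, bond, eps) {
  if (eps < 0 || eps > 1) stop("'eps' must be in [0, 1]")
  n_isl <- attr(state, "n_islands")
  if (n_isl == 3L) {
    bond <- match.arg(bond, .DIRECTED_BONDS)
    map <- .MIG_MAP[, bond]
    movable <- which(map[state] != state)
  } else {
    movable <- which(unclass(state) == 2L)
    map <- c(1L, 1L)
  }
  if (length(movable)) {
    flip <- movable[stats::runif(length(movable)) < eps]
    state[flip] <- map[state[flip]]
  }
  state
}

# counts (per configuration) from a per-locus state
.state_counts <- function(state) {
  if (attr(state, "n_islands") == 3L) tabulate(unclass(state), 5L)
  else tabulate(unclass(state), 2L)
}

#' Exact event-driven simulation of the island jump process
#'
#' Gillespie simulation with exponential waiting times between events and
#' event classes sampled proportionally to their rates. Tracks GC fractions
#' (counts / l), pairwise distances, and the same speciation policy as the
#' SDE: bonds close while the distance exceeds `zc`; the first graph
#' disconnection fixes `tau2` and permanently severs the closed bonds; `tau3`
#' is set when all bonds are closed.
#'
#' @param params An [island_params()] object (finite `l` required).
#' @param state0 Optional initial [locus_state()]; defaults to all loci in
#'   configuration 1 (all islands share every allele).
#' @param t_max Time horizon in generations.
#' @param record_stride Record the state on a regular grid with this spacing
#'   (in generations).
#' @param seed Optional integer seed.
#' @param n_islands 2 or 3 (ignored when `state0` is given).
#' @param event_log If `TRUE`, also return a per-event log with columns `t`,
#'   `event`, `n_changed`.
#' @param stop_at_speciation Stop as soon as `tau3` (three islands) or the
#'   threshold crossing (two islands) occurs.
#' @return A data frame of class `island_trajectory` (same schema as
#'   [simulate_three_island()], or columns `t`, `z` for two islands), with
#'   attributes `record` (tau2/tau3/closure times) and optionally
#'   `event_log`.
#' @export
jump_simulate <- function(params, state0 = NULL, t_max = 1e4,
                          record_stride = 1, seed = NULL, n_islands = 3L,
                          event_log = FALSE, stop_at_speciation = FALSE) {
  params <- .check_params(params)
  if (!is.finite(params$l)) stop("the jump oracle needs a finite l")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state0)) state0 <- locus_state(params$l, n_islands)
  n_isl <- attr(state0, "n_islands")
  l <- length(state0)
  u <- params$u; eps <- params$eps; zc <- params$zc
  state <- state0
  graph <- bond_graph()
  t <- 0
  grid <- seq(0, t_max, by = record_stride)
  nrec <- length(grid)
  ncol_rec <- if (n_isl == 3L) 10L else 2L
  rec <- matrix(NA_real_, nrec, ncol_rec)
  irec <- 0L
  elog <- if (event_log) list() else NULL

  snapshot <- function() {
    cnt <- .state_counts(state) / l
    if (n_isl == 3L) c(cnt, gc_distances(cnt), sum(graph$open))
    else cnt[2L]
  }
  refresh_graph <- function() {
    if (n_isl == 3L) {
      sp <- speciation_state(gc_distances(.state_counts(state) / l),
                             params, graph, t = t)
      graph <<- sp$graph
    } else {
      z <- .state_counts(state)[2L] / l
      if (z > zc && is.na(graph$tau2)) {
        graph$tau2 <<- t
        graph$open[] <<- FALSE
        graph$severed[] <<- TRUE
        graph$state <<- "two_species"
      }
    }
  }
  refresh_graph()

  mut_islands <- if (n_isl == 3L) c("A", "B", "C") else c("A", "B")
  repeat {
    rates_mut <- rep(u * l, length(mut_islands))
    if (n_isl == 3L) {
      open_pairs <- graph$open | FALSE
      rates_mig <- params$m * open_pairs[.PAIR_OF_BOND]
      mig_names <- .DIRECTED_BONDS
    } else {
      rates_mig <- params$m[c("AB", "BA")] * all(graph$open)
      mig_names <- c("AB", "BA")
    }
    rates <- c(rates_mut, rates_mig)
    total <- sum(rates)
    t_next <- if (total > 0) t + stats::rexp(1L, total) else Inf
    # fill the record grid up to the next event (state is constant between
    # events)
    while (irec < nrec && grid[irec + 1L] <= min(t_next, t_max) + 1e-12) {
      irec <- irec + 1L
      rec[irec, ] <- c(grid[irec], snapshot())
    }
    done <- if (n_isl == 3L) !is.na(graph$tau3) else !is.na(graph$tau2)
    if (t_next > t_max || (stop_at_speciation && done)) {
      t <- min(t_next, t_max)
      break
    }
    t <- t_next
    k <- sample.int(length(rates), 1L, prob = rates)
    before <- unclass(state)
    if (k <= length(mut_islands)) {
      state <- apply_mutation(state, mut_islands[k], sample.int(l, 1L))
      what <- paste0("mut_", mut_islands[k])
    } else {
      b <- mig_names[k - length(mut_islands)]
      state <- apply_migration(state, b, eps)
      what <- paste0("mig_", b)
    }
    if (event_log)
      elog[[length(elog) + 1L]] <-
        data.frame(t = t, event = what,
                   n_changed = sum(unclass(state) != before))
    refresh_graph()
  }
  rec <- rec[seq_len(irec), , drop = FALSE]
  if (n_isl == 3L) {
    colnames(rec) <- c("t", paste0("z", 1:5), "zAB", "zBC", "zCA",
                       "bonds_open")
    traj <- as.data.frame(rec)
    record <- list(tau2 = graph$tau2, tau3 = graph$tau3,
                   closed_at = graph$closed_at)
  } else {
    colnames(rec) <- c("t", "z")
    traj <- as.data.frame(rec)
    record <- list(tau2 = graph$tau2, tau3 = NA_real_,
                   closed_at = NULL)
  }
  out <- structure(traj, class = c("island_trajectory", "data.frame"),
                   model = if (n_isl == 3L) "three_island_oracle"
                           else "two_island_oracle",
                   params = params, seed = seed, record = record)
  if (event_log)
    attr(out, "event_log") <- do.call(rbind, elog)
  out
}

#' Empirical single-interval moments of the jump process
#'
#' Replicates the exact jump process over one interval of length `dt` from a
#' fixed initial state and returns the empirical first and second moments of
#' the five GC-fraction increments, for direct comparison with the SDE
#' coefficients (see [three_island_moments()]). Loci are exchangeable, so the
#' process is simulated on configuration counts; this is distributionally
#' identical to the per-locus simulation.
#'
#' @param gc0 Initial GC fractions; `l * gc0` must be whole numbers.
#' @param params An [island_params()] object with finite `l`.
#' @param dt Interval length in generations.
#' @param reps Number of replicate intervals.
#' @param seed Optional integer seed.
#' @param open Logical length-3: bonds carrying migration.
#' @return List with `draws` (`reps` x 5 matrix of increments), `mean`,
#'   `cov`, and `n`.
#' @export
moment_probe <- function(gc0, params, dt = 1, reps = 1e4, seed = NULL,
                         open = c(AB = TRUE, BC = TRUE, CA = TRUE)) {
  params <- .check_params(params)
  l <- params$l
  if (!is.finite(l)) stop("the jump oracle needs a finite l")
  gc0 <- gc_fractions(unclass(gc0))
  counts0 <- unclass(gc0) * l
  if (any(abs(counts0 - round(counts0)) > 1e-9))
    stop("l * gc0 must be whole numbers (integer locus counts)")
  counts0 <- round(counts0)
  if (!is.null(seed)) set.seed(seed)
  open <- rep_len(as.logical(open), 3L)
  u <- params$u; eps <- params$eps
  rates <- c(rep(u * l, 3L), params$m * open[.PAIR_OF_BOND])
  total <- sum(rates)
  draws <- matrix(0, reps, 5L)
  n_ev <- stats::rpois(reps, total * dt)
  busy <- which(n_ev > 0L)
  for (r in busy) {
    counts <- counts0
    types <- sample.int(9L, n_ev[r], replace = TRUE, prob = rates)
    for (k in types) {
      if (k <= 3L) {
        cfg <- sample.int(5L, 1L, prob = counts)
        new <- .MUT_MAP[cfg, k]
        counts[cfg] <- counts[cfg] - 1L
        counts[new] <- counts[new] + 1L
      } else {
        b <- k - 3L
        rows <- which(.MIG_BOND18 == b)
        src <- .MIG_SRC18[rows]; tgt <- .MIG_TGT18[rows]
        moved <- stats::rbinom(3L, counts[src], eps)
        counts[src] <- counts[src] - moved
        for (j in 1:3) counts[tgt[j]] <- counts[tgt[j]] + moved[j]
      }
    }
    draws[r, ] <- (counts - counts0) / l
  }
  colnames(draws) <- paste0("z", 1:5)
  list(draws = draws, mean = colMeans(draws), cov = stats::cov(draws),
       n = reps)
}
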