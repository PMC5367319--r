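# Two-island model: genetic distance z between two island populations,
# driven by mutation-fixation (divergence) and rare migration (homogenization).

#' Drift of the two-island genetic distance
#'
#' Mean rate of change of z per generation. Allelic replacement on either
#' island raises z by 1/l at rate u*l*(1-z) (only loci where the islands still
#' agree can diverge); successful migration in either direction lowers z by
#' eps*z on average at rate m. With both directed rates equal to m the drift is
#' `2*u*(1-z) - 2*m*eps*z`.
#'
#' @param z Genetic distance(s) in \[0, 1\]; vectorized.
#' @param params An [island_params()] object; the `AB` and `BA` migration
#'   entries are used.
#' @return Drift (rate per generation), same length as `z`.
#' @export
two_island_drift <- function(z, params) {
  params <- .check_params(params)
  mr <- params$m[["AB"]] + params$m[["BA"]]
  2 * params$u * (1 - z) - mr * params$eps * z
}

#' Diffusion (variance-generating rate) of the two-island genetic distance
#'
#' Three additive noise sources per generation: Poisson timing of mutation
#' fixations (`2*u*(1-z)/l`), Poisson timing of migration events
#' (`2*m*(eps*z)^2`), and binomial sampling of which differing loci fix the
#' migrant allele (`2*m*z*eps*(1-eps)/l`). The per-locus (1/l) terms vanish for
#' `l = Inf`.
#'
#' @inheritParams two_island_drift
#' @return Variance rate per generation, same length as `z`.
#' @export
two_island_diffusion <- function(z, params) {
  params <- .check_params(params)
  mr <- params$m[["AB"]] + params$m[["BA"]]
  eps <- params$eps
  v <- mr * (eps * z)^2
  if (is.finite(params$l))
    v <- v + 2 * params$u * (1 - z) / params$l +
      mr * z * eps * (1 - eps) / params$l
  v
}

#' Deterministic equilibrium of the two-island distance
#'
#' Root of the drift: divergence `2u(1-z)` balances homogenization
#' `2*m*eps*z`, giving `z* = u/(u + m*eps)`. With `m = 0` the distance
#' diverges to 1.
#'
#' @param params An [island_params()] object.
#' @return Equilibrium distance in \[0, 1\].
#' @export
two_island_equilibrium <- function(params) {
  params <- .check_params(params)
  me <- (params$m[["AB"]] + params$m[["BA"]]) / 2 * params$eps
  if (params$u + me <= 0)
    stop("equilibrium undefined: u + m*eps must be positive")
  params$u / (params$u + me)
}

#' One Euler-Maruyama step of the two-island SDE
#'
#' `z' = z + M(z) dt + sqrt(V(z) dt) * xi` with `xi` standard normal, clipped
#' to \[0, 1\]. Vectorized over `z` (one independent increment per element).
#'
#' @param z Current distance(s).
#' @param params An [island_params()] object.
#' @param dt Time step in generations; `u*dt` and `m*dt` should be well below
#'   one (a warning is issued above 0.1).
#' @param deterministic If `TRUE`, suppress the noise term (pure drift).
#' @return Updated distance(s).
#' @export
two_island_step <- function(z, params, dt = 1, deterministic = FALSE) {
  params <- .check_params(params)
  .check_dt(dt, max(params$u, params$m[["AB"]], params$m[["BA"]]))
  zn <- z + two_island_drift(z, params) * dt
  if (!deterministic) {
    v <- two_island_diffusion(z, params)
    zn <- zn + sqrt(pmax(v, 0) * dt) * stats::rnorm(length(z))
  }
  pmin(pmax(zn, 0), 1)
}

# rate scale used for dt warnings; l = Inf contributes u per locus but the
# aggregate replacement rate is what must stay << 1/dt, so cap at u itself
.check_dt <- function(dt, rate) {
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  if (rate * dt > 0.1)
    warning("rate * dt = ", format(rate * dt),
            " > 0.1: the Euler-Maruyama step may be too coarse")
  invisible(dt)
}

# vectorized core used by simulate_two_island and first_passage_two_island;
# assumes the RNG has been seeded by the caller
.two_island_engine <- function(params, z0, dt, t_max, reps,
                               deterministic = FALSE,
                               record_stride = NULL,
                               stop_at_zc = TRUE) {
  u <- params$u; eps <- params$eps; l <- params$l; zc <- params$zc
  mr <- params$m[["AB"]] + params$m[["BA"]]
  z <- rep(as.numeric(z0), length.out = reps)
  tau <- rep(NA_real_, reps)
  crossed <- z > zc
  tau[crossed] <- 0
  t <- 0
  rec <- NULL
  if (!is.null(record_stride)) {
    nrec <- floor(t_max / (dt * record_stride)) + 1L
    rec <- matrix(NA_real_, nrec, 1L + reps)
    rec[1L, ] <- c(0, z)
    irec <- 1L
  }
  step_i <- 0L
  active <- which(!crossed | !stop_at_zc)
  while (length(active) > 0L && t < t_max - 1e-9) {
    za <- z[active]
    # migration ceases across a closed bond: once crossed, m drops to zero
    ma <- ifelse(crossed[active], 0, mr)
    drift <- 2 * u * (1 - za) - ma * eps * za
    zn <- za + drift * dt
    if (!deterministic) {
      v <- ma * (eps * za)^2
      if (is.finite(l))
        v <- v + 2 * u * (1 - za) / l + ma * za * eps * (1 - eps) / l
      zn <- zn + sqrt(pmax(v, 0) * dt) * stats::rnorm(length(za))
    }
    z[active] <- pmin(pmax(zn, 0), 1)
    t <- t + dt
    step_i <- step_i + 1L
    newly <- active[!crossed[active] & z[active] > zc]
    if (length(newly)) {
      crossed[newly] <- TRUE
      tau[newly] <- t
    }
    if (!is.null(rec) && step_i %% record_stride == 0L) {
      irec <- irec + 1L
      rec[irec, ] <- c(t, z)
    }
    if (stop_at_zc) active <- which(!crossed)
  }
  if (!is.null(rec)) rec <- rec[seq_len(irec), , drop = FALSE]
  list(z = z, tau = tau, censored = is.na(tau), record = rec, t_end = t)
}

#' Simulate a two-island genetic-distance trajectory
#'
#' Euler-Maruyama integration of the distance SDE. If the distance crosses
#' `zc` the bond closes and migration is zero from then on (in the two-island
#' model a split is always permanent).
#'
#' @param params An [island_params()] object.
#' @param z0 Initial distance.
#' @param dt Step size in generations.
#' @param t_max Final time.
#' @param record_stride Record every `record_stride`-th step.
#' @param seed Optional integer seed.
#' @param deterministic If `TRUE`, integrate the drift only.
#' @return A data frame of class `island_trajectory` with columns `t`, `z`;
#'   attribute `tau` holds the bond-closure (speciation) time or `NA`.
#' @export
simulate_two_island <- function(params, z0 = 0, dt = 1, t_max = 1e4,
                                record_stride = 1L, seed = NULL,
                                deterministic = FALSE) {
  params <- .check_params(params)
  if (!is.null(seed)) set.seed(seed)
  out <- .two_island_engine(params, z0, dt, t_max, reps = 1L,
                            deterministic = deterministic,
                            record_stride = record_stride,
                            stop_at_zc = FALSE)
  traj <- data.frame(t = out$record[, 1L], z = out$record[, 2L])
  structure(traj, class = c("island_trajectory", "data.frame"),
            model = "two_island", params = params, seed = seed,
            tau = out$tau[1L])
}

#' Waiting time for the two-island distance to exceed the threshold
#'
#' Runs `reps` independent trajectories from `z0` and records, for each, the
#' first time the distance strictly exceeds `zc`. Replicates that do not cross
#' by `t_max` are censored.
#'
#' @inheritParams simulate_two_island
#' @param reps Number of replicates (>= 1).
#' @return An object of class `waiting_times`: list with `tau` (per-replicate
#'   times, `NA` when censored), `censored`, and the call parameters.
#' @export
first_passage_two_island <- function(params, z0 = 0, dt = 1, t_max = 1e7,
                                     reps = 100L, seed = NULL,
                                     deterministic = FALSE) {
  params <- .check_params(params)
  if (reps < 1L) stop("'reps' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- .two_island_engine(params, z0, dt, t_max, reps = reps,
                            deterministic = deterministic,
                            stop_at_zc = TRUE)
  structure(list(tau = out$tau, censored = out$censored,
                 zc = params$zc, params = params, t_max = t_max),
            class = "waiting_times")
}

#' @export
print.waiting_times <- function(x, ...) {
  s <- summarize_waiting_times(x$tau)
  cat(sprintf(
    "Waiting times to z > %g: n = %d, censored = %d\n", x$zc,
    length(x$tau), sum(x$censored)))
  if (s$n > 0)
    cat(sprintf("  mean = %g generations (SE %g)\n", s$mean, s$se))
  invisible(x)
}
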