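# Batch drivers for the waiting-time experiments: threshold sweeps, sweeps in
# (m, eps) at fixed migration rate m*eps, and the tau3/tau2 ratio against the
# heterogeneity of the three bond migration rates.

#' Summary statistics of a waiting-time sample
#'
#' Arithmetic mean and standard error over the uncensored replicates;
#' censored replicates (NA) are counted separately, never averaged in.
#'
#' @param tau Numeric vector of waiting times, `NA` for censored replicates.
#' @return List with `mean`, `se`, `n` (uncensored count), `censored`.
#' @examples
#' summarize_waiting_times(c(2, 4))  # mean 3, SE 1
#' @export
summarize_waiting_times <- function(tau) {
  if (length(tau) == 0L) stop("empty waiting-time sample")
  ok <- tau[!is.na(tau)]
  n <- length(ok)
  list(mean = if (n > 0) mean(ok) else NA_real_,
       se = if (n > 1) stats::sd(ok) / sqrt(n) else if (n == 1) 0 else
         NA_real_,
       n = n, censored = sum(is.na(tau)))
}

# run one waiting-time cell with a replicate-indexed seed stream
.wt_cell <- function(params, reps, dt, t_max, seed, cell_index,
                     backend = c("sde", "oracle"), gc0 = c(1, 0, 0, 0, 0)) {
  backend <- match.arg(backend)
  cell_seed <- if (is.null(seed)) NULL else replicate_seed(seed, cell_index)
  if (backend == "sde")
    return(three_island_waiting_times(params, gc0 = gc0, dt = dt,
                                      t_max = t_max, reps = reps,
                                      seed = cell_seed))
  # oracle backend: one Gillespie run per replicate
  tau2 <- tau3 <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    s <- if (is.null(cell_seed)) NULL else replicate_seed(cell_seed, r)
    run <- jump_simulate(params, t_max = t_max, record_stride = t_max,
                         seed = s, stop_at_speciation = TRUE)
    rec <- attr(run, "record")
    tau2[r] <- rec$tau2
    tau3[r] <- rec$tau3
  }
  data.frame(tau2 = tau2, tau3 = tau3,
             censored2 = is.na(tau2), censored3 = is.na(tau3))
}

#' Mean waiting time to speciation across thresholds and locus numbers
#'
#' For each combination of speciation threshold `zc` and locus number `l`,
#' runs `reps` replicate three-island simulations and summarizes the waiting
#' time `tau2` to the first split. Defaults reproduce the standard threshold
#' sweep: `u = 7.5e-5`, `m = 0.01` on every bond, `eps = 0.025`.
#'
#' @param zc_values Thresholds to sweep.
#' @param l_values Locus numbers (may include `Inf`).
#' @param params Base parameter set; `zc` and `l` are overridden per cell.
#' @param reps Replicates per cell (>= 2).
#' @param dt,t_max Numerical controls of each run.
#' @param seed Master seed; each cell derives an independent stream.
#' @param backend `"sde"` (default) or `"oracle"` (exact jump process;
#'   finite `l` only).
#' @return Data frame with one row per (zc, l) cell: mean, SE, uncensored
#'   count and censored count of `tau2`.
#' @export
sweep_threshold <- function(zc_values,
                            l_values = c(10, 20, 50, 100, Inf),
                            params = island_params(u = 7.5e-5, m = 0.01,
                                                   eps = 0.025),
                            reps = 200L, dt = 1, t_max = 5e5, seed = NULL,
                            backend = c("sde", "oracle")) {
  backend <- match.arg(backend)
  if (reps < 2L) stop("'reps' must be >= 2")
  grid <- expand.grid(zc = zc_values, l = l_values)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- island_params(u = params$u, m = params$m, eps = params$eps,
                       l = grid$l[i], zc = grid$zc[i],
                       irreversible_bonds = params$irreversible_bonds)
    wt <- .wt_cell(p, reps, dt, t_max, seed, i, backend)
    s <- summarize_waiting_times(wt$tau2)
    out[[i]] <- data.frame(zc = grid$zc[i], l = grid$l[i],
                           mean_tau2 = s$mean, se_tau2 = s$se,
                           n = s$n, censored = s$censored)
  }
  do.call(rbind, out)
}

#' Waiting times across (m, eps) pairs at fixed migration rate m*eps
#'
#' The deterministic dynamics depend on migration only through the product
#' `m*eps` (the average number of migrants per generation), but the
#' variance-generating rate grows with `eps` at fixed product, so fewer,
#' larger migration events shorten the waiting time to speciation. Every pair
#' must satisfy `m*eps == product` to numerical precision.
#'
#' @param pairs List of `c(m, eps)` pairs. Defaults: (0.1, 0.0025),
#'   (0.005, 0.05), (0.001, 0.25), all with product 2.5e-4.
#' @param product The fixed value of `m*eps`.
#' @param params Base parameters (`l`, `u`, `zc` are taken from here;
#'   defaults `l = 100`, `u = 7.5e-5`).
#' @inheritParams sweep_threshold
#' @return Data frame with one row per pair: m, eps, mean/SE of `tau2`,
#'   counts.
#' @export
sweep_epsilon <- function(pairs = list(c(0.1, 0.0025), c(0.005, 0.05),
                                       c(0.001, 0.25)),
                          product = 2.5e-4,
                          params = island_params(u = 7.5e-5, l = 100,
                                                 zc = 0.3, eps = 0.01),
                          reps = 200L, dt = 1, t_max = 5e5, seed = NULL,
                          backend = c("sde", "oracle")) {
  backend <- match.arg(backend)
  if (reps < 2L) stop("'reps' must be >= 2")
  for (pr in pairs)
    if (abs(pr[[1L]] * pr[[2L]] - product) > 1e-12)
      stop("pair (m = ", pr[[1L]], ", eps = ", pr[[2L]],
           ") violates m*eps = ", product)
  out <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    m_i <- pairs[[i]][[1L]]; eps_i <- pairs[[i]][[2L]]
    p <- suppressWarnings(
      island_params(u = params$u, m = m_i, eps = eps_i, l = params$l,
                    zc = params$zc,
                    irreversible_bonds = params$irreversible_bonds))
    wt <- .wt_cell(p, reps, dt, t_max, seed, i, backend)
    s <- summarize_waiting_times(wt$tau2)
    out[[i]] <- data.frame(m = m_i, eps = eps_i, mean_tau2 = s$mean,
                           se_tau2 = s$se, n = s$n, censored = s$censored)
  }
  do.call(rbind, out)
}

#' tau3/tau2 ratio against the spread of the migration rates
#'
#' For each combination of the three symmetric bond rates, runs replicate
#' three-island simulations, computes the waiting times to two and three
#' species, and regresses the ratio on the standard deviation `sigma(m)` of
#' the three bond rates (ordinary least squares with intercept). The ratio is
#' reported both as mean(tau3)/mean(tau2) (the default, used for the
#' regression) and as the mean of per-replicate ratios.
#'
#' @param m_combos List of length-3 vectors `(m_AB, m_BC, m_CA)` of symmetric
#'   bond rates.
#' @param params Base parameters; defaults `zc = 0.3`, `l = 20`,
#'   `u = 7.5e-5`, `eps = 0.01`.
#' @inheritParams sweep_threshold
#' @param reps Replicates per combination (>= 2).
#' @return List with `table` (one row per combination: rates, `sigma_m`, mean
#'   tau2/tau3, both ratio versions, censoring counts), `slope` (OLS slope of
#'   ratio on sigma_m) and `fit` (the `lm` object).
#' @export
ratio_vs_migration_sd <- function(m_combos,
                                  params = island_params(u = 7.5e-5,
                                                         eps = 0.01,
                                                         l = 20, zc = 0.3),
                                  reps = 50L, dt = 1, t_max = 5e5,
                                  seed = NULL) {
  if (reps < 2L) stop("'reps' must be >= 2")
  out <- vector("list", length(m_combos))
  for (i in seq_along(m_combos)) {
    mc <- as.numeric(m_combos[[i]])
    if (length(mc) != 3L) stop("each migration combo must have 3 rates")
    p <- island_params(u = params$u, eps = params$eps, l = params$l,
                       zc = params$zc,
                       m = stats::setNames(mc, c("AB", "BC", "CA")),
                       irreversible_bonds = params$irreversible_bonds)
    wt <- .wt_cell(p, reps, dt, t_max, seed, i, "sde")
    s2 <- summarize_waiting_times(wt$tau2)
    s3 <- summarize_waiting_times(wt$tau3)
    both <- !is.na(wt$tau2) & !is.na(wt$tau3)
    out[[i]] <- data.frame(
      m_AB = mc[1L], m_BC = mc[2L], m_CA = mc[3L],
      sigma_m = stats::sd(mc),
      mean_tau2 = s2$mean, mean_tau3 = s3$mean,
      ratio = s3$mean / s2$mean,
      mean_replicate_ratio =
        if (any(both)) mean(wt$tau3[both] / wt$tau2[both]) else NA_real_,
      n = sum(both), censored3 = s3$censored)
  }
  tab <- do.call(rbind, out)
  fit <- stats::lm(ratio ~ sigma_m, data = tab)
  list(table = tab, slope = unname(stats::coef(fit)[2L]), fit = fit)
}
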