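# Geographical configurations (GCs) of allele sharing at one locus across
# three islands A, B, C. The five configurations, labelled 1..5:
#   1 (ABC)       all three islands share the fixed allele
#   2 (A)(BC)     B and C share, A differs
#   3 (B)(CA)     C and A share, B differs
#   4 (C)(AB)     A and B share, C differs
#   5 (A)(B)(C)   all three differ
.GC_NAMES <- c("(ABC)", "(A)(BC)", "(B)(CA)", "(C)(AB)", "(A)(B)(C)")

#' GC fraction vector
#'
#' Constructs and validates the five-vector (z1..z5) of fractions of loci in
#' each geographical configuration. Components must be in \[0, 1\] and sum to 1
#' within `tol`.
#'
#' @param z Numeric vector of length 5: fractions of loci with configurations
#'   (ABC), (A)(BC), (B)(CA), (C)(AB), (A)(B)(C).
#' @param tol Tolerance on the unit-sum constraint.
#' @return Named numeric vector of class `gc_fractions`.
#' @export
gc_fractions <- function(z, tol = 1e-9) {
  if (!is.numeric(z) || length(z) != 5L || anyNA(z))
    stop("GC fractions must be a numeric vector of length 5")
  if (any(z < -tol) || any(z > 1 + tol))
    stop("GC fractions must lie in [0, 1]")
  if (abs(sum(z) - 1) > tol)
    stop("GC fractions must sum to 1 (got ", format(sum(z)), ")")
  z <- pmin(pmax(as.numeric(z), 0), 1)
  names(z) <- paste0("z", 1:5)
  class(z) <- "gc_fractions"
  z
}

#' @export
print.gc_fractions <- function(x, ...) {
  v <- unclass(x)
  names(v) <- .GC_NAMES
  print(v, ...)
  invisible(x)
}

#' Clip and renormalize a raw GC vector
#'
#' Gaussian SDE increments can push components slightly outside \[0, 1\]; this
#' operation clips each component into \[0, 1\] and rescales the vector to sum
#' exactly to 1. A vector that is already valid is returned unchanged (up to
#' the exact renormalization).
#'
#' @param raw Numeric vector of length 5.
#' @return A `gc_fractions` vector.
#' @export
normalize_gc <- function(raw) {
  if (!is.numeric(raw) || length(raw) != 5L || anyNA(raw))
    stop("expected a numeric vector of length 5")
  z <- pmin(pmax(as.numeric(raw), 0), 1)
  s <- sum(z)
  if (s <= 0)
    stop("degenerate GC state: all components zero after clipping")
  gc_fractions(z / s)
}

#' Pairwise genetic distances from GC fractions
#'
#' The distance between two islands is the fraction of loci at which they are
#' fixed for different alleles, i.e. the total fraction of configurations that
#' separate the pair: zAB = z2 + z3 + z5, zBC = z3 + z4 + z5,
#' zCA = z2 + z4 + z5.
#'
#' @param gc A `gc_fractions` vector (or a numeric vector accepted by
#'   [gc_fractions()]).
#' @return Named numeric vector `c(zAB, zBC, zCA)`.
#' @examples
#' gc_distances(c(1/3, 0, 0, 0, 2/3))   # all three distances 2/3
#' gc_distances(c(0, 1/3, 1/3, 1/3, 0)) # the same distances, different GCs
#' @export
gc_distances <- function(gc) {
  z <- gc_fractions(unclass(gc))
  c(zAB = z[[2L]] + z[[3L]] + z[[5L]],
    zBC = z[[3L]] + z[[4L]] + z[[5L]],
    zCA = z[[2L]] + z[[4L]] + z[[5L]])
}

#' Migration bond graph of the three islands
#'
#' Tracks, for each unordered island pair, whether its migration bond is open,
#' whether it has been permanently severed by a speciation event, and when it
#' (permanently) closed.
#'
#' @return An object of class `bond_graph`.
#' @export
bond_graph <- function() {
  structure(
    list(open = stats::setNames(rep(TRUE, 3L), .PAIRS),
         severed = stats::setNames(rep(FALSE, 3L), .PAIRS),
         latched = stats::setNames(rep(FALSE, 3L), .PAIRS),
         closed_at = stats::setNames(rep(NA_real_, 3L), .PAIRS),
         tau2 = NA_real_, tau3 = NA_real_,
         state = "one_species"),
    class = "bond_graph")
}

#' @export
print.bond_graph <- function(x, ...) {
  cat("Island bond graph:", x$state, "\n")
  st <- ifelse(x$severed, "severed", ifelse(x$open, "open", "closed"))
  cat(paste(sprintf("  %s: %s", .PAIRS, st), collapse = "\n"), "\n")
  if (!is.na(x$tau2)) cat("  tau2 =", x$tau2, "\n")
  if (!is.na(x$tau3)) cat("  tau3 =", x$tau3, "\n")
  invisible(x)
}

#' Speciation predicate on the island bond graph
#'
#' A bond is closed while the pairwise distance strictly exceeds `zc` (a
#' distance exactly equal to `zc` leaves the bond open). The species count is
#' read off the graph of open bonds on the three islands: with at least two
#' open bonds all islands are connected (possibly indirectly) and there is one
#' species; with exactly one open bond one island is isolated (two species);
#' with none, three species. The first time the graph disconnects, the bonds
#' closed at that moment are permanently severed (migration across them is
#' zero from then on). With `irreversible_bonds`, any closure latches even
#' before a split.
#'
#' @param d Distances `c(zAB, zBC, zCA)` as from [gc_distances()].
#' @param params An `island_params` object (supplies `zc` and the
#'   irreversibility policy).
#' @param graph A `bond_graph`, carried between calls.
#' @param t Current time, used to stamp closure and split times.
#' @return List with elements `state` (one of `"one_species"`,
#'   `"two_species"`, `"three_species"`) and `graph` (updated `bond_graph`).
#' @export
speciation_state <- function(d, params, graph = bond_graph(), t = NA_real_) {
  params <- .check_params(params)
  if (!inherits(graph, "bond_graph")) stop("'graph' must be a bond_graph")
  d <- as.numeric(d)
  if (length(d) != 3L || anyNA(d) || any(d < 0) || any(d > 1))
    stop("distances must be three numbers in [0, 1]")
  over <- d > params$zc
  if (params$irreversible_bonds) graph$latched <- graph$latched | over
  closed <- graph$severed | over | graph$latched
  n_open <- sum(!closed)
  split_now <- graph$state == "one_species" && n_open <= 1L
  if (split_now) {
    graph$tau2 <- t
    newly <- closed & !graph$severed
    graph$severed <- closed
    graph$closed_at[newly] <- t
    graph$state <- "two_species"
  }
  if (n_open == 0L && is.na(graph$tau3)) {
    graph$tau3 <- t
    newly <- closed & !graph$severed
    graph$severed[] <- TRUE
    graph$closed_at[newly] <- t
    graph$state <- "three_species"
  }
  if (graph$state == "three_species" || n_open == 0L) {
    graph$state <- "three_species"
  } else if (graph$state == "two_species" || n_open == 1L) {
    graph$state <- "two_species"
  }
  graph$open <- !closed & !graph$severed
  list(state = graph$state, graph = graph)
}
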