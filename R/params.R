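# Directed bond order used throughout the package.
.DIRECTED_BONDS <- c("AB", "BA", "AC", "CA", "BC", "CB")
# Unordered island pairs, in the order of the distance vector (zAB, zBC, zCA).
.PAIRS <- c("AB", "BC", "CA")
# Index (into .PAIRS) of the pair crossed by each directed bond.
.PAIR_OF_BOND <- c(1L, 1L, 3L, 3L, 2L, 2L)

#' Model parameters for the island speciation models
#'
#' Bundles the parameters shared by the two-island and three-island models:
#' the number of incompatibility-controlling loci `l` (may be `Inf`, in which
#' case per-locus sampling noise vanishes), the per-locus mutation-and-fixation
#' rate `u` per generation, the migration impact `eps` (expected fraction of
#' differing loci at which the migrant allele fixes after one successful
#' migration event; equals N'/(N+N') for migrant group size N' into a resident
#' population of size N), the speciation threshold `zc` (a migration bond
#' between two islands is closed while their genetic distance exceeds `zc`),
#' and the six directed migration rates.
#'
#' @param u Per-locus mutation-fixation rate per generation (>= 0).
#' @param m Migration rates per generation. Either a single number (applied to
#'   all six directed island pairs), a length-3 vector named `AB`, `BC`, `CA`
#'   (symmetric rates per unordered pair), or a length-6 vector named
#'   `AB`, `BA`, `AC`, `CA`, `BC`, `CB` (directed rates). The two-island model
#'   uses the `AB` and `BA` entries.
#' @param eps Migration impact, in (0, 1]. The model assumes `eps` small;
#'   a warning is issued above 0.25.
#' @param l Number of incompatibility loci (whole number >= 1) or `Inf`.
#' @param zc Speciation threshold in \[0, 1\].
#' @param irreversible_bonds If `TRUE`, a bond that closes (distance exceeds
#'   `zc`) stays closed even if the distance later drops back. The default
#'   `FALSE` lets bonds reopen until the island graph actually disconnects,
#'   after which severed bonds are permanently closed in either mode.
#' @return An object of class `island_params`.
#' @examples
#' p <- island_params(u = 2e-4, m = 0.015, eps = 0.01, l = 20, zc = 0.8)
#' p
#' @export
island_params <- function(u, m = 0, eps = 0.01, l = Inf, zc = 1,
                          irreversible_bonds = FALSE) {
  if (!is.numeric(u) || length(u) != 1L || is.na(u) || u < 0)
    stop("'u' must be a single nonnegative number")
  if (!is.numeric(eps) || length(eps) != 1L || is.na(eps) ||
      eps <= 0 || eps > 1)
    stop("'eps' must lie in (0, 1]")
  if (eps > 0.25)
    warning("the model assumes eps << 1; eps = ", eps,
            " is outside the regime where the diffusion limit is reliable")
  if (!is.numeric(zc) || length(zc) != 1L || is.na(zc) || zc < 0 || zc > 1)
    stop("'zc' must lie in [0, 1]")
  if (!is.numeric(l) || length(l) != 1L || is.na(l))
    stop("'l' must be a whole number >= 1 or Inf")
  if (is.finite(l) && (l < 1 || abs(l - round(l)) > 1e-8))
    stop("'l' must be a whole number >= 1 or Inf")
  if (is.finite(l)) l <- round(l)
  m6 <- expand_migration(m)
  structure(
    list(l = l, u = u, eps = eps, zc = zc, m = m6,
         irreversible_bonds = isTRUE(irreversible_bonds)),
    class = "island_params")
}

#' Expand a migration-rate specification to six directed rates
#'
#' @param m Scalar, named length-3 (`AB`, `BC`, `CA`) or named length-6
#'   (`AB`, `BA`, `AC`, `CA`, `BC`, `CB`) nonnegative rates. Unnamed vectors of
#'   length 3 or 6 are taken in those orders.
#' @return Named numeric vector of the six directed rates.
#' @export
expand_migration <- function(m) {
  if (!is.numeric(m) || anyNA(m) || any(m < 0))
    stop("migration rates must be nonnegative numbers")
  if (length(m) == 1L) {
    m6 <- rep(as.numeric(m), 6L)
  } else if (length(m) == 3L) {
    if (is.null(names(m))) names(m) <- .PAIRS
    if (!setequal(names(m), .PAIRS))
      stop("length-3 migration rates must be named ",
           paste(.PAIRS, collapse = ", "))
    # each unordered pair gets the same rate in both directions
    m6 <- as.numeric(m[.PAIRS][.PAIR_OF_BOND])
  } else if (length(m) == 6L) {
    if (is.null(names(m))) names(m) <- .DIRECTED_BONDS
    if (!setequal(names(m), .DIRECTED_BONDS))
      stop("length-6 migration rates must be named ",
           paste(.DIRECTED_BONDS, collapse = ", "))
    m6 <- as.numeric(m[.DIRECTED_BONDS])
  } else {
    stop("'m' must have length 1, 3 or 6")
  }
  names(m6) <- .DIRECTED_BONDS
  m6
}

#' @export
print.island_params <- function(x, ...) {
  cat("Island speciation model parameters\n")
  cat(sprintf("  loci l   : %s\n", if (is.finite(x$l)) x$l else "infinite"))
  cat(sprintf("  u        : %g per locus per generation\n", x$u))
  cat(sprintf("  eps      : %g\n", x$eps))
  cat(sprintf("  zc       : %g\n", x$zc))
  cat("  m (directed):\n")
  print(x$m)
  if (x$irreversible_bonds)
    cat("  bond closure: irreversible\n")
  invisible(x)
}

# internal: validate an island_params object given by the user
.check_params <- function(params) {
  if (!inherits(params, "island_params"))
    stop("'params' must be created by island_params()")
  params
}
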