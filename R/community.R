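#' Define a community of competing species
#'
#' A community is a set of `N` species competing for a single per-patch
#' resource. Each species is characterised by two metabolic traits: its
#' exponential growth rate `mu` (offspring per individual per unit time while
#' resource lasts) and its efficiency `Y` (offspring produced per unit of
#' patch resource, i.e. the number of offspring a lone founder leaves on a
#' patch with `R = 1`). The phenotype coordinate used for distances and
#' profiles is `z = log(mu)`.
#'
#' Changing the per-patch resource `R` by a factor `c` is exactly equivalent
#' to multiplying every efficiency by `c`; the optional rescaling factor `s`
#' applies that multiplication explicitly (`Y -> s * Y`), which is how the
#' large-resource ("complete dominance") limit is reached.
#'
#' @param mu numeric vector of growth rates, all positive. Species are
#'   stored sorted by increasing `mu`.
#' @param Y numeric vector of efficiencies, all positive, same length as
#'   `mu` (in the order of the supplied `mu`).
#' @param R amount of resource per patch (default 1).
#' @param s resource rescaling factor applied as `Y -> s * Y` (default 1).
#' @return An object of class `community` with fields `N`, `mu`, `Y`
#'   (already rescaled by `s`), `Y_base`, `R`, `s` and `z = log(mu)`.
#' @examples
#' comm <- community(mu = c(0.1, 0.3), Y = c(1200, 800))
#' comm$z
#' @export
community <- function(mu, Y, R = 1, s = 1) {
  mu <- as.numeric(mu)
  Y <- as.numeric(Y)
  if (length(mu) == 0L || length(mu) != length(Y))
    stop("'mu' and 'Y' must be non-empty vectors of equal length")
  if (!all(is.finite(mu)) || !all(is.finite(Y)) || !is.finite(R) || !is.finite(s))
    stop("community parameters must be finite")
  if (any(mu <= 0) || any(Y <= 0) || R <= 0 || s < 1)
    stop("community requires mu > 0, Y > 0, R > 0 and s >= 1")
  ord <- order(mu)
  mu <- mu[ord]
  Y <- Y[ord]
  structure(
    list(N = length(mu), mu = mu, Y_base = Y, Y = s * Y, R = R, s = s,
         z = log(mu)),
    class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("community: %d species, R = %g%s\n", x$N, x$R,
              if (x$s != 1) sprintf(", Y rescaled by s = %g", x$s) else ""))
  print(data.frame(mu = x$mu, Y = x$Y, z = x$z))
  invisible(x)
}

#' Geometrically spaced growth rates
#'
#' Growth rates "logarithmically spaced" on an interval, i.e. geometric
#' spacing inclusive of both endpoints, so that the phenotype coordinates
#' `z = log(mu)` form a uniform grid.
#'
#' @param n number of species.
#' @param from,to interval endpoints (defaults 0.1 and 0.3).
#' @return numeric vector of length `n`.
#' @export
mu_grid <- function(n, from = 0.1, to = 0.3) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Solve the within-patch growth time for a seeding
#'
#' Given an integer seeding vector `m`, the time `T` at which the patch
#' resource is exhausted solves
#' `sum_k m_k (exp(mu_k T) - 1) / Y_k = R`.
#' The left side is strictly increasing and convex in `T`, so the root is
#' unique; it is found by safeguarded Newton iteration from the
#' single-species depletion bound, to absolute residual below 1e-12.
#'
#' @param m integer seeding vector (length `N`), or an integer matrix with
#'   one seeding per row for batch evaluation.
#' @param comm a [community()].
#' @return numeric growth time(s), one per seeding.
#' @seealso [final_abundances()]
#' @export
growth_time <- function(m, comm) {
  mm <- as_seeding_matrix(m, comm, allow_empty = FALSE)
  drop(growth_time_batch_cpp(mm, comm$mu, comm$Y, comm$R))
}

#' Final per-patch abundances after a growth cycle
#'
#' For a seeding `m` the final abundance of species `k`, averaged over all
#' patches with that seeding, is `f_k = m_k * exp(mu_k * T)` with `T` the
#' growth time of the patch. An empty seeding returns zero abundances and
#' `T = 0`. Resource is conserved: `sum_k (f_k - m_k) / Y_k = R` whenever at
#' least one individual is seeded.
#'
#' @inheritParams growth_time
#' @return A list with components `T` (growth times) and `f` (matrix of
#'   final abundances, one row per seeding).
#' @export
final_abundances <- function(m, comm) {
  mm <- as_seeding_matrix(m, comm, allow_empty = TRUE)
  T <- growth_time_batch_cpp(mm, comm$mu, comm$Y, comm$R)
  f <- mm * exp(outer(T, comm$mu))
  list(T = drop(T), f = f)
}

as_seeding_matrix <- function(m, comm, allow_empty) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  if (ncol(m) != comm$N)
    stop("seeding has wrong number of species")
  if (any(m < 0) || any(m != round(m)))
    stop("seedings must be non-negative integers")
  if (!allow_empty && any(rowSums(m) == 0))
    stop("growth time is undefined for an empty seeding")
  storage.mode(m) <- "integer"
  m
}

#' Enumerate all seedings up to a total seed count
#'
#' All non-negative integer seeding vectors with `sum(m) <= max_total`,
#' grouped by total in ascending order so that the enumeration for a smaller
#' bound is a prefix of the enumeration for a larger one. The number of rows
#' is `choose(N + max_total, max_total)`.
#'
#' @param N number of species.
#' @param max_total maximum total seed count.
#' @return integer matrix with `N` columns.
#' @export
enumerate_seedings <- function(N, max_total) {
  if (N < 1 || max_total < 0) stop("invalid enumeration bounds")
  if (choose(N + max_total, max_total) > 2^31 - 1)
    stop("seeding enumeration would exceed integer indexing")
  enum_seedings_cpp(as.integer(N), as.integer(max_total))
}
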