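#' Poisson seeding probability
#'
#' Probability that a patch receives the integer seeding `m` when the
#' per-patch pool abundances are `n` and a fraction `alpha` of the pool is
#' dispersed: a product of independent Poisson probabilities with means
#' `alpha * n_k`.
#'
#' @param m integer seeding vector.
#' @param n non-negative abundance vector.
#' @param alpha dilution factor (> 0).
#' @return a probability in `[0, 1]`.
#' @export
seeding_probability <- function(m, n, alpha) {
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive")
  if (any(!is.finite(n)) || any(n < 0)) stop("'n' must be finite and non-negative")
  if (length(m) != length(n)) stop("'m' and 'n' must have equal length")
  if (any(m < 0) || any(m != round(m))) stop("'m' must be non-negative integers")
  exp(sum(dpois(m, alpha * n, log = TRUE)))
}

#' Truncation policy for the expectation update
#'
#' The one-cycle expectation update sums final abundances over infinitely
#' many seedings. The sum is truncated at a maximum total seed count `M`
#' chosen so that the neglected Poisson probability mass (the upper tail of
#' a Poisson with mean `alpha * sum(n)`) stays below `tail_epsilon`. By
#' default `M` is re-derived from the current state every cycle
#' (`adaptive = TRUE`), because noisy trajectories wander far from the
#' fixpoint where a fixpoint-anchored `M` silently loses probability mass.
#' Setting `adaptive = FALSE` with a fixed `static_M` reproduces the
#' original fixpoint-anchored convention.
#'
#' When the adaptive bound would require more than `config_ceiling`
#' enumerated seedings, the update falls back to plain Monte-Carlo
#' estimation with `mc_samples` Poisson draws (flagged in trace metadata).
#'
#' @param tail_epsilon maximum neglected probability mass (default 1e-7).
#' @param adaptive re-derive `M` from the current state each cycle?
#' @param static_M fixed total seed bound used when `adaptive = FALSE`.
#' @param config_ceiling maximum number of enumerated seedings before the
#'   Monte-Carlo fallback engages (default 5e6).
#' @param mc_samples Monte-Carlo sample count for the fallback.
#' @return an object of class `truncation_policy`.
#' @export
truncation_policy <- function(tail_epsilon = 1e-7, adaptive = TRUE,
                              static_M = NULL, config_ceiling = 5e6,
                              mc_samples = 30000L) {
  if (!is.finite(tail_epsilon) || tail_epsilon <= 0 || tail_epsilon >= 1)
    stop("'tail_epsilon' must lie in (0, 1)")
  if (!adaptive && is.null(static_M))
    stop("a static policy needs 'static_M'")
  structure(list(tail_epsilon = tail_epsilon, adaptive = adaptive,
                 static_M = if (is.null(static_M)) NULL else as.integer(static_M),
                 config_ceiling = config_ceiling,
                 mc_samples = as.integer(mc_samples)),
            class = "truncation_policy")
}

#' Smallest certified truncation total
#'
#' The total seed count over independent Poisson seedings is itself Poisson
#' with mean `lambda = alpha * sum(n)`. This returns the smallest `M` whose
#' upper tail probability `P(total > M)` is below `tail_epsilon`.
#'
#' @param n abundance vector (or a single precomputed intensity if
#'   `alpha = 1`).
#' @param alpha dilution factor.
#' @param tail_epsilon maximum neglected probability mass.
#' @return integer truncation total `M`.
#' @export
derive_truncation <- function(n, alpha, tail_epsilon = 1e-7) {
  if (tail_epsilon <= 0 || tail_epsilon >= 1) stop("'tail_epsilon' must lie in (0,1)")
  lambda <- alpha * sum(n)
  if (lambda < 0 || !is.finite(lambda)) stop("invalid Poisson intensity")
  M <- 0L
  while (ppois(M, lambda, lower.tail = FALSE) >= tail_epsilon) M <- M + 1L
  M
}

#' Precompute growth outcomes for all seedings up to a total
#'
#' Growth outcomes depend only on the integer seeding (the community being
#' fixed), so they are computed once per community and reused across every
#' cycle and every derivative evaluation: this table is the memoisation of
#' the growth solver. Rows are grouped by total seed count so the table for
#' any smaller bound is a prefix.
#'
#' @param comm a [community()].
#' @param max_total largest total seed count to tabulate.
#' @return an object of class `seeding_table` with the seeding matrix `mm`,
#'   growth times `T`, final abundances `Fm`, log factorial terms `lfac`,
#'   and `cumrows[M + 1]` = number of rows with total `<= M`.
#' @export
seeding_table <- function(comm, max_total) {
  stopifnot(inherits(comm, "community"))
  mm <- enumerate_seedings(comm$N, max_total)
  T <- growth_time_batch_cpp(mm, comm$mu, comm$Y, comm$R)
  structure(
    list(comm = comm, max_total = as.integer(max_total), mm = mm, T = T,
         Fm = mm * exp(outer(T, comm$mu)),
         lfac = rowSums(lgamma(mm + 1)),
         cumrows = cum_config_counts(comm$N, max_total)),
    class = "seeding_table")
}

# cum_config_counts(N, M)[t + 1] = number of seedings with total <= t,
# which is choose(N + t, t)
cum_config_counts <- function(N, max_total) {
  out <- choose(N + 0:max_total, 0:max_total)
  if (any(out > 2^31 - 1)) stop("seeding table too large")
  as.integer(out)
}

#' Extend a seeding table to a larger total
#'
#' Reuses all previously solved growth outcomes (prefix property) and solves
#' only the newly enumerated seedings.
#'
#' @param tab a [seeding_table()].
#' @param max_total new, larger bound.
#' @return the extended `seeding_table`.
#' @export
extend_seeding_table <- function(tab, max_total) {
  if (max_total <= tab$max_total) return(tab)
  comm <- tab$comm
  mm <- enumerate_seedings(comm$N, max_total)
  old <- nrow(tab$mm)
  new_rows <- mm[(old + 1):nrow(mm), , drop = FALSE]
  Tn <- growth_time_batch_cpp(new_rows, comm$mu, comm$Y, comm$R)
  structure(
    list(comm = comm, max_total = as.integer(max_total), mm = mm,
         T = c(tab$T, Tn),
         Fm = rbind(tab$Fm, new_rows * exp(outer(Tn, comm$mu))),
         lfac = c(tab$lfac, rowSums(lgamma(new_rows + 1))),
         cumrows = cum_config_counts(comm$N, max_total)),
    class = "seeding_table")
}

#' One-cycle expectation update
#'
#' Maps the per-patch abundance vector `n(t)` to `n(t+1)` by averaging final
#' abundances over all seedings weighted by their Poisson probability,
#' truncated at total seed count `M` certified by the policy:
#' `n'_k = sum_m P(m) f_k(m)`.
#'
#' @param n abundance vector.
#' @param alpha dilution factor.
#' @param comm a [community()]; ignored when `table` is supplied.
#' @param policy a [truncation_policy()].
#' @param table optional precomputed [seeding_table()] (built on the fly if
#'   missing; pass one when calling repeatedly).
#' @return the next abundance vector, with attributes `mass` (enumerated
#'   probability mass), `M` (truncation total used) and `mc` (logical:
#'   Monte-Carlo fallback used).
#' @export
step_map <- function(n, alpha, comm = NULL, policy = truncation_policy(),
                     table = NULL) {
  if (is.null(table)) {
    stopifnot(inherits(comm, "community"))
    M0 <- derive_truncation(n, alpha, policy$tail_epsilon)
    table <- seeding_table(comm, max(M0, policy$static_M, 1L))
  }
  comm <- table$comm
  if (any(!is.finite(n)) || any(n < 0)) stop("'n' must be finite and non-negative")
  if (alpha <= 0) stop("'alpha' must be positive")
  M_need <- derive_truncation(n, alpha, policy$tail_epsilon)
  if (policy$adaptive) {
    M <- M_need
    if (choose(comm$N + M, M) > policy$config_ceiling)
      return(step_map_mc(n, alpha, comm, policy))
    if (M > table$max_total)
      table <- extend_seeding_table(table, M)
  } else {
    M <- policy$static_M
    if (M_need > M)
      stop(sprintf(paste0("static truncation M = %d violates the tail bound at",
                          " the current state (needs M = %d); use an adaptive",
                          " policy or a larger static_M"), M, M_need))
    if (M > table$max_total) table <- extend_seeding_table(table, M)
  }
  res <- step_kernel_cpp(table$mm, table$Fm, table$lfac,
                         table$cumrows[M + 1L], n, alpha)
  structure(res$n_next, mass = res$mass, M = M, mc = FALSE)
}

step_map_mc <- function(n, alpha, comm, policy) {
  S <- policy$mc_samples
  mm <- matrix(rpois(S * comm$N, rep(alpha * n, each = S)), S, comm$N)
  storage.mode(mm) <- "integer"
  T <- growth_time_batch_cpp(mm, comm$mu, comm$Y, comm$R)
  f <- mm * exp(outer(T, comm$mu))
  structure(colMeans(f), mass = NA_real_,
            M = derive_truncation(n, alpha, policy$tail_epsilon), mc = TRUE)
}

#' Export the truncated expectation sum as a data frame
#'
#' One row per enumerated seeding: the seeding vector, its Poisson
#' probability at the given state, the growth time, and the final
#' abundances. Intended for inspection and debugging of the truncation.
#'
#' @param table a [seeding_table()].
#' @param n abundance vector.
#' @param alpha dilution factor.
#' @param M truncation total (defaults to the table's bound).
#' @return a data frame.
#' @export
step_table_frame <- function(table, n, alpha, M = table$max_total) {
  rows <- table$cumrows[M + 1L]
  mm <- table$mm[seq_len(rows), , drop = FALSE]
  prob <- vapply(seq_len(rows),
                 function(i) seeding_probability(mm[i, ], n, alpha), 0)
  out <- data.frame(mm, prob = prob, T = table$T[seq_len(rows)],
                    table$Fm[seq_len(rows), , drop = FALSE])
  names(out) <- c(paste0("m", seq_len(ncol(mm))), "prob", "T",
                  paste0("f", seq_len(ncol(mm))))
  out
}
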