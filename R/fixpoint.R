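#' Solve species efficiencies for a prescribed coexistence fixpoint
#'
#' Given target per-patch abundances `n0` (typically equal across species),
#' growth rates `mu` and a dilution factor `alpha0`, finds the efficiency
#' vector `Y` such that the one-cycle expectation update maps `n0` to
#' itself. This is the trade-off construction: in the usual regime the
#' solved `Y` decreases with `mu` (fast species are inefficient).
#'
#' The solver is a damped multivariate Newton iteration on
#' `G(Y) = step_map(n0; Y) - n0` with the exact Jacobian in `Y` obtained by
#' implicit differentiation of the growth-time equation, initialised from
#' the complete-dominance hierarchy inverted for `Y` at the target
#' abundances. The truncation total is certified at `tail_epsilon`
#' (default 1e-13, far below the update tolerance so that the neglected
#' tail cannot masquerade as a residual).
#'
#' @param n0 target abundance per species: a scalar (equal abundances) or a
#'   vector aligned with `mu`.
#' @param mu strictly increasing growth rates.
#' @param alpha0 dilution factor at the fixpoint.
#' @param R resource per patch.
#' @param tol convergence tolerance: `max|G| < tol * max(n0)`.
#' @param max_iter Newton iteration budget.
#' @param tail_epsilon truncation tail bound used during the solve.
#' @return An object of class `fixpoint_result`: fields `community` (with
#'   the solved `Y`), `n_star`, `alpha0`, `residual`, `converged`,
#'   `iterations`, `M` (truncation total) and `tail_epsilon`.
#' @examples
#' fp <- solve_efficiencies(100, mu = 0.2, alpha0 = 1e-3)
#' fp$community$Y  # equals n0 * (1 - alpha) / (1 - exp(-alpha * n0))
#' @export
solve_efficiencies <- function(n0, mu, alpha0, R = 1, tol = 1e-9,
                               max_iter = 200L, tail_epsilon = 1e-13) {
  mu <- as.numeric(mu)
  N <- length(mu)
  if (is.unsorted(mu, strictly = TRUE))
    stop("'mu' must be strictly increasing")
  if (length(n0) == 1L) n0 <- rep(n0, N)
  if (length(n0) != N || any(n0 <= 0)) stop("invalid target abundances")
  if (alpha0 <= 0) stop("'alpha0' must be positive")

  # dominance-hierarchy inversion at s = 1: cheap start in the right basin
  above <- rev(cumsum(rev(n0))) - n0
  Y <- n0 * exp(alpha0 * above) / (1 - exp(-alpha0 * n0)) / R
  M <- derive_truncation(n0, alpha0, tail_epsilon)
  mm <- enumerate_seedings(N, M)
  lfac <- rowSums(lgamma(mm + 1))
  lw <- mm %*% log(alpha0 * n0) - alpha0 * sum(n0) - lfac
  w <- exp(drop(lw))

  eval_G <- function(Y) {
    T <- growth_time_batch_cpp(mm, mu, Y, R)
    E <- exp(outer(T, mu))
    Fm <- mm * E
    G <- drop(crossprod(Fm, w)) - n0
    list(G = G, T = T, E = E, Fm = Fm)
  }
  jac_Y <- function(st) {
    B <- sweep(mm * (st$E - 1), 2, Y^2, "/")       # dResidual_i / dY_j * (-1)
    D <- drop((mm * sweep(st$E, 2, mu, "*")) %*% (1 / Y))
    D[D == 0] <- Inf                               # empty seeding rows
    JY <- crossprod(st$Fm, (w / D) * B)
    JY * mu                                        # row scaling by mu_k
  }

  st <- eval_G(Y)
  res <- max(abs(st$G))
  it <- 0L
  while (res >= tol * max(n0) && it < max_iter) {
    it <- it + 1L
    dY <- solve(jac_Y(st), -st$G)
    lam <- 1
    repeat {
      Yn <- Y + lam * dY
      if (all(Yn > 0)) {
        stn <- eval_G(Yn)
        if (max(abs(stn$G)) < res) break
      }
      lam <- lam / 2
      if (lam < 1e-8) {
        stn <- NULL
        break
      }
    }
    if (is.null(stn))
      stop(sprintf("efficiency solve stalled at residual %.3g after %d iterations",
                   res, it))
    Y <- Y + lam * dY
    st <- stn
    res <- max(abs(st$G))
  }
  if (res >= tol * max(n0))
    stop(sprintf("efficiency solve did not converge: residual %.3g after %d iterations",
                 res, it))
  structure(
    list(community = community(mu, Y, R = R), n_star = n0, alpha0 = alpha0,
         residual = res, converged = TRUE, iterations = it, M = M,
         tail_epsilon = tail_epsilon),
    class = "fixpoint_result")
}

#' @export
print.fixpoint_result <- function(x, ...) {
  cat(sprintf(
    "fixpoint: %d species, alpha0 = %g, residual %.3g (%s, %d iterations)\n",
    x$community$N, x$alpha0, x$residual,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Complete-dominance fixpoint (large-resource limit)
#'
#' In the limit of abundant per-patch resource (efficiencies rescaled by a
#' large factor `s`), only the fastest species present on a patch reaps its
#' resource. The fixpoint equations then decouple hierarchically: with
#' species ordered by increasing `mu`, the abundance of species `k` depends
#' only on its own parameters and on the species above it,
#' `n_k = s Y_k (1 - exp(-alpha n_k)) exp(-alpha sum_{j>k} n_j)`,
#' and each level is a scalar root solve performed top-down.
#'
#' A level with no positive root (competitive exclusion in the
#' approximation) gets abundance 0 and is reported in the `excluded`
#' attribute.
#'
#' @param comm a [community()] (its `Y` already includes any rescaling set
#'   at construction).
#' @param alpha dilution factor.
#' @param s additional resource rescaling applied as `Y -> s * Y`
#'   (default 1).
#' @return abundance vector with attribute `excluded` (logical).
#' @export
dominance_fixpoint <- function(comm, alpha, s = 1) {
  stopifnot(inherits(comm, "community"))
  if (alpha <= 0 || s < 1) stop("need alpha > 0 and s >= 1")
  Ys <- comm$Y * s * comm$R
  N <- comm$N
  n <- numeric(N)
  excluded <- logical(N)
  above <- 0
  for (k in N:1) {
    A <- Ys[k] * exp(-alpha * above)
    if (A * alpha <= 1) {          # no positive root: excluded at this level
      excluded[k] <- TRUE
      n[k] <- 0
    } else {
      h <- function(x) -A * expm1(-alpha * x) - x
      n[k] <- uniroot(h, c(1e-8 / alpha, A), tol = 1e-12,
                      extendInt = "no")$root
    }
    above <- above + n[k]
  }
  structure(n, excluded = excluded)
}

#' Linear stability of a solved fixpoint
#'
#' Computes the one-step response matrix at the fixpoint and reports the
#' spectral radius: the fixpoint is stable when all eigenvalues have
#' modulus below 1.
#'
#' @param fp a [solve_efficiencies()] result.
#' @param tail_epsilon truncation tail bound for the Jacobian.
#' @return list with `max_lambda` (largest modulus), `stable` (logical) and
#'   the complex eigenvalues `lambdas`.
#' @export
stability_check <- function(fp, tail_epsilon = fp$tail_epsilon) {
  lm <- compute_jacobian(fp, tail_epsilon = tail_epsilon)
  lam <- eigen(lm$J, only.values = TRUE)$values
  list(max_lambda = max(Mod(lam)), stable = max(Mod(lam)) < 1, lambdas = lam)
}
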