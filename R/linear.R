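#' One-step response matrix and noise-input vector at the fixpoint
#'
#' Linearizes the expectation update around the fixpoint:
#' `dn(t+1) = J dn(t) + r dalpha(t)`, with
#' `J_kl = sum_m P(m) (m_l / n_l - alpha) f_k(m)` and
#' `r_k = sum_m P(m) (sum_j m_j / alpha - sum_j n_j) f_k(m)`.
#' Both formulas are the exact derivatives of the truncated Poisson
#' expectation (growth outcomes do not depend on `n` or `alpha`), so no
#' finite-difference step size is involved.
#'
#' The default truncation tail (1e-13) is much tighter than the one used
#' for plain trajectory updates because the slowest eigenvalues sit within
#' ~1e-7 of 1 and would otherwise be polluted by truncation error.
#'
#' @param fp a [solve_efficiencies()] result.
#' @param tail_epsilon truncation tail bound.
#' @return An object of class `linear_model` with `J`, `r`,
#'   `Delta_J = J - I`, and bookkeeping fields. Pass it to
#'   [eigen_analysis()].
#' @seealso [linearize()] for the full pipeline in one call.
#' @export
compute_jacobian <- function(fp, tail_epsilon = fp$tail_epsilon) {
  stopifnot(inherits(fp, "fixpoint_result"))
  comm <- fp$community
  n <- fp$n_star
  alpha <- fp$alpha0
  M <- derive_truncation(n, alpha, tail_epsilon)
  tab <- seeding_table(comm, M)
  lw <- tab$mm %*% log(alpha * n) - alpha * sum(n) - tab$lfac
  w <- exp(drop(lw))
  G <- sweep(tab$mm, 2, n, "/") - alpha
  J <- crossprod(tab$Fm, w * G)
  r <- drop(crossprod(tab$Fm, w * (rowSums(tab$mm) / alpha - sum(n))))
  structure(
    list(J = J, r = r, Delta_J = J - diag(comm$N), fixpoint = fp,
         M = M, tail_epsilon = tail_epsilon),
    class = "linear_model")
}

#' Eigenmode decomposition of the linearized dynamics
#'
#' Diagonalizes the one-step response matrix `J`: each eigenvector is a
#' basic deformation of the abundance profile over phenotype space, its
#' eigenvalue `lambda` the per-cycle decay factor, and
#' `tau = -1 / log(lambda)` its relaxation time in cycles (for
#' `lambda = 1 - eps` close to 1, `tau ~ 1/eps`; both are reported). Modes
#' are sorted by decreasing `lambda` (slowest first). Eigenvectors are
#' normalized to unit Euclidean norm with the sign fixed so the
#' largest-magnitude component is positive.
#'
#' @param lm a `linear_model` from [compute_jacobian()].
#' @return the `linear_model` with `lambdas`, `eps = 1 - lambda`, `S`
#'   (eigenvector columns), `p = S^{-1} r`, `tau`, `tau_approx = 1/eps` and
#'   `stable` filled in. Complex eigenvalues trigger a warning and are
#'   reported by their real parts; moduli at or above 1 are flagged
#'   unstable.
#' @export
eigen_analysis <- function(lm) {
  stopifnot(inherits(lm, "linear_model"))
  ev <- eigen(lm$J)
  if (any(abs(Im(ev$values)) > 1e-9 * (abs(ev$values) + 1e-300)))
    warning("complex eigenvalues encountered; reporting real parts")
  lam <- Re(ev$values)
  S <- Re(ev$vectors)
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]
  S <- S[, ord, drop = FALSE]
  for (k in seq_len(ncol(S))) {
    v <- S[, k]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    S[, k] <- v
  }
  lm$lambdas <- lam
  lm$eps <- 1 - lam
  lm$S <- S
  lm$p <- drop(solve(S, lm$r))
  lm$tau <- ifelse(lam > 0 & lam < 1, -1 / log(lam),
                   ifelse(lam == 0, 0, NA_real_))
  lm$tau_approx <- 1 / lm$eps
  lm$stable <- all(abs(lam) < 1)
  lm
}

#' Stationary eigenmode amplitudes under white dilution noise
#'
#' For white noise of standard deviation `sigma_alpha` in the dilution
#' factor, each eigenmode is an AR(1) process
#' `q_k(t+1) = lambda_k q_k(t) + p_k dalpha(t)` whose stationary mean
#' squared amplitude is `amp2_k = p_k^2 sigma_alpha^2 / (1 - lambda_k^2)`.
#' The amplitude factorizes into noise coupling times relaxation time,
#' `amp2_k = gamma_k tau_k`; `gamma_k = amp2_k / tau_k` is reported.
#' Rescaling `sigma_alpha` scales every amplitude by the same factor, so
#' the shape of the spectrum is noise-level independent.
#'
#' @param lm a `linear_model` after [eigen_analysis()].
#' @param sigma_alpha standard deviation of the dilution factor (see
#'   [noise_model()]).
#' @return the `linear_model` with `sigma_alpha`, `amp2` and `gamma`
#'   filled in. Unstable modes get `NA` amplitudes.
#' @export
amplitude_spectrum <- function(lm, sigma_alpha) {
  stopifnot(inherits(lm, "linear_model"), !is.null(lm$lambdas))
  if (sigma_alpha < 0) stop("'sigma_alpha' must be non-negative")
  lam <- lm$lambdas
  amp2 <- ifelse(abs(lam) < 1, lm$p^2 * sigma_alpha^2 / (1 - lam^2), NA_real_)
  lm$sigma_alpha <- sigma_alpha
  lm$amp2 <- amp2
  lm$gamma <- amp2 / lm$tau
  lm
}

#' Interaction-weighted eigenvectors
#'
#' Because fast species are superior competitors, their components in the
#' raw eigenvectors are systematically smaller. To expose the oscillation
#' structure of each deformation, each component `j` is multiplied by the
#' average interaction strength of species `j` with the other species,
#' taken as the off-diagonal row mean of `|Delta_J| = |J - I|`:
#' `vtilde_j = v_j * mean_{l != j} |Delta_J_{jl}|`. Both the weighted and
#' the raw vectors are retained.
#'
#' @param lm a `linear_model` after [eigen_analysis()].
#' @return the `linear_model` with `v_weighted` (matrix, one column per
#'   mode) and `interaction_weight` filled in.
#' @export
weighted_eigenvectors <- function(lm) {
  stopifnot(inherits(lm, "linear_model"), !is.null(lm$S))
  A <- abs(lm$Delta_J)
  diag(A) <- 0
  wgt <- rowSums(A) / (ncol(A) - 1)
  lm$interaction_weight <- wgt
  lm$v_weighted <- lm$S * wgt
  lm
}

#' Order eigenmodes by roughness in phenotype space
#'
#' Modes are ranked by how jagged their interaction-weighted profile is
#' along the mu-sorted phenotype axis. The roughness score is the number of
#' sign changes of the weighted eigenvector, with ties broken by total
#' variation `sum_j |v_{j+1} - v_j|`. Rank 1 is the smoothest (nearly
#' uniform-sign) deformation; rank N the most jagged. Both the score and
#' the ordering are invariant to flipping any eigenvector's overall sign.
#'
#' @param lm a `linear_model` after [weighted_eigenvectors()].
#' @return the `linear_model` with `roughness` (sign-change count per
#'   mode), `roughness_rank` (1 = smoothest) and `roughness_order` (mode
#'   indices sorted smooth to jagged) filled in.
#' @export
roughness_order <- function(lm) {
  stopifnot(inherits(lm, "linear_model"), !is.null(lm$v_weighted))
  score <- apply(lm$v_weighted, 2, count_sign_changes)
  tv <- apply(lm$v_weighted, 2, function(v) sum(abs(diff(v))))
  ord <- order(score, tv)
  lm$roughness <- score
  lm$roughness_order <- ord
  lm$roughness_rank <- order(ord)
  lm
}

count_sign_changes <- function(v) {
  s <- sign(v)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' Sensitivity of the fixpoint to the dilution factor
#'
#' Solves `(I - J) dn = r` for the derivative of the fixpoint abundances
#' with respect to `alpha`. Finite whenever all eigenvalues are below 1;
#' a numerically singular system is reported as marginal stability.
#'
#' @param lm a `linear_model` from [compute_jacobian()].
#' @return numeric vector `dn/dalpha`, one entry per species.
#' @export
alpha_sensitivity <- function(lm) {
  stopifnot(inherits(lm, "linear_model"))
  A <- diag(nrow(lm$J)) - lm$J
  out <- tryCatch(solve(A, lm$r),
                  error = function(e)
                    stop("(I - J) is numerically singular: marginal stability"))
  drop(out)
}

#' Full linear analysis pipeline
#'
#' Convenience wrapper running [compute_jacobian()], [eigen_analysis()],
#' [weighted_eigenvectors()], [roughness_order()] and (when `sigma_alpha`
#' is supplied) [amplitude_spectrum()].
#'
#' @inheritParams compute_jacobian
#' @param sigma_alpha optional noise standard deviation for the amplitude
#'   spectrum.
#' @return a fully populated `linear_model`.
#' @export
linearize <- function(fp, sigma_alpha = NULL, tail_epsilon = fp$tail_epsilon) {
  lm <- compute_jacobian(fp, tail_epsilon = tail_epsilon)
  lm <- eigen_analysis(lm)
  lm <- weighted_eigenvectors(lm)
  lm <- roughness_order(lm)
  if (!is.null(sigma_alpha)) lm <- amplitude_spectrum(lm, sigma_alpha)
  lm
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("linear model: %d modes%s\n", nrow(x$J),
              if (!is.null(x$stable))
                sprintf(", %s", if (x$stable) "stable" else "UNSTABLE")
              else ""))
  if (!is.null(x$lambdas)) {
    df <- data.frame(lambda = x$lambdas, tau = x$tau)
    if (!is.null(x$amp2)) { df$gamma <- x$gamma; df$amp2 <- x$amp2 }
    if (!is.null(x$roughness_rank)) df$roughness_rank <- x$roughness_rank
    print(utils::head(df, 15))
  }
  invisible(x)
}

#' Export per-mode summaries as a data frame
#'
#' @param lm a populated `linear_model`.
#' @return data frame with one row per mode: `lambda`, `eps`, `tau`, `p`,
#'   and when available `gamma`, `amp2` and `roughness_rank`.
#' @export
mode_table <- function(lm) {
  stopifnot(inherits(lm, "linear_model"), !is.null(lm$lambdas))
  df <- data.frame(mode = seq_along(lm$lambdas), lambda = lm$lambdas,
                   eps = lm$eps, tau = lm$tau, p = lm$p)
  if (!is.null(lm$amp2)) { df$gamma <- lm$gamma; df$amp2 <- lm$amp2 }
  if (!is.null(lm$roughness_rank)) df$roughness_rank <- lm$roughness_rank
  df
}
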