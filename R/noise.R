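#' Log-normal environmental noise in the dilution factor
#'
#' Environmental noise enters through the dispersal dilution factor
#' `alpha`, drawn independently every cycle (white noise) from a log-normal
#' distribution with log-mean `theta` and log-standard-deviation `omega`.
#' The model is parameterised by the coefficient of variation
#' `cv = sigma_alpha / <alpha>`, from which `omega = sqrt(log(1 + cv^2))`.
#'
#' `theta` is anchored at `log(alpha0)` so the fixpoint dilution is the
#' distribution's median: the long-term dilution rate is controlled by the
#' expectation of `log(alpha)`, which this choice keeps independent of the
#' noise intensity (increasing `omega` does not bias competition toward
#' fast or efficient species).
#'
#' @param cv coefficient of variation of `alpha` (>= 0).
#' @param alpha0 reference (fixpoint) dilution factor.
#' @return object of class `noise_model` with fields `cv`, `alpha0`,
#'   `theta`, `omega`, `mean_alpha = exp(theta + omega^2/2)` and
#'   `sigma_alpha = cv * mean_alpha`.
#' @export
noise_model <- function(cv, alpha0) {
  if (cv < 0 || !is.finite(cv)) stop("'cv' must be a non-negative number")
  if (alpha0 <= 0) stop("'alpha0' must be positive")
  omega <- sqrt(log(1 + cv^2))
  theta <- log(alpha0)
  mean_alpha <- exp(theta + omega^2 / 2)
  structure(list(cv = cv, alpha0 = alpha0, theta = theta, omega = omega,
                 mean_alpha = mean_alpha, sigma_alpha = cv * mean_alpha),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("log-normal dilution noise: alpha0 = %g, cv = %g (omega = %g)\n",
              x$alpha0, x$cv, x$omega))
  invisible(x)
}

#' Draw a reproducible series of dilution factors
#'
#' Independent log-normal draws `alpha_t = exp(theta + omega * xi_t)` with
#' standard normal `xi_t`. With `omega = 0` the series is constant at
#' `alpha0`. The same `seed` always reproduces the same series, which is
#' how the exact same noise is shared across clamped-species
#' counterfactual runs.
#'
#' @param nm a [noise_model()].
#' @param cycles number of draws.
#' @param seed optional integer seed (set before drawing).
#' @return numeric vector of length `cycles`.
#' @export
draw_alphas <- function(nm, cycles, seed = NULL) {
  stopifnot(inherits(nm, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  if (nm$omega == 0) return(rep(nm$alpha0, cycles))
  exp(nm$theta + nm$omega * rnorm(cycles))
}
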