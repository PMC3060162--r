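#' Pairwise correlation versus phenotypic distance
#'
#' Computes Pearson correlations between species abundance series and
#' arranges them against the phenotypic distance `|z_k - z_l|` with
#' `z = log(mu)`. Three clamp regimes are supported:
#' * `"full"`: one trace with every species fluctuating; correlations of
#'   all within-trace pairs.
#' * `"single"`: `N` traces, each with a single free species and the same
#'   noise series; correlations are computed across traces (pure
#'   Moran-effect limit).
#' * `"pair"`: one trace per species pair, each with two free species and
#'   the same noise series; the correlation of the two free species within
#'   each trace (noise plus pairwise interaction).
#'
#' Correlations are computed on log abundances by default (abundances span
#' orders of magnitude, where Pearson on logs is stabler); set
#' `log = FALSE` for the raw scale. The first `burn_in` cycles are
#' discarded.
#'
#' @param traces a `sim_trace` (regime `"full"`) or list of `sim_trace`
#'   objects (other regimes).
#' @param regime clamp regime.
#' @param log correlate log abundances?
#' @param burn_in cycles discarded from the start of each trace.
#' @return An object of class `correlation_curve`: `pairs` (data frame
#'   `k`, `l`, `distance`, `correlation`), `binned` (mean correlation per
#'   distinct distance) and `regime`.
#' @export
correlation_vs_distance <- function(traces, regime = c("full", "single", "pair"),
                                    log = TRUE, burn_in = 1000L) {
  regime <- match.arg(regime)
  if (inherits(traces, "sim_trace")) traces <- list(traces)
  stopifnot(all(vapply(traces, inherits, TRUE, "sim_trace")))
  z <- traces[[1]]$z
  N <- length(z)
  take <- function(tr) {
    x <- tr$abundances
    if (burn_in >= nrow(x)) stop("'burn_in' leaves no cycles")
    x <- x[(burn_in + 1L):nrow(x), , drop = FALSE]
    if (log) base::log(x) else x
  }
  pairs <- switch(regime,
    full = {
      if (length(traces) != 1L) stop("regime 'full' takes a single trace")
      X <- take(traces[[1]])
      cm <- cor(X)
      idx <- which(upper.tri(cm), arr.ind = TRUE)
      data.frame(k = idx[, 1], l = idx[, 2],
                 correlation = cm[idx])
    },
    single = {
      if (length(traces) != N)
        stop("regime 'single' needs one trace per species")
      check_shared_noise(traces)
      free <- vapply(traces, free_species, 0L, expect = 1L)
      if (!setequal(free, seq_len(N)))
        stop("regime 'single' needs each species free in exactly one trace")
      traces <- traces[order(free)]
      X <- vapply(seq_len(N),
                  function(k) take(traces[[k]])[, k], numeric(
                    nrow(traces[[1]]$abundances) - burn_in))
      cm <- cor(X)
      idx <- which(upper.tri(cm), arr.ind = TRUE)
      data.frame(k = idx[, 1], l = idx[, 2], correlation = cm[idx])
    },
    pair = {
      check_shared_noise(traces)
      rows <- lapply(traces, function(tr) {
        fr <- which(!tr$clamp)
        if (length(fr) != 2L) stop("regime 'pair' needs two free species per trace")
        X <- take(tr)
        data.frame(k = fr[1], l = fr[2],
                   correlation = cor(X[, fr[1]], X[, fr[2]]))
      })
      do.call(rbind, rows)
    })
  pairs$distance <- abs(z[pairs$k] - z[pairs$l])
  pairs <- pairs[, c("k", "l", "distance", "correlation")]
  key <- signif(pairs$distance, 8)
  binned <- aggregate(pairs$correlation, by = list(distance = key), FUN = mean)
  names(binned)[2] <- "correlation"
  binned$n_pairs <- as.vector(table(key)[as.character(binned$distance)])
  binned <- binned[order(binned$distance), ]
  structure(list(pairs = pairs, binned = binned, regime = regime, log = log),
            class = "correlation_curve")
}

free_species <- function(tr, expect) {
  fr <- which(!tr$clamp)
  if (length(fr) != expect)
    stop(sprintf("trace has %d free species, expected %d", length(fr), expect))
  fr
}

check_shared_noise <- function(traces) {
  a0 <- traces[[1]]$alphas
  same <- vapply(traces, function(tr) identical(tr$alphas, a0), TRUE)
  if (!all(same))
    stop("traces in a shared-noise regime must use the identical alpha series")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("correlation curve (%s regime, %s scale): %d pairs, %d distances\n",
              x$regime, if (x$log) "log" else "raw", nrow(x$pairs),
              nrow(x$binned)))
  invisible(x)
}

#' Number of sign alternations along a correlation curve
#'
#' Counts sign changes of the binned mean correlation as a function of
#' distance (zeros are skipped). The Moran-limit curve has 0, the
#' pairwise-compensatory curve 1, and the full many-species curve several.
#'
#' @param curve a [correlation_vs_distance()] result.
#' @return integer count.
#' @export
curve_sign_changes <- function(curve) {
  stopifnot(inherits(curve, "correlation_curve"))
  count_sign_changes(curve$binned$correlation)
}

#' Abundance profiles over phenotype space
#'
#' Extracts abundance snapshots over the phenotype axis `z = log(mu)` at
#' selected cycles, together with the time-averaged profile over a window.
#'
#' @param trace a `sim_trace`.
#' @param times cycles at which to take snapshots.
#' @param window cycles used for the time average (default: everything
#'   after `burn_in`).
#' @param burn_in default burn-in for the averaging window.
#' @return list with `z`, `snapshots` (length(times) x N matrix),
#'   `average` (time-averaged profile) and `n_star`.
#' @export
profile_snapshots <- function(trace, times, window = NULL, burn_in = 1000L) {
  stopifnot(inherits(trace, "sim_trace"))
  cycles <- nrow(trace$abundances)
  if (any(times < 1 | times > cycles)) stop("'times' outside the trace range")
  if (is.null(window)) {
    if (burn_in >= cycles) stop("'burn_in' leaves no cycles")
    window <- (burn_in + 1L):cycles
  }
  list(z = trace$z,
       snapshots = trace$abundances[times, , drop = FALSE],
       average = colMeans(trace$abundances[window, , drop = FALSE]),
       n_star = trace$n_star)
}

#' Empirical eigenmode amplitudes from a simulated trace
#'
#' Projects the simulated deviations from the fixpoint onto the eigenbasis,
#' `q(t) = S^{-1} (n(t) - n_star)` (or the relative deviation
#' `(n - n_star)/n_star` when `relative = TRUE`), and returns the time
#' average of `q_k^2` per mode for comparison with the stationary linear
#' prediction. Modes whose relaxation time exceeds the usable trace length
#' are flagged as not converged.
#'
#' @param trace a `sim_trace` from the community that produced `lm`.
#' @param lm a `linear_model` after [eigen_analysis()] (and, for predicted
#'   amplitudes, [amplitude_spectrum()]).
#' @param burn_in cycles discarded from the start.
#' @param relative use relative deviations from the fixpoint?
#' @return data frame with one row per mode: `mode`, `lambda`, `tau`,
#'   `amp2_emp`, `amp2_pred` (if available) and `valid` (relaxation time
#'   shorter than the usable trace).
#' @export
empirical_mode_amplitudes <- function(trace, lm, burn_in = 1000L,
                                      relative = FALSE) {
  stopifnot(inherits(trace, "sim_trace"), inherits(lm, "linear_model"),
            !is.null(lm$S))
  cycles <- nrow(trace$abundances)
  if (burn_in >= cycles) stop("'burn_in' leaves no cycles")
  dn <- sweep(trace$abundances[(burn_in + 1L):cycles, , drop = FALSE], 2,
              trace$n_star)
  if (relative) dn <- sweep(dn, 2, trace$n_star, "/")
  q <- t(solve(lm$S, t(dn)))
  out <- data.frame(mode = seq_along(lm$lambdas), lambda = lm$lambdas,
                    tau = lm$tau, amp2_emp = colMeans(q^2))
  if (!is.null(lm$amp2)) out$amp2_pred <- lm$amp2
  out$valid <- is.finite(out$tau) & out$tau < (cycles - burn_in)
  out
}
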