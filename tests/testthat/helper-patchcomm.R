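# Shared fixtures and independent oracles.
#
# Fixpoint solves are cached per test run: solved lazily on first use and
# reused by every file.

fixture_env <- new.env(parent = emptyenv())

fixture_fp <- function(N, tail_epsilon = 1e-13) {
  key <- sprintf("fp%d_%g", N, tail_epsilon)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- solve_efficiencies(100 / N, mu_grid(N), 1e-3,
                                             tail_epsilon = tail_epsilon)
  fixture_env[[key]]
}

fixture_lm <- function(N) {
  key <- sprintf("lm%d", N)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- linearize(fixture_fp(N))
  fixture_env[[key]]
}

# independent oracle for the growth-time equation: plain bisection on the
# residual, bracketed by [0, slowest single-species depletion time]
bisect_growth_time <- function(m, mu, Y, R = 1, tol = 1e-13) {
  g <- function(T) sum(m * expm1(mu * T) / Y) - R
  pres <- m > 0
  hi <- max(log1p(R * Y[pres] / m[pres]) / mu[pres]) * (1 + 1e-9) + 1e-12
  lo <- 0
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# random small configurations for property-style loops
random_config <- function() {
  N <- sample(2:5, 1)
  list(N = N,
       mu = sort(runif(N, 0.05, 1)),
       Y = runif(N, 50, 2000),
       m = rpois(N, 2) + as.integer(seq_len(N) == sample(N, 1)))
}

# assemble a minimal sim_trace by hand (for statistics tests with
# constructed inputs)
fake_trace <- function(abund, n_star, z = seq_len(ncol(abund)),
                       alphas = rep(1e-3, nrow(abund)),
                       clamp = rep(FALSE, ncol(abund))) {
  structure(list(abundances = abund, alphas = alphas, clamp = clamp,
                 n_star = n_star, z = z, community = NULL,
                 metadata = list(seed = NA, cycles = nrow(abund),
                                 tail_epsilon = 1e-7, adaptive = TRUE,
                                 static_M = -1L, M = integer(0),
                                 mass = numeric(0), mc = logical(0),
                                 mc_fallbacks = 0L)),
            class = "sim_trace")
}
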