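test_that("single-species response matches the analytic derivative", {
  fp <- solve_efficiencies(100, mu = 0.2, alpha0 = 1e-3)
  lm <- compute_jacobian(fp, tail_epsilon = 1e-12)
  Y <- fp$community$Y
  n <- fp$n_star
  a <- fp$alpha0
  expect_equal(as.numeric(lm$J), a + a * Y * exp(-a * n), tolerance = 1e-9)
  expect_equal(as.numeric(lm$r), n + Y * n * exp(-a * n), tolerance = 1e-8)
})

test_that("analytic J and r agree with central finite differences", {
  fp <- solve_efficiencies(100 / 3, mu_grid(3), 1e-3, tail_epsilon = 1e-13)
  lm <- compute_jacobian(fp)
  pol <- truncation_policy(1e-13)
  tab <- seeding_table(fp$community, lm$M + 1L)
  h <- 1e-6 * fp$n_star[1]
  Jfd <- matrix(0, 3, 3)
  for (l in 1:3) {
    np <- fp$n_star; np[l] <- np[l] + h
    nn <- fp$n_star; nn[l] <- nn[l] - h
    Jfd[, l] <- (step_map(np, fp$alpha0, policy = pol, table = tab) -
                   step_map(nn, fp$alpha0, policy = pol, table = tab)) / (2 * h)
  }
  expect_lt(max(abs(lm$J - Jfd)) / max(abs(lm$J)), 1e-6)
  ha <- 1e-9
  rfd <- (step_map(fp$n_star, fp$alpha0 + ha, policy = pol, table = tab) -
            step_map(fp$n_star, fp$alpha0 - ha, policy = pol, table = tab)) /
    (2 * ha)
  expect_lt(max(abs(lm$r - rfd)) / max(abs(lm$r)), 1e-6)
})

test_that("eigen decomposition satisfies the eigen identity to high precision", {
  lm <- fixture_lm(6)
  for (k in 1:6) {
    v <- lm$S[, k]
    expect_lt(sqrt(sum((lm$J %*% v - lm$lambdas[k] * v)^2)), 1e-10)
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
  }
  expect_true(all(diff(lm$lambdas) < 0))          # sorted, slowest first
})

test_that("relaxation times follow from the eigenvalues", {
  lm <- structure(list(J = diag(c(exp(-1), 0.999)),
                       r = c(1, 1), Delta_J = diag(c(exp(-1), 0.999)) - diag(2)),
                  class = "linear_model")
  lm <- eigen_analysis(lm)
  expect_equal(lm$tau[2], 1, tolerance = 1e-12)            # lambda = 1/e
  expect_equal(lm$tau[1], 1 / (1 - 0.999), tolerance = 1e-3)  # small-eps limit
})

test_that("stationary amplitudes scale as white-noise AR(1) variances", {
  lm <- structure(list(J = diag(c(0.0, 0.5)), r = c(2, 3),
                       Delta_J = diag(c(0, 0.5)) - diag(2)),
                  class = "linear_model")
  lm <- eigen_analysis(lm)
  lm <- amplitude_spectrum(lm, sigma_alpha = 0.1)
  # lambda = 0: white-noise pass-through p^2 sigma^2
  i0 <- which(lm$lambdas == 0)
  expect_equal(lm$amp2[i0], lm$p[i0]^2 * 0.01, tolerance = 1e-12)
  # doubling sigma multiplies every amplitude by exactly 4
  lm2 <- amplitude_spectrum(lm, sigma_alpha = 0.2)
  expect_equal(lm2$amp2, 4 * lm$amp2, tolerance = 1e-12)
  # the factorization amp2 = gamma * tau holds for every relaxing mode
  # (at lambda = 0 relaxation is instantaneous: tau = 0, gamma undefined)
  pos <- lm$tau > 0
  expect_equal((lm$gamma * lm$tau)[pos], lm$amp2[pos], tolerance = 1e-12)
  expect_identical(lm$tau[!pos], 0)
})

test_that("interaction weighting rescales without reordering for uniform rows", {
  S <- cbind(c(1, 1, 1) / sqrt(3), c(1, -1, 1) / sqrt(3), c(1, -1, -1) / sqrt(3))
  DJ <- matrix(-0.2, 3, 3); diag(DJ) <- -0.05
  lm <- structure(list(J = DJ + diag(3), Delta_J = DJ, S = S,
                       lambdas = c(0.9, 0.8, 0.7), r = c(1, 1, 1)),
                  class = "linear_model")
  lm <- weighted_eigenvectors(lm)
  expect_equal(lm$v_weighted, 0.2 * S, tolerance = 1e-12)
})

test_that("roughness ranks smooth before jagged and ignores sign flips", {
  S <- cbind(rep(0.5, 4), c(0.5, 0.5, -0.5, -0.5), c(0.5, -0.5, 0.5, -0.5))
  DJ <- matrix(-0.1, 4, 4); diag(DJ) <- -0.02
  lm <- structure(list(J = DJ + diag(4), Delta_J = DJ, S = S,
                       lambdas = c(0.9, 0.8, 0.7), r = rep(1, 4)),
                  class = "linear_model")
  lm <- weighted_eigenvectors(lm)
  lm <- roughness_order(lm)
  expect_identical(lm$roughness_order, 1:3)
  expect_identical(lm$roughness, c(0L, 1L, 3L))
  lm2 <- lm
  lm2$S[, 2] <- -lm2$S[, 2]
  lm2 <- roughness_order(weighted_eigenvectors(lm2))
  expect_identical(lm2$roughness_order, lm$roughness_order)
})

test_that("alpha sensitivity solves the scalar case and the re-solve oracle", {
  lm1 <- structure(list(J = matrix(0.6), r = 5), class = "linear_model")
  expect_equal(alpha_sensitivity(lm1), 5 / 0.4, tolerance = 1e-12)

  fp <- solve_efficiencies(100 / 3, mu_grid(3), 1e-3, tail_epsilon = 1e-13)
  lm <- compute_jacobian(fp)
  dn <- alpha_sensitivity(lm)
  # oracle: re-solve the fixpoint at alpha0 +/- delta by iterating the map
  cache <- seeding_cache(fp$community, lm$M + 2L)
  iterfix <- function(a) {
    tr <- simulate_trace(fp, cycles = 60000, alphas = rep(a, 60000),
                         policy = truncation_policy(1e-13), cache = cache)
    tr$abundances[60000, ]
  }
  delta <- 1e-6
  fd <- (iterfix(fp$alpha0 + delta) - iterfix(fp$alpha0 - delta)) / (2 * delta)
  expect_lt(max(abs(dn - fd) / abs(dn)), 0.01)
})
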