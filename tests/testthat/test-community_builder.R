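test_that("single-species efficiency inversion matches the closed form", {
  fp <- solve_efficiencies(100, mu = 0.2, alpha0 = 1e-3)
  Y_expected <- 100 * (1 - 1e-3) / (1 - exp(-1e-3 * 100))
  expect_equal(fp$community$Y, Y_expected, tolerance = 1e-9)
  expect_true(fp$converged)
})

test_that("the solved community shows the growth-rate/efficiency trade-off", {
  fp <- fixture_fp(6)
  expect_true(fp$converged)
  expect_lt(fp$residual, 1e-9 * max(fp$n_star))
  expect_true(all(diff(fp$community$Y) < 0))       # Y decreases with mu
  expect_true(all(fp$community$Y > 0))
})

test_that("species labelling is canonical: communities sort by growth rate", {
  perm <- c(3, 1, 2)
  a <- community(c(0.1, 0.2, 0.3), c(30, 20, 10))
  b <- community(c(0.1, 0.2, 0.3)[perm], c(30, 20, 10)[perm])
  expect_identical(a$mu, b$mu)
  expect_identical(a$Y, b$Y)
})

test_that("perturbing a solved efficiency breaks the equal-abundance fixpoint", {
  fp <- fixture_fp(6)
  comm2 <- community(fp$community$mu, fp$community$Y * c(1, 1.1, 1, 1, 1, 1))
  out <- step_map(fp$n_star, fp$alpha0, comm2, truncation_policy(1e-10))
  expect_gt(max(abs(out - fp$n_star)), 1e-3)
  expect_gt(out[2], fp$n_star[2])                  # the boosted species gains
})

test_that("a super-species community drifts toward exclusion", {
  # constant efficiency with increasing growth rate removes the trade-off:
  # iterating from equal abundances, the fastest species' share rises
  comm <- community(c(0.1, 0.2, 0.3), c(800, 800, 800))
  n <- rep(30, 3)
  shares <- numeric(30)
  tab <- seeding_table(comm, 12L)
  for (i in 1:30) {
    n <- as.numeric(step_map(n, 1e-3, policy = truncation_policy(1e-9),
                             table = tab))
    shares[i] <- n[3] / sum(n)
  }
  expect_true(all(diff(shares) > 0))
})

test_that("dominance fixpoint: scalar analysis and hierarchy structure", {
  # N = 1: positive root exists iff s*Y*alpha > 1, verified by bisection
  c1 <- community(0.2, 40)
  alpha <- 0.01
  expect_identical(as.numeric(dominance_fixpoint(c1, alpha, s = 2)), 0)
  expect_true(attr(dominance_fixpoint(c1, alpha, s = 2), "excluded"))
  n1 <- dominance_fixpoint(c1, alpha, s = 10)       # s*Y*alpha = 4 > 1
  g <- function(x) 10 * 40 * (1 - exp(-alpha * x)) - x
  lo <- 1; hi <- 400
  for (i in 1:60) { mid <- (lo + hi) / 2; if (g(mid) > 0) lo <- mid else hi <- mid }
  expect_equal(as.numeric(n1), (lo + hi) / 2, tolerance = 1e-6)
  # the top species' level does not involve the other species' parameters
  c3 <- community(c(0.1, 0.2, 0.3), c(30, 20, 10))
  full <- dominance_fixpoint(c3, 0.01, s = 50)
  top_alone <- dominance_fixpoint(community(0.3, 10), 0.01, s = 50)
  expect_equal(full[3], as.numeric(top_alone), tolerance = 1e-10)
})

test_that("dominance approximation converges to the full fixpoint as s grows", {
  # fixed seeding intensity (alpha = 0.8/s) isolates the large-resource
  # error; efficiencies spread widely enough that all three levels keep a
  # positive root at every s
  c3 <- community(c(0.1, 0.2, 0.3), c(400, 10, 2))
  rel_err <- vapply(c(1e2, 1e4, 1e6), function(s) {
    a <- 0.8 / s
    dom <- dominance_fixpoint(c3, a, s = s)
    expect_false(any(attr(dom, "excluded")))
    c3s <- community(c(0.1, 0.2, 0.3), c(400, 10, 2), s = s)
    n <- as.numeric(dom) * 1.1
    tab <- seeding_table(c3s, derive_truncation(sum(dom) * 1.5, a, 1e-10) + 10L)
    for (i in 1:4000)
      n <- as.numeric(step_map(n, a, policy = truncation_policy(1e-10),
                               table = tab))
    max(abs(dom - n) / n)
  }, 0)
  expect_true(all(diff(rel_err) < 0))
})

test_that("the two-species reference pair matches its dominance limit within 5%", {
  # alpha scaled so both phenotypes survive in the complete-dominance limit
  comm <- community(c(0.25, 0.5), c(200, 125))
  alpha <- 9.6e-9
  s <- 1e6
  dom <- dominance_fixpoint(comm, alpha, s = s)
  expect_false(any(attr(dom, "excluded")))
  comms <- community(c(0.25, 0.5), c(200, 125), s = s)
  n <- as.numeric(dom) * 1.1
  tab <- seeding_table(comms, derive_truncation(sum(dom) * 1.5, alpha,
                                                1e-10) + 10L)
  for (i in 1:4000)
    n <- as.numeric(step_map(n, alpha, policy = truncation_policy(1e-10),
                             table = tab))
  expect_true(all(abs(dom - n) / n < 0.05))
})

test_that("the solved fixpoint is linearly stable with a real spectrum", {
  fp <- fixture_fp(6)
  st <- stability_check(fp)
  expect_true(st$stable)
  expect_true(all(abs(Im(st$lambdas)) < 1e-9))
  expect_true(all(Re(st$lambdas) > 0 & Re(st$lambdas) < 1))
})

test_that("a pulse in the dilution factor relaxes back toward the fixpoint", {
  fp <- fixture_fp(6)
  tr <- perturbation_experiment(fp, "alpha_pulse", magnitude = 0.3 * fp$alpha0,
                                at_cycle = 20, cycles = 400)
  dev <- abs(sweep(tr$abundances, 2, fp$n_star))
  envelope <- apply(dev, 1, max)
  expect_gt(envelope[21], 10 * envelope[10])      # the pulse displaces the system
  expect_lt(envelope[400], 0.2 * envelope[21])    # and the envelope decays
  expect_lt(max(dev[400, ]), max(dev[25, ]))
})
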