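test_that("seeding probabilities follow the Poisson product", {
  n <- rep(100 / 15, 15)
  # empty seeding: exp(-alpha * total abundance) = exp(-0.1) at the
  # canonical 15-species state
  expect_equal(seeding_probability(rep(0L, 15), n, 1e-3), exp(-0.1),
               tolerance = 1e-12)
  expect_equal(seeding_probability(c(0L, 0L), c(3, 7), 0.01),
               exp(-0.01 * 10), tolerance = 1e-12)
  expect_equal(seeding_probability(c(2L, 1L), c(3, 7), 0.01),
               dpois(2, 0.03) * dpois(1, 0.07), tolerance = 1e-12)
  expect_error(seeding_probability(c(1L, 0L), c(-1, 2), 0.01), "non-negative")
  expect_error(seeding_probability(c(1L, 0L), c(1, 2), 0), "positive")
})

test_that("enumerated probabilities plus the analytic tail sum to one", {
  n <- c(2, 5, 1)
  alpha <- 0.2
  M <- derive_truncation(n, alpha, 1e-9)
  mm <- enumerate_seedings(3, M)
  probs <- vapply(seq_len(nrow(mm)),
                  function(i) seeding_probability(mm[i, ], n, alpha), 0)
  tail <- ppois(M, alpha * sum(n), lower.tail = FALSE)
  expect_equal(sum(probs) + tail, 1, tolerance = 1e-12)
})

test_that("the truncation total matches a direct tail-summation oracle", {
  direct_M <- function(lambda, eps) {
    # brute-force: accumulate pmf terms until the remaining tail is < eps
    M <- 0
    repeat {
      tail <- 1 - sum(dpois(0:M, lambda))
      if (tail < eps) return(M)
      M <- M + 1
    }
  }
  for (lambda in c(0.1, 0.5, 2, 10)) {
    for (eps in c(1e-7, 1e-4)) {
      expect_identical(derive_truncation(lambda, 1, eps),
                       as.integer(direct_M(lambda, eps)))
    }
  }
  expect_identical(derive_truncation(0, 1, 1e-7), 0L)
})

test_that("seeding enumeration satisfies the stars-and-bars count", {
  for (N in c(2L, 4L)) for (M in c(3L, 5L)) {
    mm <- enumerate_seedings(N, M)
    expect_identical(nrow(mm), as.integer(choose(N + M, M)))
    expect_identical(anyDuplicated(mm), 0L)
    tot <- rowSums(mm)
    expect_true(all(tot <= M))
    expect_true(!is.unsorted(tot))            # grouped by total: prefix property
  }
})

test_that("the zero state is a fixed point of the update", {
  comm <- community(c(0.1, 0.3), c(1200, 800))
  out <- step_map(c(0, 0), 1e-3, comm)
  expect_true(all(out == 0))
})

test_that("single-species update matches its analytic closed form", {
  # n' = alpha n + Y (1 - exp(-alpha n)), from f(m) = m + Y for m >= 1
  for (n in c(0.1, 1, 10, 100)) {
    for (alpha in c(1e-4, 1e-3, 1e-2)) {
      comm <- community(0.3, 700)
      got <- step_map(n, alpha, comm, truncation_policy(1e-15))
      expect_equal(as.numeric(got), alpha * n + 700 * (1 - exp(-alpha * n)),
                   tolerance = 1e-10)
    }
  }
})

test_that("a solved fixpoint is invariant under the update", {
  fp <- fixture_fp(6)
  out <- step_map(fp$n_star, fp$alpha0, fp$community,
                  truncation_policy(1e-13))
  expect_lt(max(abs(out - fp$n_star)), 1e-8)
})

test_that("the truncation certificate holds and refinement is bounded by the tail", {
  comm <- community(c(0.1, 0.2, 0.3), c(1100, 900, 700))
  n <- c(30, 50, 40)
  alpha <- 5e-3
  coarse <- step_map(n, alpha, comm, truncation_policy(1e-6))
  fine <- step_map(n, alpha, comm, truncation_policy(5e-7))
  expect_gte(attr(coarse, "mass"), 1 - 1e-6)
  expect_gte(attr(fine, "mass"), 1 - 5e-7)
  # halving the tail changes the update by less than the removed mass times
  # the largest tabulated final abundance
  tab <- seeding_table(comm, attr(fine, "M"))
  expect_lt(max(abs(fine - coarse)), 1e-6 * max(tab$Fm))
})

test_that("a stale static policy errors instead of silently losing mass", {
  comm <- community(c(0.1, 0.3), c(1200, 800))
  pol <- truncation_policy(1e-7, adaptive = FALSE, static_M = 3L)
  expect_error(step_map(c(5000, 5000), 1e-3, comm, pol), "tail bound")
  # but it works where the bound holds
  ok <- step_map(c(5, 5), 1e-3, comm, pol)
  expect_true(all(is.finite(ok)))
})

test_that("the update is linear in the tabulated growth outcomes", {
  # plumbing check: with outcomes forced to a seeding-independent constant,
  # the update returns (enumerated mass) * constant
  comm <- community(c(0.1, 0.3), c(1200, 800))
  tab <- seeding_table(comm, 8L)
  tab$Fm[] <- rep(c(3, 11), each = nrow(tab$mm))
  res <- patchcomm:::step_kernel_cpp(tab$mm, tab$Fm, tab$lfac,
                                     tab$cumrows[9L], c(40, 60), 1e-2)
  expect_equal(as.numeric(res$n_next), res$mass * c(3, 11), tolerance = 1e-12)
})

test_that("step tables export with probabilities matching the enumerated mass", {
  comm <- community(c(0.1, 0.3), c(1200, 800))
  tab <- seeding_table(comm, 6L)
  df <- step_table_frame(tab, c(10, 20), 1e-2, M = 6L)
  # enumerated probability mass = Poisson cdf of the total seed count
  expect_equal(sum(df$prob), ppois(6, 1e-2 * 30), tolerance = 1e-12)
  stepped <- step_map(c(10, 20), 1e-2, comm, truncation_policy(1e-9),
                      table = tab)
  expect_equal(drop(crossprod(as.matrix(df[, c("f1", "f2")]), df$prob)),
               as.numeric(stepped), tolerance = 1e-6,
               ignore_attr = TRUE)
})
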