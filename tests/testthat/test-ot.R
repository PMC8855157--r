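test_that("exact LP transport reproduces forced and closed-form instances", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  # identity coupling when the marginals agree
  r1 <- exact_ot_lp(c(0.4, 0.6), c(0.4, 0.6), m)
  expect_equal(r1$cost, 0, tolerance = 1e-10)
  expect_equal(r1$plan, diag(c(0.4, 0.6)), tolerance = 1e-9)
  # all mass forced across
  r2 <- exact_ot_lp(c(1, 0), c(0, 1), m)
  expect_equal(r2$cost, 1)
  expect_equal(r2$plan, matrix(c(0, 0, 1, 0), 2, 2), tolerance = 1e-9)
  # partial move, cross-checked against the 2x2 closed form
  p <- c(0.3, 0.7); q <- c(0.6, 0.4)
  r3 <- exact_ot_lp(p, q, m)
  expect_equal(r3$cost, 0.3, tolerance = 1e-10)
  expect_equal(r3$cost, lp_2x2(p, q, m), tolerance = 1e-10)
})

test_that("LP matches the 1-D CDF closed form on random instances", {
  set.seed(5)
  for (n in c(4, 7, 10)) {
    m <- abs_position_cost(n)
    for (rep in 1:5) {
      p <- random_histogram(n)
      q <- random_histogram(n)
      r <- exact_ot_lp(p, q, m)
      expect_equal(r$cost, ot_1d_cost(p, q), tolerance = 1e-8)
      expect_equal(rowSums(r$plan), p, tolerance = 1e-8)
      expect_equal(colSums(r$plan), q, tolerance = 1e-8)
    }
  }
})

test_that("sinkhorn approaches the exact cost and satisfies marginals", {
  set.seed(8)
  n <- 6
  p <- random_histogram(n); q <- random_histogram(n)
  m <- random_cost(n)
  lp <- exact_ot_lp(p, q, m)
  sk <- sinkhorn_wasserstein(p, q, m, ot_config(gamma = 1e-3, max_iter = 50000))
  expect_lt(abs(sk$cost - lp$cost), 1e-2)
  expect_lt(sk$marginal_err, 1e-7)
  expect_equal(sum(sk$plan), 1, tolerance = 1e-9)
  # entropic value never undershoots the LP bound
  expect_gte(sk$cost, lp$cost - 1e-3 * 2 * log(n) - 1e-7)

  # symmetric cost: swapping arguments leaves the value unchanged
  sk_rev <- sinkhorn_wasserstein(q, p, m, ot_config(gamma = 1e-3, max_iter = 50000))
  expect_equal(sk$cost, sk_rev$cost, tolerance = 1e-6)
})

test_that("the entropic gap shrinks as gamma decreases", {
  set.seed(9)
  n <- 5
  p <- random_histogram(n); q <- random_histogram(n)
  m <- random_cost(n)
  lp <- exact_ot_lp(p, q, m)$cost
  gaps <- vapply(c(0.1, 0.01, 0.001), function(g) {
    abs(sinkhorn_wasserstein(p, q, m,
                             ot_config(gamma = g, max_iter = 50000))$cost - lp)
  }, 0)
  expect_true(all(diff(gaps) <= 1e-9))
})

test_that("large gamma drives the plan to the independent coupling", {
  set.seed(10)
  n <- 4
  p <- random_histogram(n); q <- random_histogram(n)
  m <- random_cost(n)
  sk <- sinkhorn_wasserstein(p, q, m, ot_config(gamma = 100))
  expect_lt(max(abs(sk$plan - outer(p, q))), 5e-3)
  # the deviation scales like 1/gamma
  sk10 <- sinkhorn_wasserstein(p, q, m, ot_config(gamma = 10))
  expect_lt(max(abs(sk10$plan - outer(p, q))), 5e-2)
})

test_that("zero marginal entries are supported with zero plan mass", {
  p <- c(0.5, 0.5, 0)
  q <- c(0, 0.25, 0.75)
  m <- random_cost(3)
  sk <- sinkhorn_wasserstein(p, q, m, ot_config(gamma = 0.01))
  expect_equal(rowSums(sk$plan), p, tolerance = 1e-6)
  expect_equal(colSums(sk$plan), q, tolerance = 1e-6)
  expect_true(all(sk$plan[3, ] == 0))
  expect_true(all(sk$plan[, 1] == 0))
  expect_identical(sk$potential_q[1], -Inf)
})

test_that("plan entropy follows the closed forms", {
  expect_equal(transport_entropy(matrix(c(1, 0, 0, 0), 2, 2)), 0)
  expect_equal(transport_entropy(matrix(0.25, 2, 2)), log(4))
  expect_equal(transport_entropy(diag(c(0.5, 0.5))), log(2))
  expect_error(transport_entropy(matrix(c(-0.1, 1.1, 0, 0), 2, 2)), "nonnegative")
})

test_that("the q-gradient is centred, vanishes at p = q, and matches finite differences", {
  set.seed(12)
  cfgs <- list(ot_config(gamma = 1e-2, max_iter = 500000, tol = 1e-10),
               ot_config(gamma = 1e-3, max_iter = 500000, tol = 1e-10))
  n <- 5
  m <- random_cost(n)
  p <- random_histogram(n)
  for (cfg in cfgs) {
    g0 <- wasserstein_grad_q(p, p, m, cfg)
    expect_equal(mean(g0), 0, tolerance = 1e-12)
    # q = p sits at a smoothed kink of the transport cost: the gradient is a
    # selected subgradient, small relative to the unit cost scale but not 0
    expect_lt(max(abs(g0)), 0.05)

    q <- random_histogram(n)
    g <- wasserstein_grad_q(p, q, m, cfg)
    expect_equal(mean(g), 0, tolerance = 1e-12)
    h <- 1e-5
    for (rep in 1:3) {
      d <- rnorm(n); d <- d - mean(d); d <- d / sqrt(sum(d^2))
      fd <- (sinkhorn_wasserstein(p, q + h * d, m, cfg)$cost -
             sinkhorn_wasserstein(p, q - h * d, m, cfg)$cost) / (2 * h)
      expect_equal(sum(g * d), fd, tolerance = 1e-4)
    }
  }
})

test_that("non-convergence is flagged, never silent", {
  set.seed(13)
  n <- 30
  p <- random_histogram(n); q <- random_histogram(n)
  m <- random_cost(n)
  expect_warning(
    sk <- sinkhorn_wasserstein(p, q, m, ot_config(gamma = 1e-3, max_iter = 20)),
    "did not converge")
  expect_false(sk$converged)
})
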