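test_that("negative entropy follows the closed forms", {
  expect_equal(negative_entropy(c(1, 0)), 0)
  expect_equal(negative_entropy(c(0.5, 0.5)), -log(2))
  expect_equal(negative_entropy(rep(0.25, 4)), -log(4))
  expect_lte(negative_entropy(c(0.2, 0.3, 0.5)), 0)
})

test_that("the objective decomposes into transport cost plus the entropy term", {
  set.seed(31)
  n <- 12; k <- 3
  C <- matrix(rexp(n * k), n, k,
              dimnames = list(paste0("g", 1:n), paste0("t", 1:k)))
  C <- sweep(C, 2, colSums(C), "/")
  m <- random_cost(n)
  y <- random_histogram(n)
  p <- c(0.2, 0.5, 0.3)
  for (sign_mode in c("barrier", "sparsity")) {
    cfg <- deconv_config(ot = ot_config(gamma = 1e-2, max_iter = 50000),
                         barrier_sign = sign_mode)
    obj <- deconv_objective(y, C, p, m, cfg)
    q <- as.vector(C %*% p); q <- q / sum(q)
    q <- (q + cfg$ot$epsilon_support); q <- q / sum(q)
    ys <- (y / sum(y) + cfg$ot$epsilon_support); ys <- ys / sum(ys)
    w <- sinkhorn_wasserstein(ys, q, m, cfg$ot)$cost
    s <- if (sign_mode == "barrier") 1 else -1
    expect_equal(obj, w + s * cfg$rho * sum(p * log(p)), tolerance = 1e-8)
  }
  # rho -> 0 limit: pure transport loss
  cfg0 <- deconv_config(ot = ot_config(gamma = 1e-2, max_iter = 50000),
                        rho = 1e-12)
  q <- as.vector(C %*% p); q <- q / sum(q)
  expect_equal(deconv_objective(y, C, p, m, cfg0),
               suppressWarnings(sinkhorn_wasserstein(y, q, m, cfg0$ot))$cost,
               tolerance = 1e-6)
})

test_that("an identity dictionary recovers the bulk histogram", {
  C <- diag(4)
  dimnames(C) <- list(paste0("g", 1:4), paste0("t", 1:4))
  m <- 1 - diag(4)
  y <- c(0.1, 0.2, 0.3, 0.4)
  fit <- solve_proportions_single(y, C, m, deconv_config())
  expect_lt(max(abs(fit$p - y)), 1e-2)
  expect_true(all(diff(fit$trace) <= 1e-12))
  validate_histogram(fit$p, tol = 1e-6)
})

test_that("noise-free mixtures of a well-separated dictionary are recovered", {
  set.seed(33)
  n <- 50; k <- 3
  C <- matrix(rexp(n * k), n, k,
              dimnames = list(paste0("g", 1:n), paste0("t", 1:k)))
  C <- sweep(C, 2, colSums(C), "/")
  m <- random_cost(n)
  pstar <- c(0.5, 0.3, 0.2)
  y <- as.vector(C %*% pstar)
  fit <- solve_proportions_single(y, C, m, deconv_config())
  expect_lt(max(abs(fit$p - pstar)), 0.02)
})

test_that("duplicated signature columns recover the pair's total mass", {
  set.seed(34)
  n <- 30
  base <- matrix(rexp(n * 3), n, 3)
  base <- sweep(base, 2, colSums(base), "/")
  C <- cbind(base, base[, 3])  # type 4 duplicates type 3
  dimnames(C) <- list(paste0("g", 1:n), c("t1", "t2", "t3a", "t3b"))
  m <- random_cost(n)
  pstar <- c(0.5, 0.3, 0.2, 0)   # truth puts the pair mass on one copy
  y <- as.vector(C %*% pstar)
  fit <- solve_proportions_single(y, C, m, deconv_config())
  expect_lt(abs(fit$p["t1"] - 0.5), 0.02)
  expect_lt(abs(fit$p["t2"] - 0.3), 0.02)
  expect_lt(abs(sum(fit$p[c("t3a", "t3b")]) - 0.2), 0.02)
})

test_that("multi-sample solving is a per-column map: reduction, determinism, equivariance", {
  set.seed(35)
  n <- 20; k <- 3
  C <- matrix(rexp(n * k), n, k,
              dimnames = list(paste0("g", 1:n), paste0("t", 1:k)))
  C <- sweep(C, 2, colSums(C), "/")
  m <- random_cost(n)
  P <- cbind(c(0.6, 0.3, 0.1), c(0.2, 0.2, 0.6), c(0.6, 0.3, 0.1))
  Y <- C %*% P
  colnames(Y) <- c("s1", "s2", "s3")
  cfg <- deconv_config()
  res <- solve_proportions(Y, C, m, cfg)
  expect_equal(dim(res), c(3L, 3L))
  expect_true(all(abs(colSums(res) - 1) < 1e-6))
  # m = 1 reduces to the single-sample solver
  single <- solve_proportions_single(Y[, 1], C, m, cfg)
  expect_equal(res[, "s1"], single$p)
  # identical bulk columns give identical estimates
  expect_equal(res[, "s1"], res[, "s3"], ignore_attr = TRUE)
  # permuting input columns permutes output columns identically
  res_perm <- solve_proportions(Y[, c(2, 1, 3)], C, m, cfg)
  expect_equal(res_perm[, "s2"], res[, "s2"])
  expect_identical(colnames(res_perm), c("s2", "s1", "s3"))
  # diagnostics accompany the estimate
  d <- attr(res, "diagnostics")
  expect_s3_class(d, "tbl_df")
  expect_identical(d$sample, colnames(Y))
})

test_that("gene index misalignment is rejected", {
  C <- diag(3); dimnames(C) <- list(paste0("g", 1:3), paste0("t", 1:3))
  m <- 1 - diag(4)
  expect_error(solve_proportions_single(rep(1 / 3, 3), C, m, deconv_config()),
               "misaligned")
  expect_error(deconv_objective(rep(0.25, 4), C, rep(1 / 3, 3), 1 - diag(3),
                                deconv_config()),
               "misaligned")
})

test_that("the sparsity entropy sign spreads duplicate mass less evenly", {
  # with +rho (barrier) the split between identical columns tends to even;
  # the sparsity-rewarding sign must not break total-mass recovery
  set.seed(36)
  n <- 20
  base <- matrix(rexp(n * 2), n, 2)
  base <- sweep(base, 2, colSums(base), "/")
  C <- cbind(base, base[, 2])
  dimnames(C) <- list(paste0("g", 1:n), c("t1", "t2a", "t2b"))
  m <- random_cost(n)
  y <- as.vector(C %*% c(0.6, 0.4, 0))
  fit_b <- solve_proportions_single(y, C, m, deconv_config())
  fit_l <- solve_proportions_single(y, C, m,
                                    deconv_config(barrier_sign = "sparsity"))
  expect_lt(abs(sum(fit_b$p[c("t2a", "t2b")]) - 0.4), 0.02)
  expect_lt(abs(sum(fit_l$p[c("t2a", "t2b")]) - 0.4), 0.02)
  # the barrier split is near-even between the two identical columns
  expect_lt(abs(fit_b$p["t2a"] - fit_b$p["t2b"]), 0.1)
})
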