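# Independent oracles and fixture builders used across the suite.

# Literal triple-loop evaluation of the topological-overlap dissimilarity,
# WGCNA convention: numerator sums over u not in {i, j}; connectivity
# excludes only the gene itself.
naive_disstom <- function(a) {
  n <- nrow(a)
  a0 <- a
  diag(a0) <- 0
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- a0[i, j]
      for (u in seq_len(n)) {
        if (u != i && u != j) num <- num + a0[i, u] * a0[u, j]
      }
      ki <- sum(a0[i, -i])
      kj <- sum(a0[j, -j])
      d[i, j] <- 1 - num / (min(ki, kj) + 1 - a0[i, j])
    }
  }
  d
}

# Closed-form 2x2 transport: one free variable t11 on an interval, linear
# objective, optimum at an endpoint.
lp_2x2 <- function(p, q, m) {
  lo <- max(0, p[1] + q[1] - 1)
  hi <- min(p[1], q[1])
  cost_at <- function(t11) {
    t12 <- p[1] - t11
    t21 <- q[1] - t11
    t22 <- p[2] - t21
    sum(m * matrix(c(t11, t21, t12, t22), 2, 2))
  }
  min(cost_at(lo), cost_at(hi))
}

# 1-D optimal transport with cost |i - j|: W1 equals the L1 distance of the
# CDFs. Independent closed form for testing the LP solver.
ot_1d_cost <- function(p, q) {
  n <- length(p)
  sum(abs(cumsum(p - q)[-n]))
}

abs_position_cost <- function(n) abs(outer(seq_len(n), seq_len(n), "-"))

random_histogram <- function(n) {
  x <- runif(n) + 1e-3
  x / sum(x)
}

random_cost <- function(n, rescale = TRUE) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (rescale) m <- m / max(m)
  m
}

# Exhaustive simplex grid search for ensemble weights, step 0.01 (R = 2, 3).
grid_search_weights <- function(y, fitted, step = 0.01) {
  b <- as.vector(as.matrix(y))
  A <- vapply(fitted, function(f) as.vector(as.matrix(f)), numeric(length(b)))
  R <- ncol(A)
  grid <- seq(0, 1, by = step)
  best <- NULL
  best_val <- Inf
  if (R == 2) {
    for (w1 in grid) {
      w <- c(w1, 1 - w1)
      val <- sum((b - A %*% w)^2)
      if (val < best_val) { best_val <- val; best <- w }
    }
  } else if (R == 3) {
    for (w1 in grid) for (w2 in seq(0, 1 - w1, by = step)) {
      w <- c(w1, w2, 1 - w1 - w2)
      val <- sum((b - A %*% w)^2)
      if (val < best_val) { best_val <- val; best <- w }
    }
  } else stop("grid oracle supports R = 2 or 3")
  best
}

# Small annotated count fixture: named types/individuals, deterministic.
toy_sc <- function(n_genes = 12, per_type = 4,
                   types = c("alpha", "beta"), inds = c("d1", "d2"),
                   seed = 42) {
  set.seed(seed)
  cells <- list()
  ann <- list()
  for (ind in inds) {
    for (tp in types) {
      base <- matrix(rpois(n_genes * per_type, lambda = 5 + 3 * match(tp, types)),
                     n_genes, per_type)
      cells[[paste(ind, tp)]] <- base
      ann[[paste(ind, tp)]] <- tibble::tibble(
        cell_id = sprintf("%s_%s_%d", ind, tp, seq_len(per_type)),
        cell_type = tp, individual = ind)
    }
  }
  counts <- do.call(cbind, cells)
  ann <- dplyr::bind_rows(ann)
  dimnames(counts) <- list(sprintf("g%02d", seq_len(n_genes)), ann$cell_id)
  list(counts = counts, ann = ann)
}
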