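#' Configuration for the entropic optimal transport solver
#'
#' @param gamma entropic regularisation weight (> 0); smaller values give
#'   sharper transport plans but slower Sinkhorn convergence. Default 0.001
#'   on a max-1-rescaled ground cost.
#' @param max_iter maximum Sinkhorn iterations.
#' @param tol convergence tolerance on the maximum absolute marginal
#'   violation of the plan.
#' @param epsilon_support mass added to zero histogram entries (then
#'   renormalised) before deconvolution, keeping dual potentials finite.
#' @return list of class `ot_config`.
#' @export
ot_config <- function(gamma = 0.001, max_iter = 5000, tol = 1e-7,
                      epsilon_support = 1e-9) {
  stopifnot(gamma > 0, max_iter >= 1, tol > 0, epsilon_support >= 0)
  structure(list(gamma = gamma, max_iter = max_iter, tol = tol,
                 epsilon_support = epsilon_support), class = "ot_config")
}

#' Exact optimal transport by linear programming
#'
#' Solves `min <M, T>` over the transportation polytope of `p` and `q` with
#' the simplex method. Intended as an exact oracle at small problem sizes;
#' use [sinkhorn_wasserstein()] for gene-scale problems.
#'
#' @param p,q histograms over the same index as `m` (columns of `m` for `q`).
#' @param m ground cost matrix, `length(p)` x `length(q)`.
#' @return list with `cost` (optimal transport cost) and `plan` (an optimal
#'   transport plan, rows marginalise to `p`, columns to `q`).
#' @export
exact_ot_lp <- function(p, q, m) {
  validate_histogram(p)
  validate_histogram(q)
  n <- length(p); s <- length(q)
  stopifnot(nrow(m) == n, ncol(m) == s)
  # variables T_ij, column-major; equality constraints: row sums = p,
  # column sums = q (last column constraint dropped as redundant)
  a <- as.vector(m)
  A_rows <- matrix(0, n, n * s)
  for (i in seq_len(n)) A_rows[i, i + n * (seq_len(s) - 1)] <- 1
  A_cols <- matrix(0, s - 1, n * s)
  for (j in seq_len(s - 1)) A_cols[j, (j - 1) * n + seq_len(n)] <- 1
  A3 <- rbind(A_rows, A_cols)
  b3 <- c(p, q[seq_len(s - 1)])
  sol <- boot::simplex(a = a, A3 = A3, b3 = b3, maxi = FALSE,
                       n.iter = 50 * (n + s), eps = 1e-12)
  if (sol$solved < 0) stop("transport LP did not solve")
  plan <- matrix(sol$soln, n, s)
  list(cost = sum(plan * m), plan = plan)
}

#' Entropic (Sinkhorn) Wasserstein distance, plan and dual potential
#'
#' Minimises `<M, T> - gamma * h(T)` over couplings of `p` and `q`, where
#' `h(T) = -sum T_ij log T_ij`, by stabilised Sinkhorn scaling. Returns the
#' regularised objective value at the converged plan, the plan, and the dual
#' potential for the `q` marginal (gamma times the log column scaling,
#' centred to zero mean), which is the gradient of the regularised distance
#' with respect to `q` along simplex-tangent directions.
#'
#' Zero entries of `p` or `q` are supported: the corresponding plan rows or
#' columns are zero and their potentials are `-Inf` (excluded from
#' centring).
#'
#' @param p,q histograms.
#' @param m ground cost.
#' @param cfg an [ot_config()].
#' @param warm_start optional list with potentials `f`, `g` from a previous
#'   solve on the same support (use the `raw_potentials` element of a
#'   previous result; centred potentials lose the dual gauge).
#' @param warm_tol looser marginal tolerance at which a short warm-started
#'   pass is accepted without restarting the annealing schedule; the result
#'   is still flagged unconverged if above `cfg$tol`. Default equals
#'   `cfg$tol` (no relaxation).
#' @return list with `cost` (regularised objective), `transport_cost`
#'   (`<M, T>` at the plan), `plan`, `potential_q`, `potential_p`,
#'   `iterations`, `converged`, `marginal_err`.
#' @export
sinkhorn_wasserstein <- function(p, q, m, cfg = ot_config(), warm_start = NULL,
                                 warm_tol = cfg$tol) {
  validate_histogram(p, tol = 1e-6)
  validate_histogram(q, tol = 1e-6)
  n <- length(p); s <- length(q)
  stopifnot(nrow(m) == n, ncol(m) == s)
  p <- p / sum(p); q <- q / sum(q)
  ip <- which(p > 0); iq <- which(q > 0)
  f0 <- if (!is.null(warm_start)) warm_start$f[ip] else numeric(length(ip))
  g0 <- if (!is.null(warm_start)) warm_start$g[iq] else numeric(length(iq))
  f0[!is.finite(f0)] <- 0
  g0[!is.finite(g0)] <- 0
  res <- sinkhorn_core(p[ip], q[iq], m[ip, iq, drop = FALSE], cfg$gamma,
                       as.integer(cfg$max_iter), cfg$tol, f0, g0,
                       anneal = TRUE,
                       warm_try = if (is.null(warm_start)) 0L else 150L,
                       warm_tol = warm_tol)
  if (!res$converged) {
    warning(sprintf("sinkhorn did not converge in %d iterations (marginal violation %.3g)",
                    res$iterations, res$marginal_err))
  }
  plan <- matrix(0, n, s)
  plan[ip, iq] <- res$plan
  f <- rep(-Inf, n); g <- rep(-Inf, s)
  f[ip] <- res$f; g[iq] <- res$g
  g_centered <- g - mean(g[is.finite(g)])
  f_centered <- f - mean(f[is.finite(f)])
  tc <- sum(plan * m)
  cost <- tc - cfg$gamma * transport_entropy_raw(plan)
  # dual estimate of the same value: exact at convergence, second-order
  # accurate in the potential error, and exactly the antiderivative of the
  # potentials -- the deconvolution line search relies on that consistency
  dual <- sum(res$f * p[ip]) + sum(res$g * q[iq]) -
    cfg$gamma * (sum(plan) - 1)
  list(cost = cost, dual_cost = dual, transport_cost = tc, plan = plan,
       potential_q = g_centered, potential_p = f_centered,
       raw_potentials = list(f = f, g = g),
       iterations = res$iterations, converged = res$converged,
       marginal_err = res$marginal_err)
}

transport_entropy_raw <- function(t) -sum(xlogx(as.vector(t)))

#' Entropy of a transport plan
#'
#' `h(T) = -sum T_ij log T_ij` with the `0 log 0 = 0` convention; nonnegative
#' for plans with total mass 1.
#'
#' @param t transport plan matrix (nonnegative).
#' @return scalar entropy.
#' @export
transport_entropy <- function(t) {
  stopifnot(is.matrix(t) || is.numeric(t))
  if (any(t < 0)) stop("plan entries must be nonnegative")
  transport_entropy_raw(as.matrix(t))
}

#' Gradient of the entropic Wasserstein distance in its second argument
#'
#' Returns the centred dual potential of the `q` marginal, i.e. the gradient
#' of `W_gamma(p, .)` at `q` along simplex-tangent directions.
#'
#' @inheritParams sinkhorn_wasserstein
#' @return numeric vector of length `length(q)`, mean zero over finite
#'   entries.
#' @export
wasserstein_grad_q <- function(p, q, m, cfg = ot_config(), warm_start = NULL) {
  sinkhorn_wasserstein(p, q, m, cfg, warm_start)$potential_q
}
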