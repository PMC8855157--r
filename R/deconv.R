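#' Configuration for the deconvolution solver
#'
#' @param ot an [ot_config()] for the inner Sinkhorn solves. The default
#'   caps them at 300 iterations with marginal tolerance 1e-5: the line
#'   search runs on the dual objective estimate, which is second-order
#'   accurate in the remaining potential error, so tightly converged
#'   marginals buy nothing inside the outer loop.
#' @param rho weight of the entropy term on the proportions (> 0).
#' @param barrier_sign `"barrier"` adds `+rho * <p, log p>`, an entropy
#'   barrier that keeps proportions away from the simplex boundary (the
#'   dictionary-learning convention); `"sparsity"` subtracts the term,
#'   which instead rewards sparse proportions. See the methods vignette for
#'   why the barrier form is the default.
#' @param step_size initial step of the exponentiated-gradient update;
#'   adapted by backtracking.
#' @param max_outer_iter maximum mirror-descent iterations per sample.
#' @param obj_tol relative objective-change tolerance for termination.
#' @param init `"uniform"` starts at `1/k`; `"jitter"` perturbs the uniform
#'   start with seeded multiplicative noise (multi-start use).
#' @param seed integer seed used only by `init = "jitter"`.
#' @return list of class `deconv_config`.
#' @export
deconv_config <- function(ot = ot_config(max_iter = 300, tol = 1e-5),
                          rho = 0.001,
                          barrier_sign = c("barrier", "sparsity"),
                          step_size = 5, max_outer_iter = 2000,
                          obj_tol = 1e-6, init = c("uniform", "jitter"),
                          seed = 1L) {
  barrier_sign <- match.arg(barrier_sign)
  init <- match.arg(init)
  stopifnot(inherits(ot, "ot_config"), rho > 0, step_size > 0,
            max_outer_iter >= 1, obj_tol > 0)
  structure(list(ot = ot, rho = rho, barrier_sign = barrier_sign,
                 step_size = step_size, max_outer_iter = max_outer_iter,
                 obj_tol = obj_tol, init = init, seed = as.integer(seed)),
            class = "deconv_config")
}

#' Negative entropy of a proportion vector
#'
#' `E(a) = sum_i a_i log a_i` with `0 log 0 = 0`; nonpositive on the simplex,
#' 0 at a vertex, `-log k` at the uniform vector.
#'
#' @param a proportion vector on the simplex.
#' @return scalar.
#' @export
negative_entropy <- function(a) {
  validate_histogram(a, tol = 1e-6)
  sum(xlogx(a))
}

smooth_histogram <- function(q, epsilon) {
  q <- q / sum(q)
  if (epsilon > 0) {
    q <- q + epsilon
    q <- q / sum(q)
  }
  q
}

entropy_sign <- function(cfg) if (cfg$barrier_sign == "barrier") 1 else -1

#' Deconvolution objective for one sample
#'
#' `W_gamma(y, C p)_M + s * rho * E(p)` where `s` is +1 for the barrier form
#' and -1 for the sparsity form, and `C p` is renormalised onto the
#' simplex (and epsilon-smoothed) before the transport solve.
#'
#' @param y bulk histogram.
#' @param c signature matrix (genes x cell types), gene order matching `y`.
#' @param p proportion vector over the cell types of `c`.
#' @param m ground cost over the same genes.
#' @param cfg a [deconv_config()].
#' @return scalar objective value.
#' @export
deconv_objective <- function(y, c, p, m, cfg = deconv_config()) {
  if (length(y) != nrow(c) || nrow(m) != nrow(c)) {
    stop("gene index misaligned between bulk (", length(y), "), signatures (",
         nrow(c), ") and ground cost (", nrow(m), ")")
  }
  y <- smooth_histogram(y, cfg$ot$epsilon_support)
  q <- smooth_histogram(as.vector(c %*% p), cfg$ot$epsilon_support)
  sw <- suppressWarnings(sinkhorn_wasserstein(y, q, m, cfg$ot))
  sw$cost + entropy_sign(cfg) * cfg$rho * sum(xlogx(p))
}

#' Estimate cell-type proportions for a single bulk sample
#'
#' Minimises [deconv_objective()] over the simplex by exponentiated-gradient
#' (mirror-descent) updates `p <- p * exp(-eta * g)`, renormalised, where `g`
#' chains the Sinkhorn dual potential through the signature matrix:
#' `g = C' grad_q W_gamma(y, C p) + s * rho * (log p + 1)`. The step is
#' backtracked (halved) whenever the objective would increase, so the
#' accepted objective trace is non-increasing. Inner Sinkhorn solves are
#' warm-started from the previous iteration's potentials.
#'
#' @inheritParams deconv_objective
#' @return list with `p` (named proportion vector on the simplex), `trace`
#'   (objective per accepted iteration), `iterations`, `converged`, and
#'   `sinkhorn_nonconverged` (count of inner solves that hit `max_iter`).
#' @export
solve_proportions_single <- function(y, c, m, cfg = deconv_config()) {
  k <- ncol(c)
  if (k < 2) stop("need at least 2 cell types")
  if (length(y) != nrow(c) || nrow(m) != nrow(c)) {
    stop("gene index misaligned between bulk (", length(y), "), signatures (",
         nrow(c), ") and ground cost (", nrow(m), ")")
  }
  y <- smooth_histogram(y, cfg$ot$epsilon_support)
  s <- entropy_sign(cfg)
  n_noncvg <- 0L
  ws <- NULL
  # constant-work inner budget: small gene sets get more Sinkhorn iterations
  # (and a tighter tolerance) for free -- cost per iteration scales with n^2
  ot_cfg <- cfg$ot
  ot_cfg$max_iter <- max(ot_cfg$max_iter,
                         min(50000L, ceiling(1.2e7 / length(y)^2)))
  ot_cfg$tol <- max(1e-9, min(ot_cfg$tol, ot_cfg$tol * (length(y) / 200)^2))

  evaluate <- function(p) {
    q <- smooth_histogram(as.vector(c %*% p), cfg$ot$epsilon_support)
    sw <- withCallingHandlers(
      sinkhorn_wasserstein(y, q, m, ot_cfg, warm_start = ws,
                           warm_tol = 100 * ot_cfg$tol),
      warning = function(w) {
        if (grepl("sinkhorn did not converge", conditionMessage(w))) {
          n_noncvg <<- n_noncvg + 1L
          invokeRestart("muffleWarning")
        }
      }
    )
    list(obj = sw$dual_cost + s * cfg$rho * sum(xlogx(p)), sw = sw)
  }

  p <- rep(1 / k, k)
  if (cfg$init == "jitter") {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(cfg$seed)
    p <- p * exp(0.1 * rnorm(k))
    p <- p / sum(p)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  names(p) <- colnames(c)

  ev <- evaluate(p)
  ws <- ev$sw$raw_potentials
  obj <- ev$obj
  trace <- obj
  eta <- cfg$step_size
  converged <- FALSE
  it <- 0L

  for (it in seq_len(cfg$max_outer_iter)) {
    grad_ot <- as.vector(crossprod(c, ev$sw$potential_q))
    grad_ent <- ifelse(p > 0, log(p) + 1, 0)
    g <- grad_ot + s * cfg$rho * grad_ent
    if (any(!is.finite(g))) {
      stop("non-finite gradient for cell type(s): ",
           paste(names(p)[!is.finite(g)], collapse = ", "))
    }
    g <- g - sum(g * p)  # project onto the simplex tangent (gauge only)

    accepted <- FALSE
    for (bt in seq_len(30)) {
      arg <- -eta * g
      arg <- arg - max(arg)
      p_new <- p * exp(arg)
      p_new <- p_new / sum(p_new)
      ev_new <- evaluate(p_new)
      if (is.finite(ev_new$obj) && ev_new$obj <= obj + 1e-12) {
        accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!accepted) {
      converged <- TRUE
      break
    }
    rel <- abs(obj - ev_new$obj) / max(abs(obj), 1e-12)
    p <- p_new
    ev <- ev_new
    ws <- ev$sw$raw_potentials
    obj <- ev$obj
    trace <- c(trace, obj)
    eta <- min(eta * 1.5, cfg$step_size * 10)
    if (rel < cfg$obj_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("proportion solve did not converge in ", cfg$max_outer_iter,
            " iterations")
  }
  list(p = p, trace = trace, iterations = it, converged = converged,
       sinkhorn_nonconverged = n_noncvg)
}

#' Estimate cell-type proportions for a set of bulk samples
#'
#' The objective separates across samples, so each column is solved
#' independently with [solve_proportions_single()]; column order is
#' preserved and results are deterministic for a given configuration.
#'
#' @param y bulk histograms: genes x samples matrix with columns on the
#'   simplex (see [normalize_columns()]).
#' @param c signature matrix (genes x cell types).
#' @param m ground cost over the same genes.
#' @param cfg a [deconv_config()].
#' @return cell types x samples proportion matrix (columns on the simplex)
#'   with a `diagnostics` attribute: a tibble of per-sample objective,
#'   iterations and convergence flags.
#' @export
solve_proportions <- function(y, c, m, cfg = deconv_config()) {
  if (is.list(y) && !is.matrix(y)) y <- do.call(cbind, y)
  stopifnot(is.matrix(y))
  if (is.null(colnames(y))) colnames(y) <- paste0("sample", seq_len(ncol(y)))
  fits <- lapply(seq_len(ncol(y)), function(j) {
    tryCatch(solve_proportions_single(y[, j], c, m, cfg),
             error = function(e) stop("sample '", colnames(y)[j], "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  P <- vapply(fits, `[[`, numeric(ncol(c)), "p")
  P <- matrix(P, nrow = ncol(c), dimnames = list(colnames(c), colnames(y)))
  attr(P, "diagnostics") <- tibble::tibble(
    sample = colnames(y),
    objective = vapply(fits, function(f) f$trace[length(f$trace)], 0),
    iterations = vapply(fits, `[[`, 0L, "iterations"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    sinkhorn_nonconverged = vapply(fits, `[[`, 0L, "sinkhorn_nonconverged")
  )
  P
}
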