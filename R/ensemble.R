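#' Simplex-constrained least-squares ensemble weights
#'
#' Solves `min || Y - sum_r w_r Yhat(r) ||_F^2` subject to `sum w_r = 1`,
#' `w_r >= 0`, pooling all bulk samples into one quadratic program. Solved
#' exactly: the equality-constrained KKT system is solved on every support
#' subset and the best nonnegative solution is kept, so the result is the
#' global optimum and deterministic. Rank-deficient ties are resolved toward
#' the uniform weight.
#'
#' @param y bulk matrix (genes x samples) or vector.
#' @param fitted list of predicted bulk matrices `Yhat(r)`, same shape as
#'   `y`.
#' @return named nonnegative weight vector summing to 1.
#' @export
solve_ensemble_weights <- function(y, fitted) {
  if (length(fitted) == 0) stop("no fitted bulk matrices supplied")
  b <- as.vector(as.matrix(y))
  A <- vapply(fitted, function(f) as.vector(as.matrix(f)), numeric(length(b)))
  A <- matrix(A, ncol = length(fitted))
  R <- ncol(A)
  nms <- names(fitted) %||% paste0("ref", seq_len(R))
  if (R == 1) return(setNames(1, nms))

  G <- crossprod(A)          # A'A
  h <- crossprod(A, b)[, 1]  # A'b
  uni <- rep(1 / R, R)
  # enumerate supports; R (number of reference individuals) is small

  best <- NULL
  best_val <- Inf
  for (mask in seq_len(2^R - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(R) - 1)) > 0)
    ns <- length(S)
    # KKT for min w'Gw - 2h'w s.t. sum w = 1 on support S
    K <- rbind(cbind(2 * G[S, S, drop = FALSE], rep(1, ns)), c(rep(1, ns), 0))
    rhs <- c(2 * h[S], 1)
    w_s <- tryCatch(solve(K, rhs)[seq_len(ns)], error = function(e) NULL)
    if (is.null(w_s) || any(w_s < -1e-10)) next
    w_s[w_s < 0] <- 0
    w_s <- w_s / sum(w_s)
    w <- numeric(R)
    w[S] <- w_s
    val <- sum((b - A %*% w)^2)
    better <- val < best_val - 1e-12
    # degenerate ties resolved toward the most uniform of the tied optima
    tied_more_uniform <- !is.null(best) && abs(val - best_val) <= 1e-12 &&
      sum((w - uni)^2) < sum((best - uni)^2)
    if (is.null(best) || better || tied_more_uniform) {
      best_val <- min(val, best_val)
      best <- w
    }
  }
  if (is.null(best)) stop("ensemble weight QP found no feasible solution")
  setNames(best, nms)
}

#' Ensemble deconvolution across individual references
#'
#' Runs [solve_proportions()] once per individual reference, forms each
#' individual's fitted bulk `Yhat(r) = C(r) P(r)`, solves the
#' simplex-constrained weights against the observed bulk, and combines the
#' per-individual proportion estimates on the union cell-type set (absent
#' types contribute 0), renormalising columns.
#'
#' @param y bulk histograms, genes x samples matrix.
#' @param refs named list of signature matrices, one per individual.
#' @param costs a single ground cost shared by all individuals, or a named
#'   list with one per individual (each individual's cost computed from its
#'   own cells is the recommended usage).
#' @param cfg a [deconv_config()].
#' @return object of class `ot_ensemble`: list with `weights`,
#'   `per_individual` (list of proportion matrices), `combined` (union-type
#'   proportion matrix), `fitted` (list of fitted bulks), and `residuals`
#'   (per-individual and ensemble squared fit residuals).
#' @export
ensemble_deconvolve <- function(y, refs, costs, cfg = deconv_config()) {
  stopifnot(is.matrix(y), length(refs) >= 1)
  if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
  if (is.matrix(costs)) costs <- setNames(rep(list(costs), length(refs)), names(refs))
  stopifnot(all(names(refs) %in% names(costs)))

  per_P <- list()
  fitted <- list()
  for (r in names(refs)) {
    P <- tryCatch(solve_proportions(y, refs[[r]], costs[[r]], cfg),
                  error = function(e) stop("reference '", r, "': ",
                                           conditionMessage(e), call. = FALSE))
    per_P[[r]] <- P
    fitted[[r]] <- refs[[r]] %*% P
  }
  w <- solve_ensemble_weights(y, fitted)

  types <- sort(unique(unlist(lapply(per_P, rownames))))
  expand <- function(P) {
    out <- matrix(0, length(types), ncol(P), dimnames = list(types, colnames(P)))
    out[rownames(P), ] <- P
    out
  }
  combined <- Reduce(`+`, Map(function(P, wr) expand(P) * wr, per_P, w))
  combined <- sweep(combined, 2, colSums(combined), "/")

  resid <- vapply(fitted, function(f) sum((y - f)^2), 0)
  ens_fit <- Reduce(`+`, Map(`*`, fitted, w))
  structure(list(
    weights = w,
    per_individual = per_P,
    combined = combined,
    fitted = fitted,
    residuals = tibble::tibble(
      reference = c(names(refs), ".ensemble"),
      residual = c(resid, sum((y - ens_fit)^2))
    )
  ), class = "ot_ensemble")
}
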