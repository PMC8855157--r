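#' Gene-gene ground cost from reference single-cell expression
#'
#' Computes the symmetric gene x gene dissimilarity used as the transport
#' ground cost, over cells (columns) of the reference matrix:
#' \describe{
#'   \item{euclidean}{`||x_i - x_j||_2`}
#'   \item{cosine}{`1 - cos(x_i, x_j)`}
#'   \item{correlation}{`1 - cor(x_i, x_j)` (Pearson)}
#' }
#' Genes with zero variance (correlation) or zero norm (cosine) get their
#' similarity treated as 0, i.e. cost 1 against every other gene, with a
#' warning.
#'
#' @param x genes x cells matrix, at least 2 cells.
#' @param metric one of `"euclidean"`, `"cosine"`, `"correlation"`.
#' @return symmetric nonnegative matrix with zero diagonal and attributes
#'   `metric`, `rescaled = FALSE`.
#' @seealso [tom_dissimilarity()] for the co-expression-network metric,
#'   [rescale_cost()].
#' @export
pairwise_gene_cost <- function(x, metric = c("euclidean", "cosine", "correlation")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(x), ncol(x) >= 2)
  n <- nrow(x)
  m <- switch(metric,
    euclidean = as.matrix(dist(x, method = "euclidean")),
    cosine = {
      nrm <- sqrt(rowSums(x^2))
      zero <- nrm == 0
      if (any(zero)) warning(sum(zero), " zero-norm gene(s); cosine treated as 0")
      nrm[zero] <- 1
      cosm <- (x %*% t(x)) / outer(nrm, nrm)
      cosm[zero, ] <- 0
      cosm[, zero] <- 0
      1 - cosm
    },
    correlation = {
      v <- apply(x, 1, var)
      zero <- v == 0
      if (any(zero)) warning(sum(zero), " zero-variance gene(s); correlation treated as 0")
      cm <- suppressWarnings(cor(t(x)))
      cm[zero, ] <- 0
      cm[, zero] <- 0
      1 - cm
    }
  )
  diag(m) <- 0
  m <- (m + t(m)) / 2
  m[m < 0] <- 0  # clip correlation rounding at cor ~ 1
  dimnames(m) <- list(rownames(x), rownames(x))
  attr(m, "metric") <- metric
  attr(m, "rescaled") <- FALSE
  m
}

#' Soft-thresholded (power) co-expression adjacency
#'
#' Unsigned network adjacency `a_ij = |cor(x_i, x_j)|^beta`, diagonal 1. The
#' power beta tilts the network toward scale-free topology; the customary
#' unsigned-network default is 6.
#'
#' @param x genes x cells matrix.
#' @param beta soft-threshold power (> 0).
#' @return symmetric matrix in `[0, 1]`, attribute `beta`.
#' @export
power_adjacency <- function(x, beta = 6) {
  stopifnot(is.matrix(x), ncol(x) >= 2, beta > 0)
  v <- apply(x, 1, var)
  zero <- v == 0
  if (any(zero)) warning(sum(zero), " zero-variance gene(s); adjacency set to 0")
  cm <- suppressWarnings(cor(t(x)))
  cm[zero, ] <- 0
  cm[, zero] <- 0
  a <- abs(cm)^beta
  a <- (a + t(a)) / 2
  a[a > 1] <- 1
  diag(a) <- 1
  dimnames(a) <- list(rownames(x), rownames(x))
  attr(a, "beta") <- beta
  a
}

#' Topological-overlap dissimilarity (dissTOM)
#'
#' For adjacency `a` the topological overlap of genes i and j is
#' `(sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` and the
#' dissimilarity is one minus that. Under the default WGCNA convention the
#' connectivity is `k_i = sum_{u != i} a_iu`; the `"strict"` convention also
#' removes the partner gene from the connectivity (`k_i - a_ij`), which can
#' push values outside `[0, 1]` and is provided for comparison only.
#'
#' @param a adjacency matrix from [power_adjacency()] (entries in `[0, 1]`,
#'   diagonal treated as 1).
#' @param convention `"wgcna"` (default) or `"strict"`.
#' @return symmetric dissimilarity matrix, zero diagonal; entries in `[0, 1]`
#'   under `"wgcna"`.
#' @export
tom_dissimilarity <- function(a, convention = c("wgcna", "strict")) {
  convention <- match.arg(convention)
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (any(a < 0) || any(a > 1)) stop("adjacency entries must lie in [0, 1]")
  a0 <- a
  diag(a0) <- 0
  # (a0 %*% a0)[i, j] = sum over u of a_iu a_uj excludes u = i and u = j
  # automatically because the diagonal of a0 is zero.
  num <- a0 %*% a0 + a0
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  den <- switch(convention,
    wgcna = kmin + 1 - a0,
    strict = kmin - a0 + 1 - a0
  )
  d <- 1 - num / den
  d[den == 0] <- 1  # fully disconnected pair
  diag(d) <- 0
  d <- (d + t(d)) / 2
  if (convention == "wgcna") {
    d[d < 0] <- 0
    d[d > 1] <- 1
  }
  dimnames(d) <- dimnames(a)
  attr(d, "metric") <- "dissTOM"
  attr(d, "rescaled") <- FALSE
  attr(d, "beta") <- attr(a, "beta")
  d
}

#' Rescale a ground cost to maximum entry 1
#'
#' Fixes the scale that the entropic weight gamma is relative to, so the same
#' gamma means the same amount of smoothing across metrics. Idempotent.
#'
#' @param m ground cost matrix.
#' @return rescaled matrix, attribute `rescaled = TRUE`.
#' @export
rescale_cost <- function(m) {
  validate_ground_cost(m)
  mx <- max(m)
  if (mx <= 0) stop("cannot rescale an all-zero ground cost")
  out <- m / mx
  attributes(out) <- attributes(m)
  attr(out, "rescaled") <- TRUE
  out
}

#' One-call ground cost construction
#'
#' Dispatches to [pairwise_gene_cost()] or, for `"dissTOM"`, to
#' [power_adjacency()] + [tom_dissimilarity()], then rescales to max 1 by
#' default.
#'
#' @param x genes x cells reference matrix.
#' @param metric `"dissTOM"` (default), `"euclidean"`, `"cosine"` or
#'   `"correlation"`.
#' @param beta soft-threshold power for dissTOM.
#' @param rescale rescale the result to max entry 1.
#' @return ground cost matrix.
#' @export
ground_cost <- function(x, metric = c("dissTOM", "euclidean", "cosine", "correlation"),
                        beta = 6, rescale = TRUE) {
  metric <- match.arg(metric)
  m <- if (metric == "dissTOM") {
    tom_dissimilarity(power_adjacency(x, beta = beta))
  } else {
    pairwise_gene_cost(x, metric)
  }
  if (rescale) m <- rescale_cost(m)
  m
}
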