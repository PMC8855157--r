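#' Split annotated cells evenly into reference and testing sets
#'
#' Within each individual and cell type, cells are split 50/50 by a seeded
#' draw; when the count is odd the reference set receives the extra cell. A
#' type with a single cell goes entirely to the reference set with a
#' warning. The split is disjoint and exhaustive.
#'
#' @param ann annotation tibble (`cell_id`, `cell_type`, `individual`).
#' @param seed integer seed.
#' @return list with character vectors `reference` and `testing` of cell
#'   ids.
#' @export
split_cells <- function(ann, seed = 1L) {
  validate_annotation(ann)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  ref <- character()
  test <- character()
  groups <- split(ann$cell_id, list(ann$individual, ann$cell_type), drop = TRUE)
  for (gname in sort(names(groups))) {
    ids <- groups[[gname]]
    n <- length(ids)
    if (n == 1) {
      warning("cell type group '", gname, "' has a single cell; assigned to reference")
      ref <- c(ref, ids)
      next
    }
    n_ref <- ceiling(n / 2)
    pick <- sample(ids, n_ref)
    ref <- c(ref, pick)
    test <- c(test, setdiff(ids, pick))
  }
  list(reference = ref, testing = test)
}

#' Generate pseudo-bulk mixtures from testing-set cells
#'
#' Each replicate draws `floor(fraction * N)` cells uniformly without
#' replacement from the testing pool, sums their counts per gene into one
#' bulk column, and records the realised cell-type composition of the draw
#' as the true proportion column. Replicate r uses seed `seed + r`.
#'
#' @param sc_testing genes x cells count matrix of the testing set.
#' @param ann annotation covering the testing cells.
#' @param n_replicates number of mixtures (protocol default 200).
#' @param fraction fraction of cells sampled per mixture (protocol default
#'   0.6).
#' @param seed integer base seed.
#' @return list of class `pseudobulk_set`: `mixtures` (genes x replicates
#'   integer counts), `truth` (cell types x replicates proportions),
#'   `source_individual`, `sampling_fraction`, `n_replicates`, `seed`.
#' @export
generate_pseudobulk <- function(sc_testing, ann, n_replicates = 200,
                                fraction = 0.6, seed = 1L) {
  validate_expression(sc_testing, "testing matrix")
  validate_annotation(ann)
  stopifnot(fraction > 0, fraction <= 1, n_replicates >= 1)
  ann <- ann[match(colnames(sc_testing), ann$cell_id), , drop = FALSE]
  N <- ncol(sc_testing)
  n_draw <- floor(fraction * N)
  if (n_draw < 1) stop("fraction * N < 1: nothing to sample")
  types <- sort(unique(ann$cell_type))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  mixtures <- matrix(0, nrow(sc_testing), n_replicates,
                     dimnames = list(rownames(sc_testing),
                                     paste0("mix", seq_len(n_replicates))))
  truth <- matrix(0, length(types), n_replicates,
                  dimnames = list(types, colnames(mixtures)))
  for (r in seq_len(n_replicates)) {
    set.seed(as.integer(seed) + r)
    idx <- sample.int(N, n_draw)
    mixtures[, r] <- rowSums(sc_testing[, idx, drop = FALSE])
    tab <- table(factor(ann$cell_type[idx], levels = types))
    truth[, r] <- as.numeric(tab) / n_draw
  }
  inds <- unique(ann$individual)
  structure(list(
    mixtures = mixtures, truth = truth,
    source_individual = if (length(inds) == 1) inds else "pooled",
    sampling_fraction = fraction, n_replicates = n_replicates,
    seed = as.integer(seed)
  ), class = "pseudobulk_set")
}

align_proportions <- function(truth, est) {
  types <- sort(union(rownames(truth), rownames(est)))
  pad <- function(P) {
    out <- matrix(0, length(types), ncol(P), dimnames = list(types, colnames(P)))
    out[rownames(P), ] <- P
    out
  }
  truth <- pad(truth); est <- pad(est)
  if (ncol(truth) != ncol(est)) {
    stop("proportion matrices have ", ncol(truth), " vs ", ncol(est), " samples")
  }
  list(truth = truth, est = est)
}

#' Root-mean-squared error between proportion matrices
#'
#' `sqrt(mean((P - Phat)^2))` pooled over all cell types and samples, after
#' aligning the two matrices on the union cell-type set (absent types count
#' as 0).
#'
#' @param truth,est cell types x samples proportion matrices.
#' @return scalar RMSE.
#' @export
proportion_rmse <- function(truth, est) {
  al <- align_proportions(as.matrix(truth), as.matrix(est))
  sqrt(mean((al$truth - al$est)^2))
}

#' Pearson correlation between proportion matrices
#'
#' Correlation of the flattened matrices after union-type alignment.
#' `per_sample = TRUE` instead returns the mean of per-column correlations.
#'
#' @param truth,est cell types x samples proportion matrices.
#' @param per_sample average per-sample correlations instead of flattening.
#' @return scalar correlation.
#' @export
proportion_cor <- function(truth, est, per_sample = FALSE) {
  al <- align_proportions(as.matrix(truth), as.matrix(est))
  if (per_sample) {
    return(mean(vapply(seq_len(ncol(al$truth)), function(j)
      cor(al$truth[, j], al$est[, j]), 0)))
  }
  tv <- as.vector(al$truth); ev <- as.vector(al$est)
  if (sd(tv) == 0 || sd(ev) == 0) stop("zero variance: correlation undefined")
  cor(tv, ev)
}
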