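#' Build cell-type signature matrices from annotated single cells
#'
#' For each individual (or once, pooled over all cells) the signature column
#' of a cell type is the mean of that individual's raw count vectors over
#' cells of the type, renormalised onto the simplex. Cell types with no cells
#' for an individual are simply absent from that individual's matrix.
#'
#' @param sc genes x cells count matrix (QC-passed).
#' @param ann annotation tibble covering every column of `sc`.
#' @param by_individual build one matrix per individual (`TRUE`, default) or a
#'   single pooled matrix.
#' @param cell_normalize normalise each cell to the simplex before averaging,
#'   instead of averaging raw counts (off by default).
#' @return named list of signature matrices (genes x cell types, columns on
#'   the simplex, sorted cell-type order), each carrying an `individual`
#'   attribute; the pooled matrix is named `"pooled"`.
#' @export
build_signatures <- function(sc, ann, by_individual = TRUE,
                             cell_normalize = FALSE) {
  validate_expression(sc, "single-cell matrix")
  validate_annotation(ann)
  ann <- ann[match(colnames(sc), ann$cell_id), , drop = FALSE]
  if (anyNA(ann$cell_id)) stop("every cell must be annotated")
  if (cell_normalize) sc <- normalize_columns(sc)

  groups <- if (by_individual) split(seq_len(ncol(sc)), ann$individual) else
    list(pooled = seq_len(ncol(sc)))
  out <- list()
  for (ind in names(groups)) {
    idx <- groups[[ind]]
    types <- sort(unique(ann$cell_type[idx]))
    if (length(types) < 1) {
      warning("individual ", ind, " has no annotated cells; skipped")
      next
    }
    cols <- vapply(types, function(tp) {
      rowMeans(sc[, idx[ann$cell_type[idx] == tp], drop = FALSE])
    }, numeric(nrow(sc)))
    sig <- normalize_columns(cols)
    rownames(sig) <- rownames(sc)
    attr(sig, "individual") <- ind
    out[[ind]] <- sig
  }
  if (length(out) == 0) stop("no individual yielded a signature matrix")
  out
}

#' Impute a missing cell type into a signature matrix from other individuals
#'
#' The imputed column is the entrywise mean of the donors' columns for that
#' type, renormalised; pre-existing columns are untouched. Columns of the
#' result are in sorted cell-type order.
#'
#' @param target signature matrix lacking the type.
#' @param donors list of signature matrices from other individuals.
#' @param missing cell-type id to impute.
#' @return signature matrix including the imputed column. If `target` already
#'   has the type it is returned unchanged with attribute `imputed = FALSE`.
#' @export
impute_missing_celltype <- function(target, donors, missing) {
  stopifnot(is.matrix(target), length(missing) == 1)
  if (missing %in% colnames(target)) {
    attr(target, "imputed") <- FALSE
    return(target)
  }
  have <- Filter(function(d) missing %in% colnames(d), donors)
  if (length(have) == 0) stop("no donor reference contains cell type '", missing, "'")
  donor_cols <- vapply(have, function(d) d[rownames(target), missing],
                       numeric(nrow(target)))
  col <- rowMeans(as.matrix(donor_cols))
  col <- col / sum(col)
  out <- cbind(target, col)
  colnames(out) <- c(colnames(target), missing)
  out <- out[, sort(colnames(out)), drop = FALSE]
  attr(out, "individual") <- attr(target, "individual")
  attr(out, "imputed") <- TRUE
  out
}

#' Drop the rarest cell types from a signature matrix
#'
#' Removes the `n_remove` types with the smallest cell counts for the
#' matrix's individual (ties broken lexicographically by type id). This
#' reproduces the missing-cell-type experiment in which reference types are
#' progressively removed in ascending order of abundance.
#'
#' @param sig signature matrix with an `individual` attribute.
#' @param ann annotation tibble used to count cells per type.
#' @param n_remove number of types to drop; must be `< ncol(sig)`.
#' @return signature matrix without the dropped columns.
#' @export
remove_celltypes_ascending <- function(sig, ann, n_remove) {
  stopifnot(is.matrix(sig))
  if (n_remove >= ncol(sig)) {
    stop("n_remove (", n_remove, ") must be smaller than the number of cell types (",
         ncol(sig), ")")
  }
  if (n_remove == 0) return(sig)
  ind <- attr(sig, "individual")
  sub <- if (!is.null(ind) && ind != "pooled") ann[ann$individual == ind, ] else ann
  counts <- table(sub$cell_type)[colnames(sig)]
  counts[is.na(counts)] <- 0
  ord <- order(as.numeric(counts), colnames(sig))  # ascending count, lexicographic ties
  drop <- colnames(sig)[ord[seq_len(n_remove)]]
  out <- sig[, setdiff(colnames(sig), drop), drop = FALSE]
  attr(out, "individual") <- ind
  out
}
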