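#' Quality-control rules for single-cell reference data
#'
#' @param min_frac minimum fraction of cells in which a gene must have a count
#'   greater than 1 to be kept (closed bound, i.e. `>=`).
#' @param min_cells minimum number of cells a cell type must retain.
#' @param mad_factor number of median absolute deviations (about the mean
#'   library size) beyond which a cell is dropped.
#' @param per_individual compute the library-size filter within each
#'   individual rather than pooled over all cells.
#' @return list of thresholds, class `qc_rules`.
#' @export
qc_rules <- function(min_frac = 0.05, min_cells = 50, mad_factor = 3,
                     per_individual = FALSE) {
  stopifnot(min_frac >= 0, min_frac <= 1, min_cells >= 1, mad_factor > 0)
  structure(list(min_frac = min_frac, min_cells = min_cells,
                 mad_factor = mad_factor, per_individual = per_individual),
            class = "qc_rules")
}

#' Apply quality control to an annotated single-cell matrix
#'
#' Four filters are applied in a fixed order:
#' \enumerate{
#'   \item drop genes whose row is all zero or has zero variance;
#'   \item drop cells whose library size L satisfies
#'     `|L - mean(L)| > mad_factor * median(|L - mean(L)|)`;
#'   \item keep genes with a count greater than 1 in at least `min_frac` of the
#'     remaining cells;
#'   \item keep cell types with at least `min_cells` remaining cells.
#' }
#'
#' @param sc genes x cells count matrix with dimnames.
#' @param ann annotation tibble (`cell_id`, `cell_type`, `individual`)
#'   covering every column of `sc`.
#' @param rules a [qc_rules()] object.
#' @return list with elements `matrix`, `annotation`, and `report` (a tibble
#'   with one row per rule: rule id, what was filtered, number removed).
#' @export
apply_qc <- function(sc, ann, rules = qc_rules()) {
  validate_expression(sc, "single-cell matrix")
  validate_annotation(ann)
  if (!all(colnames(sc) %in% ann$cell_id)) {
    stop("every column of sc must be annotated; missing: ",
         paste(head(setdiff(colnames(sc), ann$cell_id), 5), collapse = ", "))
  }
  ann <- ann[match(colnames(sc), ann$cell_id), , drop = FALSE]
  report <- list()

  # rule 1: all-zero or zero-variance genes
  rv <- apply(sc, 1, var)
  keep_gene <- rowSums(sc) > 0 & rv > 0
  report$zero_or_constant_genes <- sum(!keep_gene)
  sc <- sc[keep_gene, , drop = FALSE]
  if (nrow(sc) == 0) stop("all filtered by rule 1 (zero/constant genes)")

  # rule 2: library-size outliers, deviation and MAD both about the mean
  lib <- colSums(sc)
  flag_outlier <- function(L) {
    dev <- abs(L - mean(L))
    dev > rules$mad_factor * median(dev)
  }
  out <- if (rules$per_individual) {
    unsplit(lapply(split(lib, ann$individual), flag_outlier), ann$individual)
  } else {
    flag_outlier(lib)
  }
  report$library_size_outlier_cells <- sum(out)
  sc <- sc[, !out, drop = FALSE]
  ann <- ann[!out, , drop = FALSE]
  if (ncol(sc) == 0) stop("all filtered by rule 2 (library-size outliers)")

  # rule 3: genes detected (count > 1) in at least min_frac of remaining cells
  frac <- rowMeans(sc > 1)
  keep_gene <- frac >= rules$min_frac
  report$low_detection_genes <- sum(!keep_gene)
  sc <- sc[keep_gene, , drop = FALSE]
  if (nrow(sc) == 0) stop("all filtered by rule 3 (low-detection genes)")

  # rule 4: cell types with at least min_cells cells
  counts <- table(ann$cell_type)
  keep_type <- names(counts)[counts >= rules$min_cells]
  drop_cell <- !(ann$cell_type %in% keep_type)
  report$small_celltype_cells <- sum(drop_cell)
  sc <- sc[, !drop_cell, drop = FALSE]
  ann <- ann[!drop_cell, , drop = FALSE]
  if (ncol(sc) == 0) stop("all filtered by rule 4 (small cell types)")

  report_tbl <- tibble::tibble(
    rule = c("zero_or_constant_genes", "library_size_outlier_cells",
             "low_detection_genes", "small_celltype_cells"),
    unit = c("genes", "cells", "genes", "cells"),
    removed = unlist(report, use.names = FALSE)
  )
  list(matrix = sc, annotation = ann, report = report_tbl)
}

#' Normalise matrix columns onto the probability simplex
#'
#' Each column `c` becomes `(c + epsilon) / sum(c + epsilon)`. With
#' `epsilon = 0` this is plain proportional scaling.
#'
#' @param m genes x columns matrix.
#' @param epsilon small mass added to every entry before scaling, which keeps
#'   zero counts strictly positive (needed for the entropic-OT gradient).
#' @return matrix of the same shape whose columns each sum to 1.
#' @export
normalize_columns <- function(m, epsilon = 0) {
  stopifnot(is.matrix(m), epsilon >= 0)
  if (any(m < 0)) stop("negative entries cannot be normalised to a histogram")
  shifted <- m + epsilon
  tot <- colSums(shifted)
  if (any(tot <= 0)) {
    stop("all-zero column(s) with epsilon = 0: ",
         paste(head(colnames(m)[tot <= 0], 5), collapse = ", "))
  }
  sweep(shifted, 2, tot, "/")
}

#' Restrict two expression matrices to a shared, identically ordered gene set
#'
#' @param a,b genes x columns matrices with gene rownames.
#' @param select `"all-shared"` keeps every shared gene; `"top-variable"`
#'   ranks shared genes by the variance of `log1p(b)` (the reference matrix)
#'   and keeps the top `n`.
#' @param n number of genes for `select = "top-variable"`.
#' @return list with elements `a` and `b`, both restricted to the same gene
#'   list in the same order.
#' @export
align_genes <- function(a, b, select = c("all-shared", "top-variable"), n = 500) {
  select <- match.arg(select)
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) == 0) {
    stop("no shared genes; first ids were a: ",
         paste(head(rownames(a), 3), collapse = ","), " vs b: ",
         paste(head(rownames(b), 3), collapse = ","))
  }
  if (select == "top-variable") {
    v <- apply(log1p(b[shared, , drop = FALSE]), 1, var)
    shared <- shared[order(v, decreasing = TRUE)][seq_len(min(n, length(shared)))]
    shared <- shared[order(match(shared, rownames(a)))]  # stable gene order
  }
  list(a = a[shared, , drop = FALSE], b = b[shared, , drop = FALSE])
}
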