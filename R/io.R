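#' Read a gene expression matrix from delimited text or Matrix Market triplets
#'
#' Dense files must have a header row of column ids and the gene id in the
#' first field of each subsequent row; tab, comma and semicolon delimiters are
#' auto-detected from the header line. Sparse input is a Matrix Market
#' coordinate file accompanied by one-id-per-line sidecar files for genes
#' (rows) and columns (cells/samples), 1-based indices as per the MTX
#' standard.
#'
#' Duplicate gene ids are collapsed by summation (counts are conserved) with a
#' warning.
#'
#' @param path path to the dense file or the `.mtx` file.
#' @param format `"dense"` or `"mtx"`.
#' @param gene_file,column_file sidecar id files, required for `format = "mtx"`.
#' @return numeric matrix, genes in rows (rownames), columns named.
#' @export
read_expression_matrix <- function(path, format = c("dense", "mtx"),
                                   gene_file = NULL, column_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense") {
    m <- read_dense_matrix(path)
  } else {
    if (is.null(gene_file) || is.null(column_file)) {
      stop("mtx format requires gene_file and column_file sidecars")
    }
    sp <- Matrix::readMM(path)
    genes <- readLines(gene_file)
    cols <- readLines(column_file)
    if (nrow(sp) != length(genes)) {
      stop(sprintf("mtx has %d rows but gene_file lists %d ids", nrow(sp), length(genes)))
    }
    if (ncol(sp) != length(cols)) {
      stop(sprintf("mtx has %d columns but column_file lists %d ids", ncol(sp), length(cols)))
    }
    m <- as.matrix(sp)
    dimnames(m) <- list(genes, cols)
  }
  if (any(m < 0)) stop("expression matrix contains negative entries")
  m <- collapse_duplicate_genes(m)
  validate_expression(m)
  m
}

read_dense_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  if (!nzchar(header)) stop("malformed header at line 1 of ", path, ": empty line")
  sep <- c("\t", ",", ";")[which.max(c(
    lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
    lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
    lengths(regmatches(header, gregexpr(";", header, fixed = TRUE)))
  ))]
  df <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               row.names = NULL, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  if (ncol(df) < 2) stop("malformed header at line 1 of ", path,
                         ": expected gene id column plus at least one sample column")
  genes <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!apply(df[, -1, drop = FALSE], 2, is.numeric))[1]
    stop("parse error in ", path, ": non-numeric values in column '",
         colnames(df)[-1][bad], "'")
  }
  rownames(vals) <- genes
  vals
}

collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  dup <- unique(rownames(m)[duplicated(rownames(m))])
  warning("collapsing ", length(dup), " duplicated gene id(s) by summation: ",
          paste(head(dup, 5), collapse = ", "))
  out <- rowsum(m, group = rownames(m), reorder = FALSE)
  # rowsum keeps first-appearance order with reorder = FALSE
  out
}

#' Read a cell annotation table
#'
#' Delimited text with mandatory columns `cell_id`, `cell_type`, `individual`.
#'
#' @param path file path.
#' @return tibble with one row per cell.
#' @export
read_cell_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  ann <- tibble::as_tibble(df)
  ann$cell_id <- as.character(ann$cell_id)
  ann$cell_type <- as.character(ann$cell_type)
  ann$individual <- as.character(ann$individual)
  validate_annotation(ann)
  ann
}

#' Write a matrix as tab-delimited text with a gene id column
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param id_name name of the leading id column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "gene_id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
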