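# Internal validators shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that a vector is a histogram (a point on the probability simplex)
#'
#' @param x numeric vector.
#' @param tol tolerance on the deviation of `sum(x)` from 1.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_histogram <- function(x, tol = 1e-9) {
  if (!is.numeric(x) || length(x) < 1) stop("histogram must be a numeric vector")
  if (any(!is.finite(x))) stop("histogram contains non-finite entries")
  if (any(x < 0)) stop("histogram contains negative entries")
  if (abs(sum(x) - 1) > tol) {
    stop(sprintf("histogram mass %.12f differs from 1 by more than %g", sum(x), tol))
  }
  invisible(TRUE)
}

validate_expression <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m)) stop(what, " must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " must carry gene rownames and column names")
  }
  if (anyDuplicated(rownames(m))) stop(what, " has duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop(what, " has duplicate column ids")
  if (any(m < 0)) stop(what, " contains negative entries")
  invisible(TRUE)
}

validate_annotation <- function(ann) {
  req <- c("cell_id", "cell_type", "individual")
  if (!all(req %in% names(ann))) {
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(ann$cell_id)) stop("annotation has duplicate cell ids")
  if (any(!nzchar(ann$cell_type)) || any(is.na(ann$cell_type))) {
    stop("annotation has empty cell_type entries")
  }
  if (any(!nzchar(ann$individual)) || any(is.na(ann$individual))) {
    stop("annotation has empty individual entries")
  }
  invisible(TRUE)
}

validate_ground_cost <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("ground cost must be a square matrix")
  if (any(m < 0)) stop("ground cost contains negative entries")
  if (max(abs(m - t(m))) > tol) stop("ground cost is not symmetric")
  invisible(TRUE)
}

# x * log(x) with the 0 * log(0) = 0 convention
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}
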