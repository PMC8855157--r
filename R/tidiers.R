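#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a deconvolution result into a long tibble
#'
#' @param x an `ot_deconv` object.
#' @param ... unused.
#' @return tibble with columns `sample`, `cell_type`, `proportion`.
#' @export
tidy.ot_deconv <- function(x, ...) {
  P <- x$proportions
  tibble::as_tibble(P, rownames = "cell_type") |>
    tidyr::pivot_longer(-"cell_type", names_to = "sample",
                        values_to = "proportion") |>
    dplyr::arrange(.data$sample, .data$cell_type)
}

#' One-row summary of a deconvolution result
#'
#' @param x an `ot_deconv` object.
#' @param ... unused.
#' @return tibble with sample/type counts, hyperparameters, the mean final
#'   objective and convergence fractions.
#' @export
glance.ot_deconv <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    n_samples = ncol(x$proportions),
    n_cell_types = nrow(x$proportions),
    metric = x$metric,
    gamma = x$cfg$ot$gamma,
    rho = x$cfg$rho,
    ensemble = !is.null(x$ensemble),
    mean_objective = mean(d$objective),
    frac_converged = mean(d$converged)
  )
}

#' Tidy ensemble weights
#'
#' @param x an `ot_ensemble` object.
#' @param ... unused.
#' @return tibble with columns `reference`, `weight`, `residual` (squared
#'   bulk-fit residual of that single reference).
#' @export
tidy.ot_ensemble <- function(x, ...) {
  res <- x$residuals[x$residuals$reference != ".ensemble", ]
  tibble::tibble(reference = names(x$weights),
                 weight = unname(x$weights),
                 residual = res$residual[match(names(x$weights), res$reference)])
}

#' One-row summary of an ensemble fit
#'
#' @param x an `ot_ensemble` object.
#' @param ... unused.
#' @return tibble with the number of references, the ensemble residual and
#'   the best single-reference residual.
#' @export
glance.ot_ensemble <- function(x, ...) {
  single <- x$residuals$residual[x$residuals$reference != ".ensemble"]
  tibble::tibble(
    n_references = length(x$weights),
    ensemble_residual = x$residuals$residual[x$residuals$reference == ".ensemble"],
    best_single_residual = min(single),
    top_reference = names(x$weights)[which.max(x$weights)]
  )
}

#' Stacked-bar plot of estimated cell-type proportions
#'
#' @param object an `ot_deconv` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ot_deconv <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample, y = .data$proportion,
                                 fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "estimated proportion", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Bar plot of ensemble reference weights
#'
#' @param object an `ot_ensemble` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ot_ensemble <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$reference,
                                                    -.data$weight),
                                 y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "reference individual", y = "ensemble weight") +
    ggplot2::theme_minimal()
}
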