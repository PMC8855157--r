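#' High-level deconvolution of a bulk matrix against a single-cell reference
#'
#' Composes the full workflow: QC on the reference, gene alignment,
#' signature construction, ground cost construction from the reference
#' cells, and the per-sample transport solves — with the per-individual
#' ensemble when `ensemble = TRUE` and more than one individual is present.
#'
#' @param bulk genes x samples bulk matrix (raw counts or normalised).
#' @param sc genes x cells single-cell count matrix.
#' @param ann annotation tibble (`cell_id`, `cell_type`, `individual`).
#' @param metric ground cost metric (see [ground_cost()]).
#' @param gamma,rho entropic OT weight and proportion-entropy weight.
#' @param ensemble combine per-individual references by ensemble weighting;
#'   otherwise cells are pooled into one aggregated reference.
#' @param qc apply [apply_qc()] to the reference first.
#' @param rules QC thresholds, a [qc_rules()].
#' @param gene_select `"all-shared"` or `"top-variable"`.
#' @param n_genes number of genes kept under `"top-variable"`.
#' @param beta soft-threshold power for the dissTOM cost.
#' @param cfg full [deconv_config()]; overrides `gamma`/`rho` when given.
#' @return object of class `ot_deconv`: list with `proportions` (cell types
#'   x samples), `diagnostics`, `ensemble` (the `ot_ensemble` object or
#'   NULL), `qc_report`, and the configuration used.
#' @export
deconvolute <- function(bulk, sc, ann, metric = "dissTOM", gamma = 0.001,
                        rho = 0.001, ensemble = TRUE, qc = TRUE,
                        rules = qc_rules(), gene_select = "all-shared",
                        n_genes = 500, beta = 6, cfg = NULL) {
  validate_expression(bulk, "bulk matrix")
  if (is.null(cfg)) cfg <- deconv_config(ot = ot_config(gamma = gamma), rho = rho)
  qc_report <- NULL
  if (qc) {
    qcres <- apply_qc(sc, ann, rules)
    sc <- qcres$matrix; ann <- qcres$annotation; qc_report <- qcres$report
  }
  al <- align_genes(bulk, sc, select = gene_select, n = n_genes)
  bulk <- al$a; sc <- al$b
  y <- normalize_columns(bulk, epsilon = cfg$ot$epsilon_support)

  n_ind <- length(unique(ann$individual))
  if (ensemble && n_ind > 1) {
    sigs <- build_signatures(sc, ann, by_individual = TRUE)
    costs <- lapply(names(sigs), function(ind) {
      cells <- ann$cell_id[ann$individual == ind]
      ground_cost(sc[, cells, drop = FALSE], metric = metric, beta = beta)
    })
    names(costs) <- names(sigs)
    ens <- ensemble_deconvolve(y, sigs, costs, cfg)
    out <- list(proportions = ens$combined,
                diagnostics = dplyr::bind_rows(
                  lapply(ens$per_individual, attr, "diagnostics"),
                  .id = "reference"),
                ensemble = ens, qc_report = qc_report, cfg = cfg,
                metric = metric)
  } else {
    sig <- build_signatures(sc, ann, by_individual = FALSE)[["pooled"]]
    m <- ground_cost(sc, metric = metric, beta = beta)
    P <- solve_proportions(y, sig, m, cfg)
    out <- list(proportions = P, diagnostics = attr(P, "diagnostics"),
                ensemble = NULL, qc_report = qc_report, cfg = cfg,
                metric = metric)
  }
  structure(out, class = "ot_deconv")
}

#' @exportS3Method base::print
print.ot_deconv <- function(x, ...) {
  cat("Optimal-transport deconvolution\n")
  cat(sprintf("  %d cell types x %d samples, metric = %s, gamma = %g, rho = %g\n",
              nrow(x$proportions), ncol(x$proportions), x$metric,
              x$cfg$ot$gamma, x$cfg$rho))
  if (!is.null(x$ensemble)) {
    cat("  ensemble weights:\n")
    w <- x$ensemble$weights
    for (i in seq_along(w)) cat(sprintf("    %s: %.4f\n", names(w)[i], w[i]))
  }
  cat("  mean proportions:\n")
  mp <- rowMeans(x$proportions)
  for (i in seq_along(mp)) cat(sprintf("    %s: %.4f\n", names(mp)[i], mp[i]))
  invisible(x)
}

#' @exportS3Method base::print
print.ot_ensemble <- function(x, ...) {
  cat("Ensemble deconvolution over", length(x$weights), "individual references\n")
  w <- x$weights
  for (i in seq_along(w)) cat(sprintf("  %s: %.4f\n", names(w)[i], w[i]))
  invisible(x)
}

#' Run configuration for the command-line workflows
#'
#' @param bulk,reference,annotation input paths (`reference` may be a dense
#'   matrix or an `.mtx` with `gene_file`/`column_file` sidecars).
#' @param gene_file,column_file MTX sidecar paths.
#' @param out_dir output directory, created if needed.
#' @param metric,gamma,rho,beta,ensemble,gene_select,n_genes,seed as in
#'   [deconvolute()].
#' @param qc_min_cells,qc_min_frac QC thresholds (see [qc_rules()]).
#' @param n_replicates,fraction pseudo-bulk protocol settings for
#'   [run_benchmark()].
#' @return list of class `run_config`.
#' @export
run_config <- function(bulk = NULL, reference = NULL, annotation = NULL,
                       gene_file = NULL, column_file = NULL,
                       out_dir = "otdeconv_run", metric = "dissTOM",
                       gamma = 0.001, rho = 0.001, beta = 6, ensemble = TRUE,
                       gene_select = "all-shared", n_genes = 500,
                       n_replicates = 20, fraction = 0.6,
                       qc_min_cells = 50, qc_min_frac = 0.05, seed = 1L) {
  stopifnot(gamma > 0, rho > 0,
            metric %in% c("dissTOM", "euclidean", "cosine", "correlation"))
  structure(as.list(environment()), class = "run_config")
}

read_reference_inputs <- function(cfg) {
  fmt <- if (grepl("\\.mtx$", cfg$reference)) "mtx" else "dense"
  sc <- read_expression_matrix(cfg$reference, format = fmt,
                               gene_file = cfg$gene_file,
                               column_file = cfg$column_file)
  ann <- read_cell_annotation(cfg$annotation)
  list(sc = sc, ann = ann)
}

log_line <- function(con, module, msg) {
  writeLines(sprintf("[%s] [%s] %s",
                     format(Sys.time(), "%Y-%m-%d %H:%M:%S"), module, msg), con)
}

#' Run the deconvolution workflow from files
#'
#' Reads the bulk matrix, reference and annotation named in `cfg`, runs
#' [deconvolute()], and writes `proportions.tsv`, `weights.tsv` (when the
#' ensemble is used), `config.json` and `log.txt` under `cfg$out_dir`.
#' Identical configuration and seed produce identical outputs.
#'
#' @param cfg a [run_config()] with `bulk`, `reference`, `annotation` set.
#' @return invisibly, a list with the output paths and the `ot_deconv`
#'   result.
#' @export
run_deconvolve <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  con <- file(log_path, "w")
  on.exit(close(con))
  log_line(con, "io", paste("reading bulk:", cfg$bulk))
  bulk <- read_expression_matrix(cfg$bulk)
  inputs <- read_reference_inputs(cfg)
  log_line(con, "io", sprintf("reference: %d genes x %d cells",
                              nrow(inputs$sc), ncol(inputs$sc)))
  fit <- withCallingHandlers(
    deconvolute(bulk, inputs$sc, inputs$ann, metric = cfg$metric,
                gamma = cfg$gamma, rho = cfg$rho, ensemble = cfg$ensemble,
                gene_select = cfg$gene_select, n_genes = cfg$n_genes,
                rules = qc_rules(min_frac = cfg$qc_min_frac,
                                 min_cells = cfg$qc_min_cells)),
    warning = function(w) {
      log_line(con, "deconv", paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  prop_path <- file.path(cfg$out_dir, "proportions.tsv")
  write_matrix_tsv(fit$proportions, prop_path, id_name = "cell_type")
  paths <- list(proportions = prop_path, log = log_path)
  if (!is.null(fit$ensemble)) {
    w_path <- file.path(cfg$out_dir, "weights.tsv")
    write.table(data.frame(individual = names(fit$ensemble$weights),
                           weight = unname(fit$ensemble$weights)),
                w_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$weights <- w_path
  }
  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
                       cfg_path, auto_unbox = TRUE)
  paths$config <- cfg_path
  log_line(con, "deconv", "done")
  invisible(c(paths, list(fit = fit)))
}

#' Run the pseudo-bulk benchmark workflow
#'
#' Splits cells into reference and testing halves, generates pseudo-bulk
#' mixtures per individual, deconvolves them under paired (own reference)
#' and, when several individuals are present, unpaired (all other
#' individuals, ensembled) settings, and reports RMSE and Pearson
#' correlation per setting.
#'
#' @param cfg a [run_config()]; either `reference` + `annotation` paths or a
#'   scenario via `scenario`.
#' @param scenario optional [synthetic_scenario()] used instead of file
#'   inputs.
#' @return tibble with columns `individual`, `setting`, `rmse`, `cor`
#'   (also written to `benchmark.tsv` under `cfg$out_dir`).
#' @export
run_benchmark <- function(cfg, scenario = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(scenario)) {
    sim <- generate_synthetic_truth(scenario)
    sc <- sim$counts; ann <- sim$annotation
  } else {
    inputs <- read_reference_inputs(cfg)
    sc <- inputs$sc; ann <- inputs$ann
  }
  qcres <- apply_qc(sc, ann, qc_rules(
    min_frac = cfg$qc_min_frac,
    min_cells = min(cfg$qc_min_cells, max(3, ncol(sc) %/% 20))))
  sc <- qcres$matrix; ann <- qcres$annotation

  sp <- split_cells(ann, seed = cfg$seed)
  ann_ref <- ann[ann$cell_id %in% sp$reference, ]
  ann_test <- ann[ann$cell_id %in% sp$testing, ]
  sigs <- build_signatures(sc[, ann_ref$cell_id, drop = FALSE], ann_ref)
  costs <- lapply(names(sigs), function(ind) {
    cells <- ann_ref$cell_id[ann_ref$individual == ind]
    ground_cost(sc[, cells, drop = FALSE], metric = cfg$metric, beta = cfg$beta)
  })
  names(costs) <- names(sigs)
  dcfg <- deconv_config(ot = ot_config(gamma = cfg$gamma), rho = cfg$rho)

  rows <- list()
  for (ind in unique(ann_test$individual)) {
    test_cells <- ann_test$cell_id[ann_test$individual == ind]
    pb <- generate_pseudobulk(sc[, test_cells, drop = FALSE],
                              ann_test[ann_test$individual == ind, ],
                              n_replicates = cfg$n_replicates,
                              fraction = cfg$fraction, seed = cfg$seed)
    y <- normalize_columns(pb$mixtures, epsilon = dcfg$ot$epsilon_support)
    # paired: the individual's own reference
    if (ind %in% names(sigs)) {
      P <- solve_proportions(y, sigs[[ind]], costs[[ind]], dcfg)
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = ind, setting = "paired",
        rmse = proportion_rmse(pb$truth, P),
        cor = proportion_cor(pb$truth, P))
    }
    # unpaired: ensemble over the other individuals
    others <- setdiff(names(sigs), ind)
    if (length(others) >= 1) {
      ens <- ensemble_deconvolve(y, sigs[others], costs[others], dcfg)
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = ind, setting = "unpaired_ensemble",
        rmse = proportion_rmse(pb$truth, ens$combined),
        cor = proportion_cor(pb$truth, ens$combined))
    }
  }
  report <- dplyr::bind_rows(rows)
  write.table(report, file.path(cfg$out_dir, "benchmark.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report
}
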