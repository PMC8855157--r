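#' Describe a synthetic multi-individual single-cell scenario
#'
#' Defaults emulate a small multi-donor droplet experiment: per-type
#' expression programs drawn log-normally over genes, multiplicative
#' per-individual gene effects (the individual/batch shift), per-cell counts
#' multinomial at a fixed depth, and bulk mixing proportions drawn from a
#' Dirichlet. See the methods vignette for what these defaults emulate and
#' what they do not.
#'
#' @param n_genes number of genes.
#' @param n_types number of cell types.
#' @param n_individuals number of individuals.
#' @param cells_per_type cells per type per individual.
#' @param depth total counts per cell (sequencing depth).
#' @param individual_effect_sd standard deviation (log scale) of the
#'   per-individual multiplicative gene effect; 0 removes batch structure.
#' @param dirichlet_alpha concentration of the Dirichlet that draws true
#'   mixing proportions; large values concentrate near uniform.
#' @param seed integer seed.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_genes = 200, n_types = 5, n_individuals = 3,
                               cells_per_type = 100, depth = 2000,
                               individual_effect_sd = 0.3,
                               dirichlet_alpha = 1, seed = 1L) {
  stopifnot(n_genes >= 2, n_types >= 2, n_individuals >= 1,
            cells_per_type >= 1, depth >= 1, individual_effect_sd >= 0,
            dirichlet_alpha > 0)
  structure(list(n_genes = n_genes, n_types = n_types,
                 n_individuals = n_individuals,
                 cells_per_type = cells_per_type, depth = depth,
                 individual_effect_sd = individual_effect_sd,
                 dirichlet_alpha = dirichlet_alpha, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Generate a seeded synthetic multi-individual dataset with known truth
#'
#' Draws one log-normal expression program per cell type (shared across
#' individuals), one log-normal multiplicative gene effect per individual,
#' samples each cell's counts from a multinomial at the scenario depth, and
#' (optionally) paired bulk samples as multinomial draws from known
#' Dirichlet mixtures of the type programs. Fully reproducible from the
#' scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @param n_bulk number of paired bulk samples per individual (0 for none).
#' @param bulk_depth total counts per bulk sample.
#' @return list with `counts` (genes x cells), `annotation` (tibble),
#'   `type_profiles` (genes x types expected programs, per individual, a
#'   list), `bulk` (genes x (n_individuals * n_bulk) counts or NULL),
#'   `bulk_truth` (types x bulk samples proportions or NULL),
#'   `bulk_individual` (character vector), and the `scenario`.
#' @export
generate_synthetic_truth <- function(scenario, n_bulk = 0, bulk_depth = 1e5) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(sc$seed)

  genes <- sprintf("g%03d", seq_len(sc$n_genes))
  types <- paste0("type", LETTERS[seq_len(sc$n_types)])
  inds <- paste0("ind", seq_len(sc$n_individuals))

  # per-type expression programs: log-normal rates over genes
  base <- matrix(rlnorm(sc$n_genes * sc$n_types, meanlog = 0, sdlog = 1.5),
                 sc$n_genes, sc$n_types, dimnames = list(genes, types))

  # per-individual multiplicative gene effect (shared across types)
  ind_effect <- matrix(
    rlnorm(sc$n_genes * sc$n_individuals, meanlog = 0,
           sdlog = sc$individual_effect_sd),
    sc$n_genes, sc$n_individuals, dimnames = list(genes, inds))

  profiles <- lapply(inds, function(ind) {
    pr <- base * ind_effect[, ind]
    sweep(pr, 2, colSums(pr), "/")
  })
  names(profiles) <- inds

  n_cells <- sc$n_individuals * sc$n_types * sc$cells_per_type
  counts <- matrix(0L, sc$n_genes, n_cells, dimnames = list(genes, NULL))
  cell_id <- character(n_cells)
  cell_type <- character(n_cells)
  individual <- character(n_cells)
  i <- 0L
  for (ind in inds) {
    for (tp in types) {
      pr <- profiles[[ind]][, tp]
      draws <- rmultinom(sc$cells_per_type, size = sc$depth, prob = pr)
      cols <- i + seq_len(sc$cells_per_type)
      counts[, cols] <- draws
      cell_id[cols] <- sprintf("%s_%s_c%04d", ind, tp, seq_len(sc$cells_per_type))
      cell_type[cols] <- tp
      individual[cols] <- ind
      i <- i + sc$cells_per_type
    }
  }
  colnames(counts) <- cell_id
  ann <- tibble::tibble(cell_id = cell_id, cell_type = cell_type,
                        individual = individual)

  bulk <- NULL; bulk_truth <- NULL; bulk_individual <- NULL
  if (n_bulk > 0) {
    cols <- list(); tcols <- list(); who <- character()
    for (ind in inds) {
      for (j in seq_len(n_bulk)) {
        pj <- rdirichlet1(rep(sc$dirichlet_alpha, sc$n_types))
        mix <- as.vector(profiles[[ind]] %*% pj)
        cols[[length(cols) + 1]] <- rmultinom(1, size = bulk_depth, prob = mix)[, 1]
        tcols[[length(tcols) + 1]] <- pj
        who <- c(who, ind)
      }
    }
    bulk <- do.call(cbind, cols)
    dimnames(bulk) <- list(genes, sprintf("bulk%03d", seq_along(cols)))
    bulk_truth <- do.call(cbind, tcols)
    dimnames(bulk_truth) <- list(types, colnames(bulk))
    bulk_individual <- who
  }

  list(counts = counts, annotation = ann, type_profiles = profiles,
       bulk = bulk, bulk_truth = bulk_truth, bulk_individual = bulk_individual,
       scenario = sc)
}
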