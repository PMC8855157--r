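test_that("cells split evenly per individual and type, reference takes the odd cell", {
  ann <- tibble::tibble(
    cell_id = paste0("c", 1:41),
    cell_type = c(rep("A", 10), rep("B", 11), rep("A", 10), rep("B", 10)),
    individual = rep(c("d1", "d2"), c(21, 20)))
  sp <- split_cells(ann, seed = 3)
  expect_setequal(c(sp$reference, sp$testing), ann$cell_id)
  expect_length(intersect(sp$reference, sp$testing), 0)
  # d1/A: 10 -> 5/5; d1/B: 11 -> 6/5; d2: 10+10 -> 5+5 each
  tab <- function(ids) table(ann$individual[ann$cell_id %in% ids],
                             ann$cell_type[ann$cell_id %in% ids])
  tr <- tab(sp$reference); te <- tab(sp$testing)
  expect_equal(unname(tr["d1", "A"]), 5)
  expect_equal(unname(tr["d1", "B"]), 6)
  expect_equal(unname(te["d1", "B"]), 5)
  expect_equal(unname(te["d2", "A"]), 5)
  expect_equal(unname(te["d2", "B"]), 5)

  # a singleton type goes to reference with a warning
  ann1 <- tibble::tibble(cell_id = "solo", cell_type = "X", individual = "d1")
  expect_warning(sp1 <- split_cells(ann1, seed = 1), "single cell")
  expect_identical(sp1$reference, "solo")
})

test_that("pseudo-bulk mixtures record the realised composition exactly", {
  fix <- toy_sc(n_genes = 8, per_type = 5, types = c("A", "B"),
                inds = "d1", seed = 51)
  # fraction 1: every replicate is the total and the truth is the pool mix
  pb <- generate_pseudobulk(fix$counts, fix$ann, n_replicates = 3,
                            fraction = 1, seed = 7)
  expect_equal(pb$mixtures[, 1], rowSums(fix$counts))
  expect_equal(pb$mixtures[, 1], pb$mixtures[, 3])
  expect_equal(pb$truth[, 2], c(A = 0.5, B = 0.5))

  # fraction 0.5 of 10 cells: recompute the seeded draw independently
  pb2 <- generate_pseudobulk(fix$counts, fix$ann, n_replicates = 2,
                             fraction = 0.5, seed = 11)
  set.seed(11 + 1)
  idx <- sample.int(10, 5)
  expect_equal(pb2$mixtures[, 1], rowSums(fix$counts[, idx]))
  comp <- table(factor(fix$ann$cell_type[idx], levels = c("A", "B"))) / 5
  expect_equal(pb2$truth[, 1], c(A = comp[["A"]], B = comp[["B"]]))
  # column sums equal the library sizes of the sampled cells
  expect_equal(sum(pb2$mixtures[, 1]), sum(fix$counts[, idx]))
  expect_error(generate_pseudobulk(fix$counts, fix$ann, fraction = 0.05),
               "nothing to sample")
})

test_that("the synthetic generator is seeded, batch-aware and Dirichlet-calibrated", {
  sc <- synthetic_scenario(n_genes = 30, n_types = 3, n_individuals = 2,
                           cells_per_type = 10, depth = 300, seed = 9)
  a <- generate_synthetic_truth(sc, n_bulk = 2)
  b <- generate_synthetic_truth(sc, n_bulk = 2)
  expect_identical(a$counts, b$counts)       # bitwise reproducibility
  expect_identical(a$bulk, b$bulk)
  expect_equal(dim(a$counts), c(30, 2 * 3 * 10))
  expect_true(all(colSums(a$counts) == 300))
  expect_true(all(abs(colSums(a$bulk_truth) - 1) < 1e-12))

  # no individual effect: expected type profiles identical across individuals
  sc0 <- synthetic_scenario(n_genes = 30, n_types = 3, n_individuals = 2,
                            cells_per_type = 10, individual_effect_sd = 0,
                            seed = 10)
  z <- generate_synthetic_truth(sc0)
  expect_equal(z$type_profiles$ind1, z$type_profiles$ind2, tolerance = 1e-12)

  # large Dirichlet concentration pushes truth toward uniform
  scU <- synthetic_scenario(n_genes = 20, n_types = 4, n_individuals = 1,
                            cells_per_type = 5, dirichlet_alpha = 1e5, seed = 11)
  u <- generate_synthetic_truth(scU, n_bulk = 5)
  expect_lt(max(abs(u$bulk_truth - 0.25)), 0.01)
})

test_that("RMSE and correlation metrics match hand-computed fixtures", {
  t1 <- cbind(s1 = c(A = 0.6, B = 0.4))
  e1 <- cbind(s1 = c(A = 0.5, B = 0.5))
  expect_equal(proportion_rmse(t1, e1), 0.1)
  expect_equal(proportion_rmse(t1, t1), 0)

  # adding an exactly-recovered second sample halves the squared error mass
  t2 <- cbind(t1, s2 = c(A = 0.3, B = 0.7))
  e2 <- cbind(e1, s2 = c(A = 0.3, B = 0.7))
  expect_equal(proportion_rmse(t2, e2), sqrt(0.02 / 4))

  # affine transforms preserve perfect correlation
  tr <- cbind(s1 = c(A = 0.6, B = 0.3, C = 0.1),
              s2 = c(A = 0.2, B = 0.5, C = 0.3))
  expect_equal(proportion_cor(tr, tr), 1)
  expect_equal(proportion_cor(tr, 0.5 * tr + 0.1), 1)
  # k = 2 columns with est = 1 - truth flip the sign exactly
  tk <- cbind(s1 = c(A = 0.6, B = 0.4), s2 = c(A = 0.8, B = 0.2))
  expect_equal(proportion_cor(tk, 1 - tk), -1)
  expect_error(proportion_cor(tk, matrix(0.5, 2, 2,
                                         dimnames = dimnames(tk))),
               "zero variance")
})

test_that("metrics align estimates on the union type set with zero fill", {
  truth <- cbind(s1 = c(A = 0.5, B = 0.3, C = 0.2))
  est <- cbind(s1 = c(A = 0.6, B = 0.4))  # C missing from the reference
  expect_equal(proportion_rmse(truth, est),
               sqrt(mean(c(0.1, 0.1, 0.2)^2)))
  est_extra <- cbind(s1 = c(A = 0.5, B = 0.3, C = 0.1, D = 0.1))
  expect_equal(proportion_rmse(truth, est_extra), sqrt(mean(c(0, 0, 0.1, 0.1)^2)))
  bad <- cbind(s1 = c(A = 1), s2 = c(A = 1))
  expect_error(proportion_rmse(truth, bad), "samples")
})
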