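small_tree <- function() {
  data.frame(parent = c("root", "root"), child = c("ecto", "endo"),
             branch_time_hpf = c(8, 8), stringsAsFactors = FALSE)
}

test_that("sim_config validates tree topology, timepoints and statuses", {
  expect_s3_class(sim_config(), "SimConfig")
  expect_error(sim_config(timepoints_A = c(9, 6)), "sorted ascending")
  bad_tree <- data.frame(parent = c("root", "a"), child = c("a", "b"),
                         branch_time_hpf = c(10, 8))
  expect_error(sim_config(lineage_tree = bad_tree), "increase along")
  ints <- data.frame(regulator = "r1", target = "t1", lineage = "nowhere",
                     onset_hpf = 9, status_in_B = "conserved")
  expect_error(sim_config(interactions = ints), "not in tree")
  ints$lineage <- "ecto"
  ints$status_in_B <- "garbled"
  expect_error(sim_config(lineage_tree = small_tree(), interactions = ints),
               "invalid status_in_B")
})

test_that("the simulator is deterministic under a fixed seed", {
  cfg <- sim_config(lineage_tree = small_tree(), timepoints_A = c(6, 10, 14),
                    timepoints_B = c(6, 10, 14), cells_per_timepoint = 40L,
                    n_genes = 50L, seed = 7L)
  s1 <- simulate_two_species(cfg)
  s2 <- simulate_two_species(cfg)
  for (sp in c("A", "B"))
    for (tp in names(s1[[sp]]))
      expect_identical(as.matrix(s1[[sp]][[tp]]$counts),
                       as.matrix(s2[[sp]][[tp]]$counts))
  expect_identical(s1$truth$cells, s2$truth$cells)
  s3 <- simulate_two_species(sim_config(lineage_tree = small_tree(),
                                        timepoints_A = c(6, 10, 14),
                                        timepoints_B = c(6, 10, 14),
                                        cells_per_timepoint = 40L,
                                        n_genes = 50L, seed = 8L))
  expect_false(identical(as.matrix(s1$A[[1]]$counts), as.matrix(s3$A[[1]]$counts)))
})

test_that("count moments match the configured noise model", {
  # Poisson limit: with dropout 0 and infinite dispersion, per-gene sample
  # variance tracks the sample mean
  cfg <- sim_config(lineage_tree = small_tree(), timepoints_A = 6,
                    timepoints_B = 6, cells_per_timepoint = 2000L,
                    n_genes = 60L, nb_dispersion = Inf, dropout_rate = 0,
                    mean_depth_umis = NA, seed = 3L)
  sim <- simulate_two_species(cfg)
  m <- as.matrix(sim$A[[1]]$counts)  # all cells are root lineage at 6 hpf
  mu <- rowMeans(m)
  vv <- apply(m, 1, var)
  keep <- mu > 0.2
  expect_gt(sum(keep), 20)
  expect_lt(median(abs(vv[keep] / mu[keep] - 1)), 0.15)

  # negative binomial: variance approximately mu + mu^2/size
  cfg2 <- sim_config(lineage_tree = small_tree(), timepoints_A = 6,
                     timepoints_B = 6, cells_per_timepoint = 5000L,
                     n_genes = 60L, nb_dispersion = 2, dropout_rate = 0,
                     mean_depth_umis = NA, seed = 4L)
  m2 <- as.matrix(simulate_two_species(cfg2)$A[[1]]$counts)
  mu2 <- rowMeans(m2)
  vv2 <- apply(m2, 1, var)
  keep2 <- mu2 > 0.5
  pred <- mu2[keep2] + mu2[keep2]^2 / 2
  expect_lt(median(abs(vv2[keep2] / pred - 1)), 0.2)
})

test_that("species B onsets are the species A onsets plus the configured delay", {
  cfg <- sim_config(onset_delay_B = 3)
  sim <- simulate_two_species(cfg)
  on <- sim$truth$onsets
  nonroot <- setdiff(names(on$A), "root")
  expect_equal(on$B[nonroot], on$A[nonroot] + 3)
  expect_equal(unname(on$A["root"]), 0)
})

test_that("a delayed lineage program rises later in species B by the delay", {
  # mean expression of the ecto program genes, within ecto cells, crosses
  # half-maximum ~3 h later in species B
  cfg <- sim_config(lineage_tree = small_tree(),
                    timepoints_A = 6:16, timepoints_B = 6:16,
                    cells_per_timepoint = 200L, n_genes = 60L,
                    onset_delay_B = 3, dropout_rate = 0,
                    mean_depth_umis = NA, seed = 5L)
  sim <- simulate_two_species(cfg)
  # per-timepoint mean expression profile of ecto cells, full gene vector;
  # the lag minimizing the A-vs-B profile mismatch should equal the delay
  profA <- sapply(sim$A, function(cm) {
    lin <- sim$truth$cells$lineage[match(cm$barcodes, sim$truth$cells$barcode)]
    Matrix::rowMeans(cm$counts[, lin == "ecto", drop = FALSE])
  })
  profB <- sapply(sim$B, function(cm) {
    lin <- sim$truth$cells$lineage[match(cm$barcodes, sim$truth$cells$barcode)]
    Matrix::rowMeans(cm$counts[, lin == "ecto", drop = FALSE])
  })
  # timepoints where a lineage has no cells yet give NaN profiles (species B
  # populates ecto 3 h later); compare only the jointly populated columns
  lags <- 0:5
  err <- sapply(lags, function(L) {
    ia <- seq_len(ncol(profA) - L); ib <- ia + L
    mean((profA[, ia] - profB[, ib])^2, na.rm = TRUE)
  })
  expect_equal(lags[which.min(err)], 3)
})

test_that("a lost interaction leaves no co-expression in species B beyond background", {
  ints <- data.frame(regulator = "rX", target = "tX", lineage = "ecto",
                     onset_hpf = 9, status_in_B = "lost",
                     stringsAsFactors = FALSE)
  cfg <- sim_config(lineage_tree = small_tree(), timepoints_A = c(8, 12, 16),
                    timepoints_B = c(8, 12, 16), cells_per_timepoint = 600L,
                    n_genes = 50L, interactions = ints, seed = 6L)
  sim <- simulate_two_species(cfg)
  co_B <- sum(sapply(sim$B, function(cm)
    sum(cm$counts["rX", ] >= 1 & cm$counts["tX", ] >= 1)))
  co_A <- sum(sapply(sim$A, function(cm)
    sum(cm$counts["rX", ] >= 1 & cm$counts["tX", ] >= 1)))
  # with zero baseline leak the regulator and target domains are disjoint
  # in B (target only in its secondary lineage), so co-occurrence is nil
  expect_equal(co_B, 0)
  expect_gt(co_A, 50)
  # both genes remain individually expressed in B (Fig-8-style loss)
  expr_B <- count_expressing_cells(sim$B, "rX", "tX")
  expect_gt(expr_B[["regulator"]], 100)
  expect_gt(expr_B[["target"]], 100)
})

test_that("the truth lineage graph conserves descendant mass", {
  # single active lineage: path graph with unit weights
  lone <- data.frame(parent = "root", child = "late",
                     branch_time_hpf = 100, stringsAsFactors = FALSE)
  cfg <- sim_config(lineage_tree = lone, timepoints_A = c(6, 9, 12),
                    timepoints_B = c(6, 9, 12), cells_per_timepoint = 30L,
                    n_genes = 30L, seed = 2L)
  g <- truth_lineage_tree(simulate_two_species(cfg)$truth)
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$weight, c(1, 1))

  # branching: outgoing weights sum to 1 from every node
  cfg2 <- sim_config(cells_per_timepoint = 30L, n_genes = 30L)
  g2 <- truth_lineage_tree(simulate_two_species(cfg2)$truth)
  out_sums <- tapply(g2$edges$weight, g2$edges$source, sum)
  expect_true(all(abs(out_sums - 1) < 1e-12))
  # the 7 hpf binary branch: root@6 has two children
  expect_equal(sum(g2$edges$source == "root@6"), 2)
})
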