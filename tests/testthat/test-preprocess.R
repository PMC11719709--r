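test_that("QC filtering applies strict inequalities at the published boundaries", {
  # build cells sitting exactly on and next to the 200 / 4000 / 10000 bounds
  n_genes <- 4001
  mk_col <- function(n_detected, total) {
    col <- integer(n_genes)
    col[seq_len(n_detected)] <- 1L
    col[1] <- col[1] + as.integer(total - n_detected)
    col
  }
  cols <- cbind(
    mk_col(200, 300),     # exactly min_genes -> removed
    mk_col(201, 300),     # just above -> kept
    mk_col(4000, 5000),   # exactly max_genes -> removed
    mk_col(3999, 5000),   # just below -> kept
    mk_col(500, 10000),   # exactly max_counts -> removed
    mk_col(500, 9999))    # just below -> kept
  cm <- count_matrix(Matrix::Matrix(cols, sparse = TRUE),
                     sprintf("g%04d", seq_len(n_genes)),
                     paste0("cell", 1:6), "A", 6)
  kept <- filter_cells(cm, 200, 4000, 10000)
  expect_equal(kept$barcodes, c("cell2", "cell4", "cell6"))
})

test_that("QC survivors equal a brute-force per-cell recount on random fixtures", {
  for (s in 1:4) {
    set.seed(100 + s)
    m <- matrix(rpois(300 * 80, 2.5), 300, 80)
    cm <- count_matrix(m, sprintf("g%03d", 1:300), sprintf("c%02d", 1:80))
    thr <- list(min_genes = sample(50:150, 1), max_genes = sample(200:280, 1),
                max_counts = sample(600:900, 1))
    kept <- suppressWarnings(
      filter_cells(cm, thr$min_genes, thr$max_genes, thr$max_counts))
    oracle <- oracle_filter_survivors(m, thr$min_genes, thr$max_genes, thr$max_counts)
    expect_equal(match(kept$barcodes, cm$barcodes), oracle)
  }
})

test_that("normalization matches its closed form and an independent oracle", {
  # single cell, counts (0, 10): S equals the cell's own total
  cm1 <- count_matrix(cbind(c(0, 10)), c("g1", "g2"), "c1")
  expect_equal(as.vector(normalize_log_cpm(cm1)), c(0, log(11)), tolerance = 1e-12)
  # random fixture vs an independently coded one-liner
  set.seed(11)
  m <- matrix(rpois(20 * 30, 3) + 1, 20, 30)
  cm <- count_matrix(m, paste0("g", 1:20), paste0("c", 1:30))
  tu <- colSums(m)
  oracle <- log1p(t(t(m) * (median(tu) / tu)))
  expect_equal(unname(normalize_log_cpm(cm)), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  # cell-to-cell depth differences cancel: a cell with doubled counts gets
  # the same normalized column as its unscaled twin
  m2 <- cbind(m, m[, 1] * 2L)
  cm2 <- count_matrix(m2, paste0("g", 1:20), paste0("c", 1:31))
  n2 <- normalize_log_cpm(cm2)
  expect_equal(n2[, 31], n2[, 1], tolerance = 1e-12, ignore_attr = TRUE)
  # zero-depth cells are an error, not silently propagated
  cm0 <- count_matrix(cbind(c(1, 0), c(0, 0)), c("g1", "g2"), c("c1", "c2"))
  expect_error(normalize_log_cpm(cm0), "zero-depth")
})

test_that("variable-gene selection ranks by variance with lexicographic ties", {
  norm <- rbind(gA = c(0, 0, 0, 0),     # var 0
                gC = c(1, 5, 1, 5),     # high var, ties with gB
                gB = c(5, 1, 5, 1),
                gD = c(1, 2, 1, 2))
  idx <- select_variable_genes(norm, 2)
  expect_equal(rownames(norm)[idx], c("gB", "gC"))
  expect_error(select_variable_genes(norm, 9), "exceeds gene count")
  set.seed(12)
  big <- matrix(rnorm(100 * 30), 100, 30,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
  idx2 <- select_variable_genes(big, 10)
  v <- apply(big, 1, var)
  expect_equal(sort(v[idx2]), sort(v, decreasing = TRUE)[10:1], tolerance = 1e-12)
})

test_that("PCA embedding preserves geometry and uses a fixed sign convention", {
  set.seed(13)
  norm <- matrix(rnorm(30 * 25), 30, 25,
                 dimnames = list(paste0("g", 1:30), paste0("c", 1:25)))
  emb <- embed_pca(norm, 24)
  # full-rank embedding preserves pairwise cell distances
  expect_equal(as.matrix(dist(emb$coords)), as.matrix(dist(t(norm) )),
               tolerance = 1e-8, ignore_attr = TRUE)
  # coordinates are centered
  expect_lt(max(abs(colMeans(emb$coords))), 1e-10)
  # sign convention: the dominant loading of every component is positive
  dom <- apply(emb$basis, 2, function(l) l[which.max(abs(l))])
  expect_true(all(dom > 0))
  # deterministic across repeated calls
  expect_identical(emb$coords, embed_pca(norm, 24)$coords)
  expect_error(embed_pca(norm, 40), "n_pcs exceeds")
})

test_that("graph clustering separates well-separated blobs deterministically", {
  set.seed(14)
  blob1 <- matrix(rnorm(60 * 3), 60, 3)
  blob2 <- matrix(rnorm(60 * 3) + 30, 60, 3)
  coords <- rbind(blob1, blob2)
  cl <- cluster_cells(coords, k_neighbors = 10, seed = 1L)
  expect_length(cl, 120)
  # no community spans both blobs: the kNN graph is disconnected between them
  expect_length(intersect(unique(cl[1:60]), unique(cl[61:120])), 0)
  expect_identical(cl, cluster_cells(coords, k_neighbors = 10, seed = 1L))
  expect_error(cluster_cells(coords, k_neighbors = 200), "k_neighbors")
})
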