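mk_fates <- function(P, ref = 24) {
  structure(list(probs = P, fate_names = colnames(P),
                 reference_timepoint = ref, flagged = integer(0)),
            class = "FateMatrix")
}

test_that("triangle projection commits cells at the published 0.7 threshold", {
  P <- rbind(c1 = c(A = 0.8, B = 0.1, C = 0.1),
             c2 = c(A = 0.7, B = 0.2, C = 0.1),
             c3 = c(A = 0.69, B = 0.21, C = 0.1),
             c4 = c(A = 0.1, B = 0.15, C = 0.75))
  tri <- triangle_projection(mk_fates(P), "A", "B", threshold = 0.7)
  expect_equal(tri$committed_to, c("A", "A", "uncommitted", "other"))
  # pure fates land on the triangle vertices
  Ppure <- rbind(p1 = c(A = 1, B = 0, C = 0),
                 p2 = c(A = 0, B = 1, C = 0),
                 p3 = c(A = 0, B = 0, C = 1))
  tri2 <- triangle_projection(mk_fates(Ppure), "A", "B")
  expect_equal(tri2$x, c(0.5, 1, 0), tolerance = 1e-12)
  expect_equal(tri2$y, c(sqrt(3) / 2, 0, 0), tolerance = 1e-12)
  # barycentric coordinates always sum to one after grouping
  expect_equal(tri$p_fate_A + tri$p_fate_B + tri$p_other, rep(1, 4),
               tolerance = 1e-12)
  expect_error(triangle_projection(mk_fates(P), "A", "A"), "must differ")
  expect_error(triangle_projection(mk_fates(P), "A", "Z"), "unknown fate")
  expect_error(triangle_projection(mk_fates(P), "A", "B", threshold = 0.4),
               "threshold")
})

# fixture: one parent cluster of 20 cells whose descendant mass splits
# between two child clusters in a configurable ratio
split_fixture <- function(frac_to_x) {
  src <- paste0("p", 1:20)
  tgt <- c(paste0("x", 1:12), paste0("y", 1:12))
  g <- matrix(0, 20, 24, dimnames = list(src, tgt))
  g[, 1:12] <- frac_to_x / 12
  g[, 13:24] <- (1 - frac_to_x) / 12
  g <- g / 20                      # unit total mass
  clusters <- data.frame(
    barcode = c(src, tgt),
    timepoint_hpf = c(rep(6, 20), rep(9, 24)),
    cluster_id = c(rep("P", 20), rep("X", 12), rep("Y", 12)),
    stringsAsFactors = FALSE)
  list(maps = list(fixture_map(g, 6, 9, src, tgt)), clusters = clusters)
}

test_that("an 80/20 descendant split keeps both edges at the 0.15 cutoff", {
  fx <- split_fixture(0.8)
  g <- build_lineage_graph(fx$maps, fx$clusters, min_cells = 10, edge_cutoff = 0.15)
  expect_equal(nrow(g$edges), 2)
  w <- setNames(g$edges$weight, g$edges$target)
  expect_equal(unname(w[c("X@9", "Y@9")]), c(0.8, 0.2), tolerance = 1e-12)
})

test_that("a 90/10 descendant split drops the minor edge below the cutoff", {
  fx <- split_fixture(0.9)
  g <- build_lineage_graph(fx$maps, fx$clusters, min_cells = 10, edge_cutoff = 0.15)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$target, "X@9")
  expect_equal(g$edges$weight, 0.9, tolerance = 1e-12)
})

test_that("clusters under the minimum cell count are removed before weighting", {
  fx <- split_fixture(0.8)
  # shrink cluster Y to 9 cells (below min_cells = 10)
  gone <- c("y10", "y11", "y12")
  cl <- fx$clusters[!fx$clusters$barcode %in% gone, ]
  g0 <- fx$maps[[1]]$gamma[, !colnames(fx$maps[[1]]$gamma) %in% gone]
  maps <- list(fixture_map(g0, 6, 9, rownames(g0), colnames(g0)))
  g <- build_lineage_graph(maps, cl, min_cells = 10, edge_cutoff = 0.15)
  expect_false(any(grepl("^Y@", g$nodes$id)))
  # with Y gone, all of P's surviving mass flows to X
  expect_equal(g$edges$weight, 1, tolerance = 1e-12)
})

test_that("edge F1 is 1 on identical graphs and 0 on disjoint ones", {
  nodes <- data.frame(id = c("a@6", "b@9"), cluster = c("a", "b"),
                      timepoint = c(6, 9), n_cells = c(5L, 5L))
  e1 <- data.frame(source = "a@6", target = "b@9", weight = 1)
  g1 <- lineage_graph(nodes, e1)
  expect_equal(graph_edge_f1(g1, g1), 1)
  nodes2 <- data.frame(id = c("c@6", "d@9"), cluster = c("c", "d"),
                       timepoint = c(6, 9), n_cells = c(5L, 5L))
  g2 <- lineage_graph(nodes2, data.frame(source = "c@6", target = "d@9", weight = 1))
  expect_equal(graph_edge_f1(g1, g2), 0)
})

test_that("edge F1 maps arbitrary cluster labels through majority lineages", {
  nodes_p <- data.frame(id = c("0@6", "1@9"), cluster = c("0", "1"),
                        timepoint = c(6, 9), n_cells = c(3L, 3L))
  pred <- lineage_graph(nodes_p,
                        data.frame(source = "0@6", target = "1@9", weight = 1))
  nodes_t <- data.frame(id = c("root@6", "ecto@9"), cluster = c("root", "ecto"),
                        timepoint = c(6, 9), n_cells = c(3L, 3L))
  truth <- lineage_graph(nodes_t,
                         data.frame(source = "root@6", target = "ecto@9", weight = 1))
  lin <- data.frame(barcode = c("b1", "b2", "b3", "b4"),
                    lineage = c("root", "root", "ecto", "ecto"))
  asg <- data.frame(barcode = c("b1", "b2", "b3", "b4"),
                    cluster_id = c("0", "0", "1", "1"))
  expect_equal(graph_edge_f1(pred, truth, lin, asg), 1)
})
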