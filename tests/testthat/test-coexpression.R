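mk_profile <- function(tp, n_total, n_low, n_high, regulator = "r", target = "t",
                       species = "A") {
  df <- data.frame(timepoint_hpf = tp, n_total_cells = n_total,
                   n_coexpressing = n_low + n_high, n_low = n_low,
                   n_high = n_high, proportion = (n_low + n_high) / n_total)
  structure(df, class = c("CoexpressionProfile", "data.frame"),
            regulator = regulator, target = target, species = species,
            genes_present = c(regulator = TRUE, target = TRUE))
}

test_that("cell-level co-expression classes follow the read-count definition", {
  expect_equal(classify_cell_coexpression(0, 3), "none")
  expect_equal(classify_cell_coexpression(1, 4), "low")
  expect_equal(classify_cell_coexpression(2, 2), "high")
  expect_equal(classify_cell_coexpression(c(0, 1, 2, 5, 1), c(3, 1, 2, 0, 4)),
               c("none", "low", "high", "none", "low"))
  expect_error(classify_cell_coexpression(-1, 2), "nonnegative")
})

test_that("increasing a UMI count never demotes the co-expression class", {
  rank <- c(none = 0, low = 1, high = 2)
  set.seed(40)
  for (k in 1:200) {
    a <- rpois(1, 2); b <- rpois(1, 2)
    base <- rank[classify_cell_coexpression(a, b)]
    expect_gte(rank[classify_cell_coexpression(a + 1, b)], base)
    expect_gte(rank[classify_cell_coexpression(a, b + 1)], base)
  }
})

test_that("the five-cell worked example tallies 3 co-expressing cells", {
  m <- rbind(rA = c(0, 1, 2, 5, 1),
             rB = c(3, 1, 2, 0, 4))
  cm <- count_matrix(m, c("rA", "rB"), paste0("c", 1:5), "A", 10)
  prof <- coexpression_timecourse(list(cm), "rA", "rB")
  expect_equal(prof$n_coexpressing, 3)
  expect_equal(prof$n_low, 2)
  expect_equal(prof$n_high, 1)
  expect_equal(prof$proportion, 0.6)
})

test_that("time-course tallies equal a brute-force double-loop recount", {
  set.seed(41)
  for (k in 1:5) {
    m <- matrix(rpois(20 * 200, 0.7), 20, 200)
    cm <- count_matrix(m, paste0("g", 1:20), paste0("c", 1:200), "A", k)
    prof <- coexpression_timecourse(list(cm), "g3", "g7")
    o <- oracle_coexpr_counts(m[3, ], m[7, ])
    expect_equal(prof$n_low, o$n_low)
    expect_equal(prof$n_high, o$n_high)
    expect_equal(prof$n_coexpressing, o$n_coexpressing)
    expect_equal(prof$proportion, o$n_coexpressing / 200)
  }
})

test_that("absent genes give zero-count profiles with a warning", {
  cm <- count_matrix(matrix(1, 2, 3), c("g1", "g2"), paste0("c", 1:3), "A", 6)
  expect_warning(prof <- coexpression_timecourse(list(cm), "g1", "missing"),
                 "absent")
  expect_equal(prof$n_coexpressing, 0)
  expect_false(attr(prof, "genes_present")[["target"]])
})

test_that("overlay rows agree with the profile counts at each timepoint", {
  set.seed(42)
  m <- matrix(rpois(10 * 50, 0.8), 10, 50)
  cm <- count_matrix(m, paste0("g", 1:10), paste0("c", 1:50), "A", 12)
  coords <- matrix(rnorm(100), 50, 2, dimnames = list(paste0("c", 1:50), NULL))
  ov <- coexpression_overlay(list(cm), "g1", "g2", coords)
  prof <- coexpression_timecourse(list(cm), "g1", "g2")
  expect_equal(sum(ov$class == "low"), prof$n_low)
  expect_equal(sum(ov$class == "high"), prof$n_high)
  expect_equal(nrow(ov), 50)
  expect_error(coexpression_overlay(list(cm), "g1", "g2", coords[1:10, , drop = FALSE]),
               "missing coords")
})

test_that("identical profiles in both species are called conserved", {
  P <- mk_profile(c(6, 9, 12), 100, c(0, 3, 5), c(0, 4, 9))
  supp <- c(regulator = 50L, target = 50L)
  lins <- c(ecto = "ecto")
  cl <- c(ecto = 12L)
  call <- classify_interaction(P, P, supp, supp, cl, cl,
                               homologous_cluster_map = lins)
  expect_s3_class(call, "InteractionCall")
  expect_equal(call$label, "conserved")
  expect_equal(call$evidence$onset_A, call$evidence$onset_B)
})

test_that("species relabeling swaps lost and novel but fixes the others", {
  gone <- mk_profile(c(6, 9, 12), 100, c(0, 0, 1), c(0, 0, 0))
  there <- mk_profile(c(6, 9, 12), 100, c(0, 3, 5), c(0, 6, 9))
  supp <- c(regulator = 60L, target = 60L)
  lins <- c(ecto = "ecto"); cl <- c(ecto = 10L)
  lost <- classify_interaction(there, gone, supp, supp, cl, cl,
                               homologous_cluster_map = lins)
  novel <- classify_interaction(gone, there, supp, supp, cl, cl,
                                homologous_cluster_map = lins)
  expect_equal(lost$label, "lost")
  expect_equal(novel$label, "novel")
})

test_that("weak expression support yields indeterminate, not lost", {
  gone <- mk_profile(c(6, 9), 100, c(0, 0), c(0, 0))
  there <- mk_profile(c(6, 9), 100, c(2, 6), c(1, 8))
  call <- classify_interaction(there, gone,
                               c(regulator = 50L, target = 50L),
                               c(regulator = 50L, target = 5L))  # target barely expressed in B
  expect_equal(call$label, "indeterminate")
})

test_that("onset differences at or beyond the threshold are temporal shifts", {
  early <- mk_profile(c(6, 9, 12, 16, 20), 200, c(0, 4, 6, 6, 6), c(0, 8, 10, 10, 10))
  late <- mk_profile(c(6, 9, 12, 16, 20), 200, c(0, 0, 0, 4, 6), c(0, 0, 0, 8, 10))
  supp <- c(regulator = 80L, target = 80L)
  call <- classify_interaction(early, late, supp, supp)
  expect_equal(call$label, "shifted_temporal")
  expect_equal(call$evidence$onset_A, 9)
  expect_equal(call$evidence$onset_B, 16)
  # a known global developmental offset is discounted before the comparison
  call2 <- classify_interaction(early, late, supp, supp, global_offset_hours = 7)
  expect_equal(call2$label, "conserved")
})

test_that("disjoint co-expressing territories are spatial shifts", {
  P <- mk_profile(c(6, 9, 12), 150, c(0, 4, 6), c(0, 7, 10))
  supp <- c(regulator = 70L, target = 70L)
  hom <- c(ecto = "ecto", endo = "endo")
  call <- classify_interaction(P, P, supp, supp,
                               coexpr_clusters_A = c(ecto = 15L),
                               coexpr_clusters_B = c(endo = 14L),
                               homologous_cluster_map = hom)
  expect_equal(call$label, "shifted_spatial")
  expect_equal(call$evidence$cluster_overlap, 0)
  # half-overlapping distributions at the 0.5 boundary remain conserved
  call2 <- classify_interaction(P, P, supp, supp,
                                coexpr_clusters_A = c(ecto = 10L, endo = 10L),
                                coexpr_clusters_B = c(ecto = 10L, endo = 10L),
                                homologous_cluster_map = hom)
  expect_equal(call2$label, "conserved")
  # no homology map: spatial test skipped with a flag
  expect_warning(call3 <- classify_interaction(P, P, supp, supp,
                                               coexpr_clusters_A = c(ecto = 15L),
                                               coexpr_clusters_B = c(endo = 14L)),
                 "spatial test skipped")
  expect_true(call3$evidence$spatial_test_skipped)
  expect_equal(call3$label, "conserved")
})

test_that("expression and cluster tallies match direct recounts", {
  set.seed(43)
  m1 <- matrix(rpois(4 * 30, 0.9), 4, 30,
               dimnames = list(c("r", "t", "g3", "g4"), paste0("c", 1:30)))
  cm <- count_matrix(m1, rownames(m1), colnames(m1), "A", 6)
  cnt <- count_expressing_cells(list(cm), "r", "t")
  expect_equal(cnt[["regulator"]], sum(m1["r", ] >= 1))
  expect_equal(cnt[["target"]], sum(m1["t", ] >= 1))
  clusters <- setNames(rep(c("u", "w"), each = 15), paste0("c", 1:30))
  cc <- coexpression_cluster_counts(list(cm), "r", "t", clusters)
  co <- m1["r", ] >= 1 & m1["t", ] >= 1
  expect_equal(unname(cc["u"]), sum(co[1:15]))
  expect_equal(unname(cc["w"]), sum(co[16:30]))
  expect_equal(sum(cc), sum(co))
  maj <- majority_coexpression_cluster(list(cm), "r", "t", clusters)
  expect_equal(maj, names(which.max(cc)))
})
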