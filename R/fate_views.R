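#' Barycentric (triangle) projection of fate probabilities
#'
#' Collapses each cell's fate distribution to three coordinates — fate A,
#' fate B, and everything else — and places it in an equilateral triangle
#' (fate A at the top vertex, fate B at the right, "other" at the bottom
#' left). A cell is called committed to the fate whose probability reaches
#' the threshold (published value 0.7), otherwise uncommitted.
#'
#' @param fates a `FateMatrix`.
#' @param fate_A,fate_B two distinct fate names present in `fates`.
#' @param threshold commitment threshold in (0.5, 1].
#' @return data.frame: barcode, p_fate_A, p_fate_B, p_other, committed_to,
#'   x, y (triangle plot coordinates).
#' @export
triangle_projection <- function(fates, fate_A, fate_B, threshold = 0.7) {
  stopifnot(inherits(fates, "FateMatrix"))
  if (fate_A == fate_B) stop("fate_A and fate_B must differ")
  if (!all(c(fate_A, fate_B) %in% fates$fate_names))
    stop("unknown fate name(s): ",
         paste(setdiff(c(fate_A, fate_B), fates$fate_names), collapse = ", "))
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  P <- fates$probs
  pA <- P[, fate_A]
  pB <- P[, fate_B]
  pO <- rowSums(P[, setdiff(colnames(P), c(fate_A, fate_B)), drop = FALSE])
  tot <- pA + pB + pO
  ok <- tot > 1e-12
  pA[ok] <- pA[ok] / tot[ok]; pB[ok] <- pB[ok] / tot[ok]; pO[ok] <- pO[ok] / tot[ok]
  committed <- rep("uncommitted", nrow(P))
  committed[pA >= threshold] <- fate_A
  committed[pB >= threshold] <- fate_B
  committed[pO >= threshold] <- "other"
  # vertices: A top, B right, other bottom-left (equilateral, side 1)
  vA <- c(0.5, sqrt(3) / 2); vB <- c(1, 0); vO <- c(0, 0)
  x <- pA * vA[1] + pB * vB[1] + pO * vO[1]
  y <- pA * vA[2] + pB * vB[2] + pO * vO[2]
  data.frame(barcode = rownames(P), p_fate_A = pA, p_fate_B = pB,
             p_other = pO, committed_to = committed, x = x, y = y,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a lineage tree from transport maps and cluster labels
#'
#' For each consecutive pair of time points, the edge weight from cluster i
#' to cluster j is the fraction of i's transported descendant mass that
#' lands in j: `w(i,j) = sum_{x in i, y in j} gamma[x,y] / sum_{x in i}
#' gamma[x,.]` (mass-weighted, using the growth-adjusted couplings as
#' solved). Clusters with fewer than `min_cells` cells at a time point are
#' removed before weights are computed; edges below `edge_cutoff` are
#' removed after. The published cutoffs are 10 cells and 0.15.
#'
#' @param maps list of `TransportMap` with barcode provenance.
#' @param clusters data.frame with columns barcode, timepoint_hpf, and a
#'   cluster column (`cluster_id` or `cell_type`).
#' @param min_cells minimum cluster size per time point.
#' @param edge_cutoff minimal retained edge weight.
#' @param cluster_col which column of `clusters` labels cells.
#' @return a `LineageGraph`; node ids are "<cluster>@<timepoint>".
#' @export
build_lineage_graph <- function(maps, clusters, min_cells = 10, edge_cutoff = 0.15,
                                cluster_col = "cluster_id") {
  stopifnot(is.data.frame(clusters),
            all(c("barcode", "timepoint_hpf", cluster_col) %in% names(clusters)))
  lab <- setNames(as.character(clusters[[cluster_col]]), clusters$barcode)
  nodes <- list(); edges <- list()
  seen_nodes <- character(0)
  for (m in maps) {
    if (is.null(m$source_barcodes) || is.null(m$target_barcodes))
      stop("transport maps must carry barcode provenance")
    src_lab <- lab[m$source_barcodes]
    tgt_lab <- lab[m$target_barcodes]
    if (anyNA(src_lab) || anyNA(tgt_lab))
      stop("cluster labels missing for some cells in maps")
    # node filtering: clusters under min_cells are dropped, their cells excluded
    src_keep_cl <- names(which(table(src_lab) >= min_cells))
    tgt_keep_cl <- names(which(table(tgt_lab) >= min_cells))
    si <- src_lab %in% src_keep_cl
    ti <- tgt_lab %in% tgt_keep_cl
    if (!any(si) || !any(ti)) {
      warning("no surviving clusters at ", m$source_timepoint, " -> ",
              m$target_timepoint, " hpf; graph discontinuity")
      next
    }
    g <- m$gamma[si, ti, drop = FALSE]
    sl <- src_lab[si]; tl <- tgt_lab[ti]
    for (tp_side in list(list(t = m$source_timepoint, labs = sl),
                         list(t = m$target_timepoint, labs = tl))) {
      for (cl in unique(tp_side$labs)) {
        id <- paste0(cl, "@", tp_side$t)
        if (!id %in% seen_nodes) {
          seen_nodes <- c(seen_nodes, id)
          nodes[[length(nodes) + 1L]] <- data.frame(
            id = id, cluster = cl, timepoint = tp_side$t,
            n_cells = sum(tp_side$labs == cl), stringsAsFactors = FALSE)
        }
      }
    }
    # mass by (source cluster, target cluster)
    agg <- rowsum(t(rowsum(g, sl)), tl)   # clusters_t x clusters_s
    agg <- t(agg)                         # clusters_s x clusters_t
    w <- agg / rowSums(agg)
    for (i in rownames(w)) for (j in colnames(w)) {
      if (w[i, j] >= edge_cutoff)
        edges[[length(edges) + 1L]] <- data.frame(
          source = paste0(i, "@", m$source_timepoint),
          target = paste0(j, "@", m$target_timepoint),
          weight = w[i, j], stringsAsFactors = FALSE)
    }
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes) else
    data.frame(id = character(), cluster = character(),
               timepoint = numeric(), n_cells = integer())
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(), weight = numeric())
  lineage_graph(nodes, edges)
}

#' Edge-set F1 between a predicted and a true lineage graph
#'
#' Clusters of the predicted graph are mapped to lineage names by majority
#' vote over a barcode -> true-lineage table, then the two edge sets
#' (parent lineage @ t -> child lineage @ t') are compared by F1. Clusters
#' that cannot be mapped are counted as mismatches with a warning.
#'
#' @param predicted `LineageGraph` whose clusters are arbitrary labels.
#' @param truth `LineageGraph` with lineage names as clusters (e.g. from
#'   [truth_lineage_tree()]).
#' @param cell_lineages data.frame with columns barcode, lineage (the
#'   simulator truth); NULL when predicted clusters already use lineage names.
#' @param cluster_assignment data.frame with columns barcode and the
#'   predicted cluster label column `cluster_id`; required with
#'   `cell_lineages`.
#' @return F1 in [0,1].
#' @export
graph_edge_f1 <- function(predicted, truth, cell_lineages = NULL,
                          cluster_assignment = NULL) {
  stopifnot(inherits(predicted, "LineageGraph"), inherits(truth, "LineageGraph"))
  map_cluster <- identity
  if (!is.null(cell_lineages)) {
    stopifnot(!is.null(cluster_assignment))
    tab <- merge(cluster_assignment[, c("barcode", "cluster_id")],
                 cell_lineages[, c("barcode", "lineage")], by = "barcode")
    maj <- tapply(tab$lineage, as.character(tab$cluster_id),
                  function(v) names(sort(table(v), decreasing = TRUE))[1])
    map_cluster <- function(cl) {
      out <- maj[cl]
      if (anyNA(out)) warning("unmappable cluster(s): ",
                              paste(unique(cl[is.na(out)]), collapse = ", "))
      ifelse(is.na(out), paste0("?", cl), out)
    }
  }
  canon <- function(g, mapfun) {
    if (!nrow(g$edges)) return(character(0))
    nd <- setNames(g$nodes$cluster, g$nodes$id)
    tp <- setNames(g$nodes$timepoint, g$nodes$id)
    unique(paste0(mapfun(nd[g$edges$source]), "@", tp[g$edges$source], "->",
                  mapfun(nd[g$edges$target]), "@", tp[g$edges$target]))
  }
  pe <- canon(predicted, map_cluster)
  te <- canon(truth, identity)
  if (!length(pe) && !length(te)) return(1.0)
  tp_n <- length(intersect(pe, te))
  prec <- if (length(pe)) tp_n / length(pe) else 0
  rec <- if (length(te)) tp_n / length(te) else 0
  if (prec + rec == 0) return(0.0)
  2 * prec * rec / (prec + rec)
}
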