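#' Restrict two count matrices to 1:1 ortholog pairs
#'
#' Both matrices are reduced to the genes present in the ortholog map, with
#' rows ordered identically by pair index so row g of one species is the
#' ortholog of row g of the other. Pairs referencing a gene absent from
#' either matrix are dropped with a warning.
#'
#' @param cmA,cmB `CountMatrix` objects for species A and B.
#' @param om an `OrthologMap` (columns gene_a, gene_b).
#' @return list of two `CountMatrix` objects (A, B) with matched rows.
#' @export
restrict_to_orthologs <- function(cmA, cmB, om) {
  stopifnot(inherits(cmA, "CountMatrix"), inherits(cmB, "CountMatrix"),
            inherits(om, "OrthologMap"))
  ia <- match(om$gene_a, cmA$gene_ids)
  ib <- match(om$gene_b, cmB$gene_ids)
  keep <- !is.na(ia) & !is.na(ib)
  if (!all(keep))
    warning(sum(!keep), " ortholog pair(s) dropped: gene absent from a matrix")
  if (!any(keep)) stop("no ortholog pairs shared by both matrices")
  ia <- ia[keep]; ib <- ib[keep]
  list(
    A = count_matrix(cmA$counts[ia, , drop = FALSE], cmA$gene_ids[ia],
                     cmA$barcodes, cmA$species, cmA$timepoint_hpf),
    B = count_matrix(cmB$counts[ib, , drop = FALSE], cmB$gene_ids[ib],
                     cmB$barcodes, cmB$species, cmB$timepoint_hpf))
}

#' Joint embedding of two species in shared ortholog gene space
#'
#' A simplified cross-species integration: both (ortholog-restricted,
#' per-gene standardized) expression matrices are projected on one shared
#' set of gene-space directions, the top-k right singular vectors of the
#' stacked cells x genes matrix. Identical datasets map to identical
#' coordinates, and the embedding is invariant to a common gene permutation.
#' Sign convention as in [embed_pca()].
#'
#' @param normA,normB genes x cells matrices on matched ortholog rows.
#' @param k number of shared directions (<= gene count).
#' @param standardize center/scale each gene across the pooled cells.
#' @return list of two `EmbeddingMatrix` objects (A, B) sharing `basis`,
#'   plus `singular_values` of the stacked matrix.
#' @export
joint_embedding_cca <- function(normA, normB, k = 30, standardize = TRUE) {
  if (nrow(normA) != nrow(normB)) stop("matrices must share ortholog rows")
  if (k > nrow(normA)) stop("k exceeds gene count")
  X <- t(cbind(normA, normB))          # pooled cells x genes
  if (standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    sdv[sdv < 1e-12] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  }
  sv <- svd(X, nu = 0, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  basis <- sv$v %*% diag(flip, k)
  rownames(basis) <- rownames(normA)
  nA <- ncol(normA)
  coords <- X %*% basis
  make_emb <- function(cc, src) {
    rownames(cc) <- colnames(src)
    structure(list(coords = cc, basis = basis, d = k,
                   sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(X) - 1)),
                   provenance = "ortholog-restricted joint gene-space SVD"),
              class = "EmbeddingMatrix")
  }
  list(A = make_emb(coords[seq_len(nA), , drop = FALSE], normA),
       B = make_emb(coords[-seq_len(nA), , drop = FALSE], normB),
       singular_values = sv$d[seq_len(k)])
}

#' Earth mover distance between two weighted point clouds
#'
#' Exact optimal-transport cost (linear program, Euclidean ground metric)
#' between two clouds in a shared embedding space. Weights are renormalized
#' to sum to 1. Clouds larger than `max_points` are down-sampled
#' (weight-proportional, fixed seed) before the exact solve.
#'
#' @param points_x,points_y point coordinate matrices (rows = points).
#' @param w_x,w_y nonnegative weights (default uniform).
#' @param max_points size cap per cloud before down-sampling.
#' @param seed down-sampling seed.
#' @return nonnegative scalar EMD.
#' @export
emd <- function(points_x, points_y, w_x = NULL, w_y = NULL,
                max_points = 2000L, seed = 1L) {
  px <- as.matrix(points_x); py <- as.matrix(points_y)
  if (nrow(px) == 0 || nrow(py) == 0) stop("empty cloud")
  if (is.null(w_x)) w_x <- rep(1, nrow(px))
  if (is.null(w_y)) w_y <- rep(1, nrow(py))
  if (any(w_x < 0) || any(w_y < 0)) stop("weights must be nonnegative")
  if (sum(w_x) <= 0 || sum(w_y) <= 0) stop("weights must have positive sum")
  ds <- function(p, w, sd_off) {
    keep <- w > 0
    p <- p[keep, , drop = FALSE]; w <- w[keep]
    if (nrow(p) > max_points) {
      set.seed(seed + sd_off)
      idx <- sample.int(nrow(p), max_points, prob = w)
      p <- p[idx, , drop = FALSE]; w <- rep(1, max_points)
    }
    list(p = p, w = w / sum(w))
  }
  X <- ds(px, w_x, 0L); Y <- ds(py, w_y, 1L)
  # direct (cancellation-free) Euclidean distances: the expanded
  # a^2 + b^2 - 2ab form loses precision for near-identical points
  nx <- nrow(X$p)
  D <- as.matrix(dist(rbind(X$p, Y$p)))[seq_len(nx), nx + seq_len(nrow(Y$p)),
                                        drop = FALSE]
  res <- .emd_simplex(D, X$w, Y$w)
  if (!res$converged) warning("EMD simplex hit iteration cap; cost may be approximate")
  res$cost
}

#' Align developmental time courses across species by earth mover distance
#'
#' For each terminal lineage/fate, cells at every time point of each species
#' are weighted by their fate probability toward that lineage (renormalized
#' within species and time point) and compared in the shared joint embedding
#' by exact EMD, giving a |T_A| x |T_B| matrix per lineage. For every
#' species-A time point the best pair is the species-B time point of
#' minimal EMD (ties broken toward the earliest B time point).
#'
#' @param coordsA,coordsB cells x d coordinates in the shared embedding,
#'   rownames = barcodes.
#' @param cellsA,cellsB data.frames with columns barcode, timepoint_hpf.
#' @param fatesA,fatesB `FateMatrix` objects computed against each species'
#'   own final time point.
#' @param lineage_fate_map named character vector: names are fate names in
#'   `fatesA`, values the homologous fate names in `fatesB` (defaults to the
#'   shared fate names).
#' @param max_points,seed passed to [emd()].
#' @param min_weight time points whose total fate weight falls below this
#'   are flagged missing and excluded from best pairs.
#' @return list of `AlignmentResult` (one per lineage): list with
#'   `cell_lineage`, `emd` matrix (rows = A timepoints, cols = B
#'   timepoints; NA where flagged), `best_pairs` data.frame
#'   (timepoint_A, timepoint_B), and `offsets` (timepoint_B - timepoint_A).
#' @export
align_timecourses <- function(coordsA, coordsB, cellsA, cellsB, fatesA, fatesB,
                              lineage_fate_map = NULL, max_points = 2000L,
                              seed = 1L, min_weight = 1e-6) {
  stopifnot(inherits(fatesA, "FateMatrix"), inherits(fatesB, "FateMatrix"))
  if (is.null(lineage_fate_map)) {
    shared <- intersect(fatesA$fate_names, fatesB$fate_names)
    lineage_fate_map <- setNames(shared, shared)
  }
  tA <- sort(unique(cellsA$timepoint_hpf))
  tB <- sort(unique(cellsB$timepoint_hpf))
  out <- list()
  for (fa in names(lineage_fate_map)) {
    fb <- lineage_fate_map[[fa]]
    wA <- fatesA$probs[, fa]
    wB <- fatesB$probs[, fb]
    M <- matrix(NA_real_, length(tA), length(tB),
                dimnames = list(as.character(tA), as.character(tB)))
    cloud <- function(coords, cells, w, t) {
      bcs <- cells$barcode[cells$timepoint_hpf == t]
      bcs <- intersect(bcs, rownames(coords))
      ww <- w[bcs]
      ww[is.na(ww)] <- 0
      list(p = coords[bcs, , drop = FALSE], w = ww)
    }
    for (i in seq_along(tA)) {
      ca <- cloud(coordsA, cellsA, wA, tA[i])
      if (sum(ca$w) < min_weight) next
      for (j in seq_along(tB)) {
        cb <- cloud(coordsB, cellsB, wB, tB[j])
        if (sum(cb$w) < min_weight) next
        M[i, j] <- emd(ca$p, cb$p, ca$w, cb$w, max_points = max_points,
                       seed = seed + 1000L * i + j)
      }
    }
    bp <- data.frame(timepoint_A = numeric(0), timepoint_B = numeric(0))
    for (i in seq_along(tA)) {
      row <- M[i, ]
      if (all(is.na(row))) next
      j <- which(row == min(row, na.rm = TRUE))[1]   # earliest B on ties
      bp <- rbind(bp, data.frame(timepoint_A = tA[i], timepoint_B = tB[j]))
    }
    out[[fa]] <- structure(list(cell_lineage = fa, emd = M, best_pairs = bp,
                                offsets = bp$timepoint_B - bp$timepoint_A),
                           class = "AlignmentResult")
  }
  out
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult '%s': %d x %d EMD matrix, median offset %s h\n",
              x$cell_lineage, nrow(x$emd), ncol(x$emd),
              if (length(x$offsets)) median(x$offsets) else NA))
  invisible(x)
}

#' Count of best pairs where species B lags species A
#'
#' The summary used for alignment line plots: how many aligned time-point
#' pairs fall above the slope-1 line (B time point later than A's).
#'
#' @param result an `AlignmentResult`.
#' @return integer count.
#' @export
pairs_above_diagonal <- function(result) {
  stopifnot(inherits(result, "AlignmentResult"))
  sum(result$best_pairs$timepoint_B > result$best_pairs$timepoint_A)
}
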