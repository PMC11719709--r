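#' QC-filter cells by detected genes and total UMIs
#'
#' Keeps exactly the cells with `n_genes_detected` strictly greater than
#' `min_genes`, strictly less than `max_genes`, and `total_umis` strictly
#' less than `max_counts` (strict inequalities, matching the published
#' nFeature_RNA > 200 / nFeature_RNA < 4,000 (or 7,000) / nCount_RNA <
#' 10,000 filters; the looser gene ceiling suits deeper planktotroph-style
#' libraries). Genes are unchanged.
#'
#' @param cm a `CountMatrix`.
#' @param min_genes,max_genes bounds on genes detected per cell.
#' @param max_counts bound on total UMIs per cell.
#' @return filtered `CountMatrix` (possibly with zero cells, with a warning).
#' @export
filter_cells <- function(cm, min_genes = 200, max_genes = 4000, max_counts = 10000) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (min_genes >= max_genes) stop("min_genes must be < max_genes")
  ng <- Matrix::colSums(cm$counts > 0)
  tu <- Matrix::colSums(cm$counts)
  keep <- ng > min_genes & ng < max_genes & tu < max_counts
  if (!any(keep)) warning("all cells removed by QC filter")
  tp <- if (length(cm$timepoint_hpf) == 1) cm$timepoint_hpf else cm$timepoint_hpf[keep]
  count_matrix(cm$counts[, keep, drop = FALSE], cm$gene_ids, cm$barcodes[keep],
               species = cm$species, timepoint_hpf = tp)
}

#' Log median-scaled counts-per-cell normalization
#'
#' A documented simple normalization standing in for variance-stabilizing
#' regression: `x[g,c] = log(1 + counts[g,c] * S / total_umis[c])` with `S`
#' the median per-cell total, i.e. every cell is rescaled to the median
#' library size before the log. Cell-to-cell depth differences cancel;
#' the global factor `S` keeps values on the scale of typical raw counts.
#' Co-expression analyses never use these values; they operate on raw UMIs.
#'
#' @param cm a `CountMatrix` with no zero-depth cells (filter first).
#' @return dense genes x cells numeric matrix with dimnames.
#' @export
normalize_log_cpm <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  tu <- Matrix::colSums(cm$counts)
  if (any(tu == 0))
    stop("zero-depth cell(s): ", paste(head(cm$barcodes[tu == 0], 5), collapse = ", "))
  S <- median(tu)
  m <- as.matrix(cm$counts)
  log1p(sweep(m, 2, S / tu, `*`))
}

#' Select highly variable genes
#'
#' Returns the indices of the `n_top` genes with the highest variance of
#' normalized expression across cells; ties broken by gene id (lexicographic).
#'
#' @param norm genes x cells numeric matrix with rownames.
#' @param n_top number of genes to select.
#' @return integer vector of row indices, ordered by decreasing variance.
#' @export
select_variable_genes <- function(norm, n_top) {
  if (n_top > nrow(norm)) stop("n_top exceeds gene count")
  v <- apply(norm, 1, var)
  ids <- rownames(norm)
  if (is.null(ids)) ids <- sprintf("row%06d", seq_len(nrow(norm)))
  ord <- order(-v, ids)
  ord[seq_len(n_top)]
}

#' Principal-component embedding
#'
#' Centers genes and projects cells on the top right singular vectors of the
#' cells x genes matrix. Deterministic sign convention: the largest-magnitude
#' loading of each component is positive.
#'
#' @param norm genes x cells numeric matrix.
#' @param n_pcs number of components, at most min(genes, cells).
#' @return object of class `EmbeddingMatrix`: list with `coords` (cells x d),
#'   `basis` (genes x d loadings), `d`, `sdev` (singular values / sqrt(n-1)),
#'   `provenance`.
#' @export
embed_pca <- function(norm, n_pcs = 30) {
  if (n_pcs > min(dim(norm))) stop("n_pcs exceeds min(genes, cells)")
  x <- t(norm)                       # cells x genes
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  coords <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs) %*% diag(flip, n_pcs)
  basis <- sv$v %*% diag(flip, n_pcs)
  rownames(coords) <- colnames(norm)
  rownames(basis) <- rownames(norm)
  structure(list(coords = coords, basis = basis, d = n_pcs,
                 sdev = sv$d[seq_len(n_pcs)] / sqrt(max(1, nrow(x) - 1)),
                 provenance = "log-median-CPM, centered, SVD"),
            class = "EmbeddingMatrix")
}

#' Graph-based clustering of embedded cells
#'
#' Builds a k-nearest-neighbor graph (Euclidean distance in the embedding)
#' and partitions it by modularity-maximizing community detection (Louvain)
#' at the given resolution. Deterministic under a fixed seed.
#'
#' @param emb an `EmbeddingMatrix` (or plain cells x d matrix).
#' @param k_neighbors neighbors per cell (must be < number of cells).
#' @param resolution modularity resolution.
#' @param seed RNG seed.
#' @return integer cluster labels (0-based), one per cell.
#' @export
cluster_cells <- function(emb, k_neighbors = 15, resolution = 1.0, seed = 1L) {
  coords <- if (inherits(emb, "EmbeddingMatrix")) emb$coords else as.matrix(emb)
  n <- nrow(coords)
  if (n == 1) return(0L)
  if (k_neighbors >= n) stop("k_neighbors must be < number of cells")
  d <- as.matrix(dist(coords))
  if (all(d < 1e-12)) {
    warning("degenerate embedding: all points identical; single cluster")
    return(rep(0L, n))
  }
  # kNN edge list (mutualized by union)
  nn <- t(apply(d, 1, function(r) order(r)[2:(k_neighbors + 1)]))
  ei <- rep(seq_len(n), k_neighbors)
  ej <- as.vector(nn)
  und <- cbind(pmin(ei, ej), pmax(ei, ej))
  und <- unique(und)
  g <- igraph::graph_from_edgelist(und, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(cl)) - 1L
}
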