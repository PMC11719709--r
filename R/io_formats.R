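#' @useDynLib devoalign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as is
#' @importFrom stats median dist rlnorm rnbinom runif sd var setNames
#' @importFrom utils read.delim write.table head
NULL

#' Construct a sparse UMI count matrix with cell metadata
#'
#' The universal input container of the pipeline: a genes x cells sparse
#' integer matrix of UMI counts, carrying a species label and an hours
#' post-fertilization (hpf) time point, either one value shared by all cells
#' or one value per cell.
#'
#' @param counts sparse (or dense) genes x cells matrix of nonnegative
#'   integer UMI counts; coerced to `dgCMatrix`.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param barcodes character vector of unique cell barcodes (columns).
#' @param species single species label.
#' @param timepoint_hpf nonnegative numeric, length 1 or one per cell.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, gene_ids, barcodes, species = "unknown",
                         timepoint_hpf = NA_real_) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length (", length(gene_ids), ") != row count (", nrow(counts), ")")
  if (length(barcodes) != ncol(counts))
    stop("barcodes length (", length(barcodes), ") != column count (", ncol(counts), ")")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  x <- counts@x
  if (length(x) && (any(!is.finite(x)) || any(x < 0) || any(x != round(x))))
    stop("counts must be nonnegative integers")
  if (!length(timepoint_hpf) %in% c(1L, ncol(counts)))
    stop("timepoint_hpf must have length 1 or one value per cell")
  rownames(counts) <- gene_ids
  colnames(counts) <- barcodes
  structure(list(counts = counts,
                 gene_ids = as.character(gene_ids),
                 barcodes = as.character(barcodes),
                 species = as.character(species)[1],
                 timepoint_hpf = as.numeric(timepoint_hpf)),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  tp <- if (length(x$timepoint_hpf) == 1) x$timepoint_hpf else
    paste0(min(x$timepoint_hpf), "-", max(x$timepoint_hpf))
  cat(sprintf("CountMatrix: %d genes x %d cells, species '%s', %s hpf, %d nonzeros\n",
              nrow(x$counts), ncol(x$counts), x$species, tp,
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Per-cell QC statistics table
#'
#' One row per cell with the detected-gene count and total UMIs used by the
#' QC filter, plus species / time point / optional cluster and cell-type
#' annotations.
#'
#' @param cm a `CountMatrix`.
#' @param cluster_id optional integer cluster label per cell.
#' @param cell_type optional character cell-type label per cell.
#' @return data.frame with columns barcode, species, timepoint_hpf,
#'   cluster_id, cell_type, n_genes_detected, total_umis.
#' @export
cell_table <- function(cm, cluster_id = NULL, cell_type = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  n <- ncol(cm$counts)
  tp <- if (length(cm$timepoint_hpf) == 1) rep(cm$timepoint_hpf, n) else cm$timepoint_hpf
  data.frame(
    barcode = cm$barcodes,
    species = cm$species,
    timepoint_hpf = tp,
    cluster_id = if (is.null(cluster_id)) NA_integer_ else as.integer(cluster_id),
    cell_type = if (is.null(cell_type)) NA_character_ else as.character(cell_type),
    n_genes_detected = Matrix::colSums(cm$counts > 0),
    total_umis = Matrix::colSums(cm$counts),
    row.names = NULL, stringsAsFactors = FALSE)
}

.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.find_10x_file <- function(directory, stems) {
  for (s in stems) for (ext in c("", ".gz")) {
    p <- file.path(directory, paste0(s, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read a 10x-style MTX triplet directory
#'
#' Expects the standard triplet layout: `matrix.mtx[.gz]`, a gene/feature TSV
#' (`features.tsv` or `genes.tsv`, first column used as the id), and
#' `barcodes.tsv`. Gzipped files are read transparently.
#'
#' @param directory path containing the three files.
#' @param species,timepoint_hpf labels attached to the returned object.
#' @return a `CountMatrix` (genes x cells).
#' @export
read_10x_mtx <- function(directory, species = "unknown", timepoint_hpf = NA_real_) {
  mtx <- .find_10x_file(directory, "matrix.mtx")
  feat <- .find_10x_file(directory, c("features.tsv", "genes.tsv"))
  bc <- .find_10x_file(directory, "barcodes.tsv")
  if (is.null(mtx)) stop("format error: missing matrix.mtx[.gz] in ", directory)
  if (is.null(feat)) stop("format error: missing features.tsv/genes.tsv[.gz] in ", directory)
  if (is.null(bc)) stop("format error: missing barcodes.tsv[.gz] in ", directory)
  # cross-check declared nnz against the triplet count before parsing
  hdr <- .read_mtx_header(mtx)
  if (is.null(hdr)) stop("format error: malformed MTX header in ", mtx)
  con <- .open_maybe_gz(mtx)
  all_lines <- readLines(con); close(con)
  body <- all_lines[!startsWith(all_lines, "%") & nzchar(trimws(all_lines))]
  n_triplets <- length(body) - 1L  # first non-comment line is the size header
  if (n_triplets != hdr$nnz)
    stop("integrity error: MTX declares ", hdr$nnz, " entries but file has ",
         n_triplets, " triplet lines")
  m <- Matrix::readMM(mtx)
  genes <- read.delim(feat, header = FALSE, stringsAsFactors = FALSE, quote = "", comment.char = "")[[1]]
  bcs <- read.delim(bc, header = FALSE, stringsAsFactors = FALSE, quote = "", comment.char = "")[[1]]
  if (length(genes) != nrow(m))
    stop("integrity error: features TSV has ", length(genes),
         " rows but MTX declares ", nrow(m), " rows")
  if (length(bcs) != ncol(m))
    stop("integrity error: barcodes TSV has ", length(bcs),
         " rows but MTX declares ", ncol(m), " columns")
  count_matrix(m, genes, bcs, species = species, timepoint_hpf = timepoint_hpf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_mtx_header <- function(path) {
  con <- .open_maybe_gz(path); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) return(NULL)
    if (!startsWith(ln, "%")) break
  }
  v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  if (length(v) != 3) return(NULL)
  list(nrow = v[1], ncol = v[2], nnz = v[3])
}

#' Write a CountMatrix as a 10x-style MTX triplet directory
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` (optionally gzipped)
#' readable by [read_10x_mtx()]. Values are written as integers.
#'
#' @param cm a `CountMatrix`.
#' @param directory output directory (created if absent).
#' @param gzip write .gz files.
#' @export
write_10x_mtx <- function(cm, directory, gzip = FALSE) {
  stopifnot(inherits(cm, "CountMatrix"))
  x <- cm$counts@x
  if (length(x) && any(x != round(x))) stop("validation error: non-integer counts")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  mpath <- file.path(directory, paste0("matrix.mtx", ext))
  # write coordinate integer MTX by hand so the field type is integer
  tm <- as(cm$counts, "TsparseMatrix")
  con <- if (gzip) gzfile(mpath, "wt") else file(mpath, "wt")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(tm), ncol(tm), length(tm@x))), con)
  if (length(tm@x))
    writeLines(paste(tm@i + 1L, tm@j + 1L, as.integer(tm@x)), con)
  close(con)
  .write_tsv_col <- function(v, p) {
    con <- if (gzip) gzfile(p, "wt") else file(p, "wt")
    writeLines(v, con); close(con)
  }
  .write_tsv_col(cm$gene_ids, file.path(directory, paste0("features.tsv", ext)))
  .write_tsv_col(cm$barcodes, file.path(directory, paste0("barcodes.tsv", ext)))
  invisible(NULL)
}

#' Read a two-column 1:1 ortholog table
#'
#' TSV with one gene id per species per row; a header row is auto-detected
#' (kept only if its two fields recur nowhere else as ids, the usual
#' "geneA\tgeneB" header convention: we drop the first row when it does not
#' look like data, i.e. when requested via `header`, or when it duplicates
#' nothing and `header = NA` heuristics flag it).
#'
#' @param path TSV path (optionally gzipped).
#' @param header TRUE/FALSE, or NA to auto-detect (first row dropped when
#'   either field reappears nowhere and both look like column names).
#' @return an `OrthologMap`: data.frame with columns gene_a, gene_b.
#' @export
read_ortholog_table <- function(path, header = NA) {
  df <- tryCatch(read.delim(path, header = FALSE, stringsAsFactors = FALSE, quote = "", comment.char = ""),
                 error = function(e) data.frame())
  if (nrow(df) == 0) {
    warning("empty ortholog table: ", path)
    return(ortholog_map(character(), character()))
  }
  if (ncol(df) < 2) stop("ortholog table must have 2 columns: ", path)
  if (is.na(header)) {
    first <- tolower(as.character(df[1, 1:2]))
    header <- any(grepl("gene|ortho|species|^id", first))
  }
  if (isTRUE(header)) df <- df[-1, , drop = FALSE]
  ortholog_map(as.character(df[[1]]), as.character(df[[2]]))
}

#' Construct a 1:1 ortholog map
#'
#' @param gene_a,gene_b equal-length id vectors; each id may appear in at
#'   most one pair (the 1:1 constraint).
#' @return data.frame of class `OrthologMap`.
#' @export
ortholog_map <- function(gene_a, gene_b) {
  stopifnot(length(gene_a) == length(gene_b))
  dup_a <- unique(gene_a[duplicated(gene_a)])
  dup_b <- unique(gene_b[duplicated(gene_b)])
  if (length(dup_a) || length(dup_b))
    stop("validation error: 1:1 constraint violated; duplicated ids: ",
         paste(c(dup_a, dup_b), collapse = ", "))
  structure(data.frame(gene_a = as.character(gene_a),
                       gene_b = as.character(gene_b),
                       stringsAsFactors = FALSE),
            class = c("OrthologMap", "data.frame"))
}

#' Write a lineage graph as d3.js-style JSON
#'
#' Nodes carry `id`, `cluster`, `timepoint`, `n_cells`; links carry
#' `source`, `target`, `weight`. Weights are serialized at full precision.
#'
#' @param graph a `LineageGraph` (see [build_lineage_graph()]).
#' @param path output JSON file.
#' @export
write_lineage_graph <- function(graph, path) {
  stopifnot(inherits(graph, "LineageGraph"))
  obj <- list(
    nodes = if (nrow(graph$nodes)) graph$nodes else
      data.frame(id = character(), cluster = character(),
                 timepoint = numeric(), n_cells = integer()),
    links = if (nrow(graph$edges)) graph$edges[, c("source", "target", "weight")] else
      data.frame(source = character(), target = character(), weight = numeric()))
  jsonlite::write_json(obj, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' Read back a lineage graph written by [write_lineage_graph()]
#' @param path JSON file.
#' @return a `LineageGraph`.
#' @export
read_lineage_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(obj$links, stringsAsFactors = FALSE)
  if (!nrow(nodes)) nodes <- data.frame(id = character(), cluster = character(),
                                        timepoint = numeric(), n_cells = integer())
  if (!nrow(edges)) edges <- data.frame(source = character(), target = character(),
                                        weight = numeric())
  lineage_graph(nodes, edges)
}

#' Construct a lineage graph object
#'
#' @param nodes data.frame with columns id, cluster, timepoint, n_cells.
#' @param edges data.frame with columns source, target, weight (descendant
#'   fraction in [0,1]); edges connect consecutive time points only.
#' @return object of class `LineageGraph`.
#' @export
lineage_graph <- function(nodes, edges) {
  stopifnot(all(c("id", "cluster", "timepoint", "n_cells") %in% names(nodes)),
            all(c("source", "target", "weight") %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$weight < -1e-12 | edges$weight > 1 + 1e-12))
      stop("edge weights must lie in [0,1]")
    bad <- !(edges$source %in% nodes$id) | !(edges$target %in% nodes$id)
    if (any(bad)) stop("edges reference unknown nodes")
  }
  structure(list(nodes = nodes, edges = edges), class = "LineageGraph")
}

#' @export
print.LineageGraph <- function(x, ...) {
  cat(sprintf("LineageGraph: %d nodes, %d edges over %d timepoints\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$timepoint))))
  invisible(x)
}

#' Default pipeline configuration
#'
#' Houses the transport and tree parameters used throughout: entropic
#' regularization epsilon = 0.05, marginal relaxation lambda1 = 1 (source)
#' and lambda2 = 50 (target), 20 iterations of growth-rate learning, fate
#' commitment threshold 0.7, lineage-tree minimum cluster size 10 and edge
#' cutoff 0.15, and QC filter thresholds (strict inequalities).
#'
#' @param ... overrides of any default field.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_genes = 200L, max_genes = 4000L, max_counts = 10000L,
    epsilon = 0.05, lambda1 = 1, lambda2 = 50, growth_iters = 20L,
    fate_threshold = 0.7, tree_min_cells = 10L, tree_edge_cutoff = 0.15,
    n_pcs = 30L, k_neighbors = 15L, resolution = 1.0, n_hvg = 2000L,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$min_genes >= cfg$max_genes) stop("min_genes must be < max_genes")
  if (cfg$epsilon <= 0 || cfg$lambda1 <= 0 || cfg$lambda2 <= 0)
    stop("epsilon, lambda1, lambda2 must be positive")
  if (cfg$fate_threshold <= 0 || cfg$fate_threshold > 1)
    stop("fate_threshold must be in (0,1]")
  if (cfg$tree_edge_cutoff < 0 || cfg$tree_edge_cutoff > 1)
    stop("tree_edge_cutoff must be in [0,1]")
  structure(cfg, class = c("PipelineConfig", "list"))
}
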