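#' Classify a cell's co-expression of a gene pair from raw UMIs
#'
#' Two genes are co-expressed in a cell when at least 1 UMI of each is
#' present. Cells with only 1 UMI from one or both genes are "low"; cells
#' with at least 2 UMIs from both are "high" (moderate-to-high). Vectorized.
#'
#' @param umis_a,umis_b nonnegative integer UMI counts (recycled).
#' @return character vector in {"none", "low", "high"}.
#' @export
classify_cell_coexpression <- function(umis_a, umis_b) {
  if (any(umis_a < 0) || any(umis_b < 0)) stop("counts must be nonnegative")
  out <- rep("none", max(length(umis_a), length(umis_b)))
  a <- rep_len(umis_a, length(out)); b <- rep_len(umis_b, length(out))
  co <- a >= 1 & b >= 1
  out[co] <- "low"
  out[a >= 2 & b >= 2] <- "high"
  out
}

#' Per-time-point co-expression time course for a regulator-target pair
#'
#' Tallies, at each time point and from raw UMI counts, the cells with at
#' least one read from both genes, split into low and moderate-to-high
#' classes, normalized by the total cell count of the sample. Never uses
#' normalized expression.
#'
#' @param cms list of `CountMatrix`, one per time point.
#' @param regulator,target gene ids.
#' @return object of class `CoexpressionProfile`: data.frame with columns
#'   timepoint_hpf, n_total_cells, n_coexpressing, n_low, n_high,
#'   proportion; attributes `regulator`, `target`, `species`,
#'   `genes_present` (logical pair).
#' @export
coexpression_timecourse <- function(cms, regulator, target) {
  stopifnot(is.list(cms), length(cms) > 0)
  species <- cms[[1]]$species
  present <- c(regulator = all(vapply(cms, function(cm) regulator %in% cm$gene_ids, logical(1))),
               target = all(vapply(cms, function(cm) target %in% cm$gene_ids, logical(1))))
  rows <- lapply(cms, function(cm) {
    n <- ncol(cm$counts)
    if (n == 0) stop("timepoint with 0 cells at ",
                     if (length(cm$timepoint_hpf) == 1) cm$timepoint_hpf else NA)
    tp <- if (length(cm$timepoint_hpf) == 1) cm$timepoint_hpf else cm$timepoint_hpf[1]
    if (!all(present)) {
      return(data.frame(timepoint_hpf = tp, n_total_cells = n,
                        n_coexpressing = 0L, n_low = 0L, n_high = 0L,
                        proportion = 0))
    }
    ua <- as.vector(cm$counts[regulator, ])
    ub <- as.vector(cm$counts[target, ])
    cls <- classify_cell_coexpression(ua, ub)
    n_low <- sum(cls == "low"); n_high <- sum(cls == "high")
    data.frame(timepoint_hpf = tp, n_total_cells = n,
               n_coexpressing = n_low + n_high, n_low = n_low,
               n_high = n_high, proportion = (n_low + n_high) / n)
  })
  if (!all(present))
    warning("gene(s) absent from matrices: ",
            paste(names(present)[!present], collapse = ", "),
            "; zero counts reported")
  df <- do.call(rbind, rows)
  df <- df[order(df$timepoint_hpf), ]
  rownames(df) <- NULL
  structure(df, class = c("CoexpressionProfile", "data.frame"),
            regulator = regulator, target = target, species = species,
            genes_present = present)
}

#' Co-expression overlay table for embedding scatter plots
#'
#' One row per cell with its 2-D coordinates, co-expression class at its
#' own time point, and cluster — the table behind three-tone overlay plots
#' (gray none / light low / dark high).
#'
#' @param cms list of `CountMatrix` (the same set the profile used).
#' @param regulator,target gene ids.
#' @param coords cells x 2 matrix with barcode rownames.
#' @param clusters named vector or data.frame(barcode, cluster_id).
#' @return data.frame: barcode, x, y, class, cluster, timepoint_hpf.
#' @export
coexpression_overlay <- function(cms, regulator, target, coords, clusters = NULL) {
  if (is.data.frame(clusters))
    clusters <- setNames(as.character(clusters$cluster_id), clusters$barcode)
  rows <- lapply(cms, function(cm) {
    miss <- setdiff(cm$barcodes, rownames(coords))
    if (length(miss))
      stop("missing coords for barcodes: ", paste(head(miss, 5), collapse = ", "),
           if (length(miss) > 5) " ..." else "")
    cls <- if (all(c(regulator, target) %in% cm$gene_ids))
      classify_cell_coexpression(as.vector(cm$counts[regulator, ]),
                                 as.vector(cm$counts[target, ]))
    else rep("none", ncol(cm$counts))
    tp <- if (length(cm$timepoint_hpf) == 1) cm$timepoint_hpf else cm$timepoint_hpf[1]
    data.frame(barcode = cm$barcodes,
               x = coords[cm$barcodes, 1], y = coords[cm$barcodes, 2],
               class = cls,
               cluster = if (is.null(clusters)) NA_character_ else
                 unname(clusters[cm$barcodes]),
               timepoint_hpf = tp, row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default thresholds for interaction-evolution classification
#'
#' The decision cascade's tunables: minimum cells expressing each gene for
#' support, the stray-cell allowance for a "lost" call, the minimum
#' sustained co-expression proportion and high-cell count defining a
#' signal, the minimum onset difference for a temporal shift, and the
#' minimum homologous-cluster overlap before a spatial shift is called.
#'
#' @param ... overrides.
#' @return named list.
#' @export
interaction_params <- function(...) {
  p <- list(min_expressing_cells = 20L, max_stray_low_cells = 2L,
            min_signal_prop = 0.005, min_high_cells = 5L,
            min_shift_hours = 4, min_cluster_overlap = 0.5)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown params: ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

# earliest timepoint with proportion >= thr sustained for >= 1 subsequent
# timepoint (or reaching the final timepoint)
.coexpr_onset <- function(profile, thr) {
  p <- profile$proportion >= thr
  n <- length(p)
  for (i in seq_len(n)) {
    if (p[i] && (i == n || p[i + 1])) return(profile$timepoint_hpf[i])
  }
  NA_real_
}

# does the species show a supported co-expression signal?
.coexpr_signal <- function(profile, params) {
  any(profile$proportion >= params$min_signal_prop &
        profile$n_high >= params$min_high_cells)
}

#' Classify the evolutionary status of a regulatory interaction
#'
#' Cross-species decision cascade over two co-expression profiles computed
#' on the same (ortholog-paired) regulator-target pair:
#' (1) each gene must be expressed (>= 1 UMI) in at least
#' `min_expressing_cells` cells somewhere in its species, else
#' "indeterminate"; (2) "lost" when species B has no moderate-to-high cell
#' at any time point and at most `max_stray_low_cells` co-expressing cells
#' in total while species A shows a supported signal; (3) "novel" is the
#' mirror image; (4) "shifted_temporal" when both species have sustained
#' signal but onsets (after removing any known global offset) differ by at
#' least `min_shift_hours`; (5) "shifted_spatial" when the homolog-mapped
#' co-expressing cluster distributions share less than
#' `min_cluster_overlap` of their mass; (6) else "conserved".
#'
#' @param profile_A,profile_B `CoexpressionProfile` objects.
#' @param expressing_cells_A,expressing_cells_B named length-2 integer
#'   vectors (regulator, target): cells with >= 1 UMI of each gene across
#'   the species (see [count_expressing_cells()]).
#' @param coexpr_clusters_A,coexpr_clusters_B optional named counts of
#'   co-expressing cells per cluster in each species (see
#'   [coexpression_cluster_counts()]); the spatial overlap score is the
#'   shared mass of the two distributions after mapping species-A clusters
#'   through `homologous_cluster_map`.
#' @param homologous_cluster_map optional named vector mapping species-A
#'   clusters to their species-B homologs; when missing, the spatial test
#'   is skipped and flagged.
#' @param global_offset_hours known global developmental offset of species
#'   B (e.g. the median EMD-alignment offset); subtracted from onset_B
#'   before the temporal-shift comparison. Default 0 (raw onsets compared).
#' @param params [interaction_params()].
#' @return object of class `InteractionCall`: list with `label`, `evidence`.
#' @export
classify_interaction <- function(profile_A, profile_B,
                                 expressing_cells_A, expressing_cells_B,
                                 coexpr_clusters_A = NULL, coexpr_clusters_B = NULL,
                                 homologous_cluster_map = NULL,
                                 global_offset_hours = 0,
                                 params = interaction_params()) {
  stopifnot(inherits(profile_A, "CoexpressionProfile"),
            inherits(profile_B, "CoexpressionProfile"))
  ev <- list(onset_A = NA_real_, onset_B = NA_real_,
             peak_prop_A = max(profile_A$proportion),
             peak_prop_B = max(profile_B$proportion),
             support_A = expressing_cells_A >= params$min_expressing_cells,
             support_B = expressing_cells_B >= params$min_expressing_cells,
             cluster_overlap = NA_real_, spatial_test_skipped = FALSE)
  done <- function(label) structure(list(
    regulator = attr(profile_A, "regulator"), target = attr(profile_A, "target"),
    label = label, evidence = ev), class = "InteractionCall")

  if (!all(ev$support_A) || !all(ev$support_B)) return(done("indeterminate"))

  sig_A <- .coexpr_signal(profile_A, params)
  sig_B <- .coexpr_signal(profile_B, params)
  absent_B <- all(profile_B$n_high == 0) &&
    sum(profile_B$n_coexpressing) <= params$max_stray_low_cells
  absent_A <- all(profile_A$n_high == 0) &&
    sum(profile_A$n_coexpressing) <= params$max_stray_low_cells
  if (sig_A && absent_B) return(done("lost"))
  if (sig_B && absent_A) return(done("novel"))

  ev$onset_A <- .coexpr_onset(profile_A, params$min_signal_prop)
  ev$onset_B <- .coexpr_onset(profile_B, params$min_signal_prop)
  if (!is.na(ev$onset_A) && !is.na(ev$onset_B) &&
      abs(ev$onset_A - (ev$onset_B - global_offset_hours)) >= params$min_shift_hours)
    return(done("shifted_temporal"))

  if (!is.null(coexpr_clusters_A) && !is.null(coexpr_clusters_B) &&
      sum(coexpr_clusters_A) > 0 && sum(coexpr_clusters_B) > 0) {
    if (is.null(homologous_cluster_map)) {
      ev$spatial_test_skipped <- TRUE
      warning("no homologous cluster map; spatial test skipped")
    } else {
      # shared mass of the co-expressing-cell distributions over clusters,
      # with species-A clusters mapped to their B homologs
      fA <- coexpr_clusters_A / sum(coexpr_clusters_A)
      mapped <- homologous_cluster_map[names(fA)]
      keep <- !is.na(mapped)
      fA <- tapply(fA[keep], mapped[keep], sum)
      fB <- coexpr_clusters_B / sum(coexpr_clusters_B)
      shared <- intersect(names(fA), names(fB))
      ev$cluster_overlap <- sum(pmin(fA[shared], fB[shared]))
      if (ev$cluster_overlap < params$min_cluster_overlap)
        return(done("shifted_spatial"))
    }
  }
  done("conserved")
}

#' Co-expressing cells per cluster across a time course
#'
#' @param cms list of `CountMatrix`.
#' @param regulator,target gene ids.
#' @param clusters data.frame(barcode, cluster_id) or named vector.
#' @return named integer vector: co-expressing cells per cluster.
#' @export
coexpression_cluster_counts <- function(cms, regulator, target, clusters) {
  if (is.data.frame(clusters))
    clusters <- setNames(as.character(clusters$cluster_id), clusters$barcode)
  hits <- character(0)
  for (cm in cms) {
    if (!all(c(regulator, target) %in% cm$gene_ids)) next
    cls <- classify_cell_coexpression(as.vector(cm$counts[regulator, ]),
                                      as.vector(cm$counts[target, ]))
    hits <- c(hits, unname(clusters[cm$barcodes[cls != "none"]]))
  }
  hits <- hits[!is.na(hits)]
  if (!length(hits)) return(integer(0))
  tab <- table(hits)
  setNames(as.integer(tab), names(tab))
}

#' @export
print.InteractionCall <- function(x, ...) {
  cat(sprintf("InteractionCall %s -> %s: %s (onsets A=%s, B=%s)\n",
              x$regulator, x$target, x$label,
              x$evidence$onset_A, x$evidence$onset_B))
  invisible(x)
}

#' Cells expressing each of two genes across a time course
#'
#' @param cms list of `CountMatrix`.
#' @param regulator,target gene ids.
#' @return named integer vector (regulator, target): cells with >= 1 UMI.
#' @export
count_expressing_cells <- function(cms, regulator, target) {
  cnt <- c(regulator = 0L, target = 0L)
  for (cm in cms) {
    if (regulator %in% cm$gene_ids)
      cnt["regulator"] <- cnt["regulator"] + sum(cm$counts[regulator, ] >= 1)
    if (target %in% cm$gene_ids)
      cnt["target"] <- cnt["target"] + sum(cm$counts[target, ] >= 1)
  }
  cnt
}

#' Majority cluster among co-expressing cells of a time course
#'
#' @param cms list of `CountMatrix`.
#' @param regulator,target gene ids.
#' @param clusters data.frame(barcode, cluster_id) or named vector.
#' @return the cluster label holding the plurality of co-expressing cells,
#'   or NA when no cell co-expresses the pair.
#' @export
majority_coexpression_cluster <- function(cms, regulator, target, clusters) {
  if (is.data.frame(clusters))
    clusters <- setNames(as.character(clusters$cluster_id), clusters$barcode)
  hits <- character(0)
  for (cm in cms) {
    if (!all(c(regulator, target) %in% cm$gene_ids)) next
    cls <- classify_cell_coexpression(as.vector(cm$counts[regulator, ]),
                                      as.vector(cm$counts[target, ]))
    hits <- c(hits, unname(clusters[cm$barcodes[cls != "none"]]))
  }
  hits <- hits[!is.na(hits)]
  if (!length(hits)) return(NA_character_)
  names(sort(table(hits), decreasing = TRUE))[1]
}
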