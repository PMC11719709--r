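#' Run the full comparative-trajectory pipeline on simulated data
#'
#' Executes the stage sequence used throughout: simulate -> QC filter ->
#' normalize -> embed -> cluster -> transport with growth learning -> fate
#' probabilities -> lineage tree and triangle view -> ortholog restriction
#' and joint embedding -> cross-species EMD time alignment -> co-expression
#' time courses and interaction calls. All tabular outputs are written
#' under `outdir` as CSV/JSON, and a manifest (config snapshot, seeds,
#' per-stage status and warnings, output paths with checksums) is written
#' last.
#'
#' @param sim_cfg a [sim_config()] (the data-generating conditions).
#' @param config a [pipeline_config()] (analysis parameters).
#' @param outdir output directory (created).
#' @param stages character vector of stages to run, subset of
#'   c("simulate","preprocess","transport","fates","tree","align","coexpr").
#'   Later stages require earlier ones.
#' @return the manifest (list), invisibly also written to
#'   `outdir/manifest.json`.
#' @export
run_pipeline <- function(sim_cfg = sim_config(), config = pipeline_config(),
                         outdir = tempfile("devoalign_run_"),
                         stages = c("simulate", "preprocess", "transport",
                                    "fates", "tree", "align", "coexpr")) {
  stopifnot(inherits(sim_cfg, "SimConfig"), inherits(config, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), sim_config_seed = sim_cfg$seed,
                   stages = list(), outputs = character(0))
  warnings_log <- character(0)
  note <- function(stage, status) manifest$stages[[stage]] <<- status
  save_csv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, p)
    p
  }

  sim <- withCallingHandlers(
    simulate_two_species(sim_cfg),
    warning = function(w) { warnings_log <<- c(warnings_log, conditionMessage(w)) })
  note("simulate", "ok")
  state <- list(sim = sim)

  if ("preprocess" %in% stages) {
    pp <- list()
    for (s in c("A", "B")) {
      # one shared embedding per species so transport costs are comparable
      # across time points
      cm_all <- .concat_counts(sim[[s]])
      norm <- normalize_log_cpm(cm_all)
      d <- min(config$n_pcs, min(dim(norm)) - 1)
      emb <- embed_pca(norm, d)
      tps <- as.numeric(names(sim[[s]]))
      coords <- lapply(tps, function(t)
        emb$coords[cm_all$timepoint_hpf == t, , drop = FALSE])
      names(coords) <- as.character(tps)
      pp[[s]] <- list(cm_all = cm_all, emb = emb, coords = coords)
    }
    state$pp <- pp
    note("preprocess", "ok")
  }

  if ("transport" %in% stages) {
    tr <- list()
    for (s in c("A", "B")) {
      tps <- as.numeric(names(sim[[s]]))
      totals <- vapply(sim[[s]], function(cm) ncol(cm$counts), numeric(1))
      tr[[s]] <- learn_growth(state$pp[[s]]$coords, tps, totals, config = config,
                              n_iter = config$growth_iters)
    }
    state$tr <- tr
    note("transport", "ok")
  }

  truth_cells <- sim$truth$cells
  terminal_fate_sets <- function(s) {
    tps <- as.numeric(names(sim[[s]]))
    tl <- max(tps)
    last <- truth_cells[truth_cells$species == s & truth_cells$timepoint_hpf == tl, ]
    split(last$barcode, last$lineage)
  }

  if ("fates" %in% stages) {
    fates <- list()
    for (s in c("A", "B")) {
      tps <- as.numeric(names(sim[[s]]))
      fsets <- terminal_fate_sets(s)
      fates[[s]] <- lapply(tps[-length(tps)], function(t)
        fate_probabilities(state$tr[[s]]$maps, fsets, t, max(tps)))
      names(fates[[s]]) <- as.character(tps[-length(tps)])
    }
    state$fates <- fates
    fl <- fates$A[[1]]
    if (length(fl$fate_names) >= 2) {
      tri <- triangle_projection(fl, fl$fate_names[1], fl$fate_names[2],
                                 threshold = config$fate_threshold)
      save_csv(tri, "triangle_A_earliest.csv")
    }
    note("fates", "ok")
  }

  if ("tree" %in% stages) {
    cl <- truth_cells
    names(cl)[names(cl) == "lineage"] <- "cluster_id"
    for (s in c("A", "B")) {
      g <- build_lineage_graph(state$tr[[s]]$maps,
                               cl[cl$species == s, ],
                               min_cells = config$tree_min_cells,
                               edge_cutoff = config$tree_edge_cutoff)
      p <- file.path(outdir, paste0("lineage_graph_", s, ".json"))
      write_lineage_graph(g, p)
      manifest$outputs <- c(manifest$outputs, p)
      state$tree[[s]] <- g
    }
    note("tree", "ok")
  }

  if ("align" %in% stages) {
    cmA <- .concat_counts(sim$A); cmB <- .concat_counts(sim$B)
    ro <- restrict_to_orthologs(cmA, cmB, sim$orthologs)
    je <- joint_embedding_cca(normalize_log_cpm(ro$A), normalize_log_cpm(ro$B),
                              k = min(config$n_pcs, nrow(ro$A$counts) - 1))
    # fate matrices per timepoint stacked into one barcode-indexed matrix
    stackF <- function(fl, s) {
      probs <- do.call(rbind, lapply(fl, `[[`, "probs"))
      tl <- max(as.numeric(names(sim[[s]])))
      fin <- terminal_fate_sets(s)
      ind <- matrix(0, length(unlist(fin)), ncol(probs),
                    dimnames = list(unlist(fin), colnames(probs)))
      for (f in names(fin)) ind[fin[[f]], f] <- 1
      structure(list(probs = rbind(probs, ind), fate_names = colnames(probs),
                     reference_timepoint = tl, flagged = integer(0)),
                class = "FateMatrix")
    }
    align <- align_timecourses(
      je$A$coords, je$B$coords,
      truth_cells[truth_cells$species == "A", ],
      truth_cells[truth_cells$species == "B", ],
      stackF(state$fates$A, "A"), stackF(state$fates$B, "B"),
      max_points = 400L, seed = config$seed)
    state$align <- align
    emd_long <- do.call(rbind, lapply(align, function(ar) {
      df <- as.data.frame(as.table(ar$emd), stringsAsFactors = FALSE)
      names(df) <- c("timepoint_A", "timepoint_B", "emd")
      df$lineage <- ar$cell_lineage
      df
    }))
    save_csv(emd_long, "emd_matrices.csv")
    bp <- do.call(rbind, lapply(align, function(ar)
      cbind(lineage = ar$cell_lineage, ar$best_pairs)))
    save_csv(bp, "alignment_best_pairs.csv")
    note("align", "ok")
  }

  if ("coexpr" %in% stages && !is.null(sim_cfg$interactions)) {
    calls <- list(); tc_rows <- list()
    hom <- {
      lins <- unique(truth_cells$lineage)
      setNames(lins, lins)
    }
    clustersA <- setNames(truth_cells$lineage, truth_cells$barcode)
    for (i in seq_len(nrow(sim_cfg$interactions))) {
      ia <- sim_cfg$interactions[i, ]
      pA <- coexpression_timecourse(sim$A, ia$regulator, ia$target)
      pB <- coexpression_timecourse(sim$B, ia$regulator, ia$target)
      call <- classify_interaction(
        pA, pB,
        count_expressing_cells(sim$A, ia$regulator, ia$target),
        count_expressing_cells(sim$B, ia$regulator, ia$target),
        coexpression_cluster_counts(sim$A, ia$regulator, ia$target, clustersA),
        coexpression_cluster_counts(sim$B, ia$regulator, ia$target, clustersA),
        homologous_cluster_map = hom,
        global_offset_hours = sim_cfg$onset_delay_B[[ia$lineage]])
      calls[[i]] <- data.frame(regulator = ia$regulator, target = ia$target,
                               true_status = ia$status_in_B, label = call$label,
                               onset_A = call$evidence$onset_A,
                               onset_B = call$evidence$onset_B)
      for (sp in c("A", "B")) {
        pr <- if (sp == "A") pA else pB
        pr$species <- sp; pr$regulator <- ia$regulator; pr$target <- ia$target
        tc_rows[[length(tc_rows) + 1L]] <- as.data.frame(pr)
      }
    }
    save_csv(do.call(rbind, calls), "interaction_calls.csv")
    save_csv(do.call(rbind, tc_rows), "coexpression_timecourses.csv")
    note("coexpr", "ok")
  }

  manifest$warnings <- warnings_log
  manifest$checksums <- vapply(manifest$outputs, function(p)
    as.vector(tools::md5sum(p)), character(1))
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$path <- mp
  manifest$state <- state
  invisible(manifest)
}

# concatenate per-timepoint count matrices of one species
.concat_counts <- function(cms) {
  counts <- do.call(cbind, lapply(cms, `[[`, "counts"))
  tp <- unlist(lapply(cms, function(cm)
    rep(cm$timepoint_hpf[1], ncol(cm$counts))))
  count_matrix(counts, cms[[1]]$gene_ids,
               unlist(lapply(cms, `[[`, "barcodes")),
               species = cms[[1]]$species, timepoint_hpf = tp)
}
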