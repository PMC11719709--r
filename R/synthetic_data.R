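#' Configuration for the two-species embryo simulator
#'
#' Defines the study conditions the simulator emulates: two species sampled
#' at discrete hpf time points over a branching lineage tree, with
#' per-lineage exponential proliferation, species-B specification delays
#' (lecithotroph-like heterochrony), and injected regulator-target
#' co-expression whose evolutionary status differs between species.
#'
#' The default tree is a four-terminal-territory embryo (ectoderm, endoderm,
#' skeletogenic, pigment) with binary specifications at 7, 10 and 13 hpf,
#' sampled at 6, 9, 12, 16, 20 and 24 hpf in both species, with a global
#' 3 h specification delay in species B.
#'
#' @param n_genes number of background genes (interaction genes are appended
#'   when their ids are not among the background ids).
#' @param lineage_tree data.frame with columns parent, child,
#'   branch_time_hpf; all children of one parent must share a branch time.
#' @param timepoints_A,timepoints_B sampled hpf values, ascending.
#' @param onset_delay_B hours of specification delay in species B; a single
#'   number applied to every lineage, or a named vector per lineage.
#' @param cells_per_timepoint expected cells per (species, timepoint); a
#'   single integer, or a list with elements A and B (each length 1 or one
#'   per timepoint).
#' @param growth_rates per-lineage exponential growth rate (per hour); a
#'   single number or a named vector (missing lineages get the default).
#' @param interactions data.frame with columns regulator, target, lineage,
#'   onset_hpf, status_in_B; status is one of "conserved", "lost", "novel"
#'   or "shifted:+<hours>" (e.g. "shifted:+6").
#' @param n_program_genes program genes per lineage.
#' @param nb_dispersion negative-binomial size parameter (Inf for Poisson).
#' @param dropout_rate independent zeroing probability per entry.
#' @param mean_depth_umis mean per-cell library size (NA disables depth
#'   scaling: configured means are used as-is).
#' @param depth_sigma lognormal sd of per-cell depth around the mean.
#' @param gate_steepness logistic onset slope (per hour).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of per-gene
#'   baseline means.
#' @param amp_interaction gated amplitude of interaction regulator/target.
#' @param leak_interaction baseline leak of interaction genes.
#' @param target_secondary_domain give each target an independent expression
#'   domain in a second lineage (keeps "lost" targets individually
#'   expressed).
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 200L,
                       lineage_tree = data.frame(
                         parent = c("root", "root", "mesendo", "mesendo", "meso", "meso"),
                         child = c("ecto", "mesendo", "endo", "meso", "skel", "pigm"),
                         branch_time_hpf = c(7, 7, 10, 10, 13, 13),
                         stringsAsFactors = FALSE),
                       timepoints_A = c(6, 9, 12, 16, 20, 24),
                       timepoints_B = c(6, 9, 12, 16, 20, 24),
                       onset_delay_B = 3,
                       cells_per_timepoint = 300L,
                       growth_rates = 0.15,
                       interactions = NULL,
                       n_program_genes = 10L,
                       nb_dispersion = 2,
                       dropout_rate = 0.15,
                       mean_depth_umis = 1200,
                       depth_sigma = 0.35,
                       gate_steepness = 4,
                       baseline_meanlog = log(0.5),
                       baseline_sdlog = 1,
                       amp_interaction = 4,
                       leak_interaction = 0,
                       target_secondary_domain = TRUE,
                       seed = 1L) {
  stopifnot(is.data.frame(lineage_tree),
            all(c("parent", "child", "branch_time_hpf") %in% names(lineage_tree)))
  if (is.unsorted(timepoints_A) || is.unsorted(timepoints_B))
    stop("timepoints must be sorted ascending")
  if (anyDuplicated(lineage_tree$child)) stop("each lineage may branch from one parent only")
  # branch times must increase along root-to-leaf paths
  bt <- setNames(lineage_tree$branch_time_hpf, lineage_tree$child)
  for (i in seq_len(nrow(lineage_tree))) {
    p <- lineage_tree$parent[i]
    if (p %in% names(bt) && bt[[p]] >= lineage_tree$branch_time_hpf[i])
      stop("branch times must increase along root-to-leaf paths (", p, " -> ",
           lineage_tree$child[i], ")")
  }
  # siblings must share their branch event
  for (p in unique(lineage_tree$parent)) {
    tt <- lineage_tree$branch_time_hpf[lineage_tree$parent == p]
    if (length(unique(tt)) > 1)
      stop("children of '", p, "' must share one branch time")
  }
  lins <- .sim_lineages(lineage_tree)
  if (!is.null(interactions)) {
    stopifnot(all(c("regulator", "target", "lineage", "onset_hpf", "status_in_B")
                  %in% names(interactions)))
    bad <- !interactions$lineage %in% lins
    if (any(bad)) stop("interaction lineage(s) not in tree: ",
                       paste(unique(interactions$lineage[bad]), collapse = ", "))
    ok <- interactions$status_in_B %in% c("conserved", "lost", "novel") |
      grepl("^shifted:\\+?-?[0-9.]+$", interactions$status_in_B)
    if (!all(ok)) stop("invalid status_in_B: ",
                       paste(interactions$status_in_B[!ok], collapse = ", "))
  }
  delays <- if (length(onset_delay_B) == 1 && is.null(names(onset_delay_B)))
    setNames(rep(as.numeric(onset_delay_B), length(lins)), lins)
  else {
    d <- setNames(rep(0, length(lins)), lins)
    d[names(onset_delay_B)] <- onset_delay_B
    d
  }
  gr <- setNames(rep(0.15, length(lins)), lins)
  if (is.null(names(growth_rates))) {
    gr[] <- as.numeric(growth_rates[1])
  } else {
    unknown_l <- setdiff(names(growth_rates), lins)
    if (length(unknown_l)) stop("growth_rates name(s) not in tree: ",
                                paste(unknown_l, collapse = ", "))
    gr[names(growth_rates)] <- growth_rates
  }
  cpt <- if (is.list(cells_per_timepoint)) cells_per_timepoint else
    list(A = cells_per_timepoint, B = cells_per_timepoint)
  cpt$A <- rep(as.integer(cpt$A), length.out = length(timepoints_A))
  cpt$B <- rep(as.integer(cpt$B), length.out = length(timepoints_B))
  if (any(c(cpt$A, cpt$B) <= 0)) stop("cells_per_timepoint must be positive")
  structure(list(
    n_genes = as.integer(n_genes), lineage_tree = lineage_tree,
    timepoints_A = timepoints_A, timepoints_B = timepoints_B,
    onset_delay_B = delays, cells_per_timepoint = cpt,
    growth_rates = gr, interactions = interactions,
    n_program_genes = as.integer(n_program_genes),
    nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
    mean_depth_umis = mean_depth_umis, depth_sigma = depth_sigma,
    gate_steepness = gate_steepness,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    amp_interaction = amp_interaction, leak_interaction = leak_interaction,
    target_secondary_domain = isTRUE(target_secondary_domain),
    seed = as.integer(seed)), class = c("SimConfig", "list"))
}

# all lineage names, root first
.sim_lineages <- function(tree) {
  root <- setdiff(tree$parent, tree$child)
  if (length(root) != 1) stop("lineage tree must have exactly one root")
  c(root, tree$child)
}

.sim_root <- function(tree) setdiff(tree$parent, tree$child)

# root-to-node path (inclusive)
.sim_path <- function(tree, node) {
  path <- node
  while (node %in% tree$child) {
    node <- tree$parent[match(node, tree$child)]
    path <- c(node, path)
  }
  path
}

# birth time of each lineage for one species (root is born at 0);
# species B adds the per-lineage specification delay
.sim_birth_times <- function(cfg, species) {
  lins <- .sim_lineages(cfg$lineage_tree)
  bt <- setNames(rep(0, length(lins)), lins)
  for (i in seq_len(nrow(cfg$lineage_tree))) {
    ch <- cfg$lineage_tree$child[i]
    bt[ch] <- cfg$lineage_tree$branch_time_hpf[i] +
      if (species == "B") cfg$onset_delay_B[[ch]] else 0
  }
  bt
}

# Propagate unit mass sitting on `node` at time t_from forward to t_to,
# splitting equally at branch events and growing exponentially per lineage.
# Returns named vector of masses over the lineages active at t_to.
.sim_propagate <- function(cfg, species, node, t_from, mass, t_to) {
  tree <- cfg$lineage_tree
  bt <- .sim_birth_times(cfg, species)
  kids <- tree$child[tree$parent == node]
  g <- cfg$growth_rates[[node]]
  if (length(kids) && bt[[kids[1]]] <= t_to) {
    s <- bt[[kids[1]]]
    m_at_split <- mass * exp(g * (s - t_from))
    out <- numeric(0)
    for (k in kids) {
      sub <- .sim_propagate(cfg, species, k, s, m_at_split / length(kids), t_to)
      out <- c(out, sub)
    }
    out
  } else {
    setNames(mass * exp(g * (t_to - t_from)), node)
  }
}

# active lineages and their relative masses at time t
.sim_masses <- function(cfg, species, t) {
  root <- .sim_root(cfg$lineage_tree)
  .sim_propagate(cfg, species, root, 0, 1, t)
}

.sim_gate <- function(t, onset, k) 1 / (1 + exp(-k * (t - onset)))

.sim_shift_hours <- function(status) {
  if (grepl("^shifted:", status))
    as.numeric(sub("^shifted:\\+?", "", status)) else 0
}

# gene architecture: baseline means, per-lineage program gene sets and
# amplitudes, interaction gene indices; drawn once from the seeded RNG
.sim_genes <- function(cfg) {
  lins <- .sim_lineages(cfg$lineage_tree)
  ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  extra <- character(0)
  if (!is.null(cfg$interactions))
    extra <- setdiff(unique(c(cfg$interactions$regulator, cfg$interactions$target)), ids)
  ids <- c(ids, extra)
  n <- length(ids)
  baseline <- rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
  names(baseline) <- ids
  baseline[extra] <- cfg$leak_interaction
  # disjoint program gene sets over the background genes
  programs <- list()
  pool <- setdiff(seq_len(cfg$n_genes), match(extra, ids))
  for (l in lins) {
    take <- sample(pool, min(cfg$n_program_genes, length(pool)))
    pool <- setdiff(pool, take)
    programs[[l]] <- list(idx = take,
                          amp = 1 + stats::rgamma(length(take), shape = 2, scale = 1.5))
  }
  list(ids = ids, baseline = baseline, programs = programs)
}

# expected (pre-depth-scaling) expression for one (species, lineage, time)
.sim_mean_vector <- function(cfg, genes, species, lineage, t) {
  mu <- genes$baseline
  bt <- .sim_birth_times(cfg, species)
  k <- cfg$gate_steepness
  for (p in .sim_path(cfg$lineage_tree, lineage)) {
    pr <- genes$programs[[p]]
    if (length(pr$idx))
      mu[pr$idx] <- mu[pr$idx] + pr$amp * .sim_gate(t, bt[[p]], k)
  }
  if (!is.null(cfg$interactions)) {
    path <- .sim_path(cfg$lineage_tree, lineage)
    for (i in seq_len(nrow(cfg$interactions))) {
      ia <- cfg$interactions[i, ]
      delay <- if (species == "B") cfg$onset_delay_B[[ia$lineage]] else 0
      onset <- ia$onset_hpf + delay
      if (ia$lineage %in% path) {
        # regulator: a lineage TF, expressed regardless of interaction status
        mu[ia$regulator] <- mu[ia$regulator] + cfg$amp_interaction * .sim_gate(t, onset, k)
        # target gated with the regulator, per evolutionary status
        on <- if (species == "A") ia$status_in_B != "novel" else
          switch(sub(":.*", "", ia$status_in_B),
                 conserved = TRUE, shifted = TRUE, novel = TRUE, lost = FALSE)
        if (on) {
          extra_shift <- if (species == "B") .sim_shift_hours(ia$status_in_B) else 0
          mu[ia$target] <- mu[ia$target] +
            cfg$amp_interaction * .sim_gate(t, onset + extra_shift, k)
        }
      }
      if (cfg$target_secondary_domain) {
        sec <- .sim_secondary_lineage(cfg, ia$lineage)
        if (!is.null(sec) && sec %in% path) {
          dl <- if (species == "B") cfg$onset_delay_B[[sec]] else 0
          mu[ia$target] <- mu[ia$target] +
            cfg$amp_interaction * .sim_gate(t, ia$onset_hpf + dl, k)
        }
      }
    }
  }
  mu
}

# independent expression domain for a target: first terminal lineage (by
# name) that is not on the interaction lineage's path and not its descendant
.sim_secondary_lineage <- function(cfg, lineage) {
  tree <- cfg$lineage_tree
  terminals <- setdiff(tree$child, tree$parent)
  path <- .sim_path(tree, lineage)
  ok <- terminals[vapply(terminals, function(tm) {
    !(lineage %in% .sim_path(tree, tm)) && !(tm %in% path)
  }, logical(1))]
  if (length(ok)) sort(ok)[1] else NULL
}

#' Simulate matched two-species developmental scRNA-seq datasets
#'
#' Draws per-time-point sparse UMI matrices for species A and B under the
#' configured lineage tree, growth, specification delays, and interaction
#' statuses. Gene means are a lognormal baseline plus lineage-program terms
#' gated by logistic onsets (shifted in species B by the per-lineage delay);
#' counts are negative binomial with independent dropout, and per-cell depth
#' is lognormal around `mean_depth_umis`. Fixed seed gives identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `A`, `B` (lists of `CountMatrix`, one per
#'   timepoint), `cells` (CellTable data.frame with true lineage in
#'   `cell_type`), `orthologs` (identity `OrthologMap`), `truth` (`SimTruth`).
#' @export
simulate_two_species <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  genes <- .sim_genes(cfg)
  out <- list(A = list(), B = list())
  cells_rows <- list()
  truth_cells <- list()
  for (species in c("A", "B")) {
    tps <- if (species == "A") cfg$timepoints_A else cfg$timepoints_B
    ncells <- cfg$cells_per_timepoint[[species]]
    for (j in seq_along(tps)) {
      t <- tps[j]
      masses <- .sim_masses(cfg, species, t)
      probs <- masses / sum(masses)
      n <- ncells[j]
      if (n <= 0) stop("infeasible config: zero cells at ", species, " ", t, " hpf")
      nl <- as.vector(stats::rmultinom(1, n, probs))
      lineage_of <- rep(names(probs), nl)
      barcodes <- sprintf("%s_t%05.1f_c%04d", species, t, seq_len(n))
      counts <- matrix(0L, nrow = length(genes$ids), ncol = n)
      depth <- if (is.na(cfg$mean_depth_umis)) rep(NA_real_, n) else
        rlnorm(n, log(cfg$mean_depth_umis) - cfg$depth_sigma^2 / 2, cfg$depth_sigma)
      for (l in unique(lineage_of)) {
        idx <- which(lineage_of == l)
        mu <- .sim_mean_vector(cfg, genes, species, l, t)
        for (ci in idx) {
          m <- if (is.na(depth[ci])) mu else mu * (depth[ci] / sum(mu))
          cnt <- if (is.infinite(cfg$nb_dispersion)) stats::rpois(length(m), m)
          else rnbinom(length(m), size = cfg$nb_dispersion, mu = m)
          if (cfg$dropout_rate > 0)
            cnt[runif(length(cnt)) < cfg$dropout_rate] <- 0L
          counts[, ci] <- cnt
        }
      }
      cm <- count_matrix(Matrix::Matrix(counts, sparse = TRUE), genes$ids, barcodes,
                         species = species, timepoint_hpf = t)
      out[[species]][[as.character(t)]] <- cm
      truth_cells[[length(truth_cells) + 1L]] <- data.frame(
        barcode = barcodes, species = species, timepoint_hpf = t,
        lineage = lineage_of, stringsAsFactors = FALSE)
      cells_rows[[length(cells_rows) + 1L]] <- cell_table(cm, cell_type = lineage_of)
    }
  }
  truth_cells <- do.call(rbind, truth_cells)
  cells <- do.call(rbind, cells_rows)
  onsets <- lapply(c(A = "A", B = "B"), function(s) .sim_birth_times(cfg, s))
  itab <- if (is.null(cfg$interactions)) NULL else {
    it <- cfg$interactions
    it$true_label <- vapply(it$status_in_B, function(s) {
      if (grepl("^shifted:", s)) "shifted_temporal" else s
    }, character(1))
    it
  }
  expected <- rbind(
    data.frame(species = "A", timepoint_hpf = cfg$timepoints_A,
               n_cells = cfg$cells_per_timepoint$A),
    data.frame(species = "B", timepoint_hpf = cfg$timepoints_B,
               n_cells = cfg$cells_per_timepoint$B))
  truth <- structure(list(cells = truth_cells, onsets = onsets,
                          interactions = itab, expected_cells = expected,
                          growth_rates = cfg$growth_rates, config = cfg),
                     class = "SimTruth")
  orth <- ortholog_map(genes$ids, genes$ids)
  list(A = out$A, B = out$B, cells = cells, orthologs = orth, truth = truth)
}

#' True lineage graph implied by the simulator configuration
#'
#' Nodes are (lineage, timepoint) for the lineages active at each sampled
#' time point; edges connect consecutive time points with weight equal to
#' the fraction of a parent lineage's descendant mass found in each
#' descendant lineage at the next time point. Outgoing weights from any
#' node sum to 1.
#'
#' @param truth a `SimTruth`.
#' @param species "A" or "B".
#' @return a `LineageGraph`.
#' @export
truth_lineage_tree <- function(truth, species = "A") {
  stopifnot(inherits(truth, "SimTruth"))
  cfg <- truth$config
  tps <- if (species == "A") cfg$timepoints_A else cfg$timepoints_B
  cells <- truth$cells[truth$cells$species == species, ]
  nodes <- list(); edges <- list()
  for (j in seq_along(tps)) {
    t <- tps[j]
    act <- names(.sim_masses(cfg, species, t))
    for (l in act) {
      n_cells <- sum(cells$lineage == l & cells$timepoint_hpf == t)
      nodes[[length(nodes) + 1L]] <- data.frame(
        id = paste0(l, "@", t), cluster = l, timepoint = t,
        n_cells = n_cells, stringsAsFactors = FALSE)
    }
    if (j < length(tps)) {
      t2 <- tps[j + 1]
      for (l in act) {
        flow <- .sim_propagate(cfg, species, l, t, 1, t2)
        w <- flow / sum(flow)
        for (d in names(w))
          edges[[length(edges) + 1L]] <- data.frame(
            source = paste0(l, "@", t), target = paste0(d, "@", t2),
            weight = unname(w[[d]]), stringsAsFactors = FALSE)
      }
    }
  }
  lineage_graph(do.call(rbind, nodes),
                if (length(edges)) do.call(rbind, edges) else
                  data.frame(source = character(), target = character(),
                             weight = numeric()))
}
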