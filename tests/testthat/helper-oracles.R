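# Independent reference implementations used to cross-check the package's
# numerical core. These deliberately share no code with the package: the
# unbalanced-transport oracle is a generic quasi-Newton optimizer over
# log-coupling variables, the balanced oracle is a plain Sinkhorn loop, and
# the co-expression/filtering oracles are brute-force double loops.

# objective of the unbalanced entropic OT problem in log-coupling variables,
# with its analytic gradient, minimized by BFGS
oracle_uot <- function(C, a, b, epsilon, lambda1, lambda2) {
  n <- nrow(C); m <- ncol(C)
  fn <- function(theta) {
    g <- matrix(exp(theta), n, m)
    r <- rowSums(g); cc <- colSums(g)
    ent <- -sum(g * (log(g) - 1))
    kl <- function(x, y) sum(x * log(x / y)) - sum(x) + sum(y)
    sum(C * g) - epsilon * ent + lambda1 * kl(r, a) + lambda2 * kl(cc, b)
  }
  gr <- function(theta) {
    g <- matrix(exp(theta), n, m)
    r <- rowSums(g); cc <- colSums(g)
    d <- C + epsilon * log(g) +
      matrix(lambda1 * log(r / a), n, m) +
      matrix(lambda2 * log(cc / b), n, m, byrow = TRUE)
    as.vector(d * g)
  }
  par <- as.vector(log(outer(a, b) / sum(b)))
  value <- Inf
  for (r in 1:8) {   # polish with restarts until the value stabilizes
    opt <- stats::optim(par, fn, gr, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-15))
    par <- opt$par
    if (value - opt$value < 1e-10) { value <- opt$value; break }
    value <- opt$value
  }
  list(gamma = matrix(exp(par), n, m), value = value)
}

# balanced entropic OT by standard Sinkhorn iteration (marginals enforced
# exactly); the lambda -> Inf limit of the unbalanced problem
oracle_sinkhorn_balanced <- function(C, a, b, epsilon, iters = 20000, tol = 1e-13) {
  K <- exp(-C / epsilon)
  u <- rep(1, nrow(C)); v <- rep(1, ncol(C))
  for (i in seq_len(iters)) {
    u_new <- a / as.vector(K %*% v)
    v_new <- b / as.vector(crossprod(K, u_new))
    if (max(abs(u_new - u), abs(v_new - v)) < tol) { u <- u_new; v <- v_new; break }
    u <- u_new; v <- v_new
  }
  (u %o% v) * K
}

# brute-force co-expression tally: explicit double loop over cells
oracle_coexpr_counts <- function(umis_a, umis_b) {
  n_low <- 0L; n_high <- 0L
  for (i in seq_along(umis_a)) {
    if (umis_a[i] >= 1 && umis_b[i] >= 1) {
      if (umis_a[i] >= 2 && umis_b[i] >= 2) n_high <- n_high + 1L
      else n_low <- n_low + 1L
    }
  }
  list(n_low = n_low, n_high = n_high, n_coexpressing = n_low + n_high)
}

# brute-force QC survivor set: per-cell loop applying the strict inequalities
oracle_filter_survivors <- function(counts, min_genes, max_genes, max_counts) {
  keep <- logical(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    col <- counts[, j]
    ng <- sum(col >= 1)
    keep[j] <- (ng > min_genes) && (ng < max_genes) && (sum(col) < max_counts)
  }
  which(keep)
}

# small random CountMatrix fixture
random_count_matrix <- function(n_genes, n_cells, seed, species = "A", tp = 6,
                                lambda = 0.6) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  count_matrix(m, paste0("g", seq_len(n_genes)),
               paste0("bc", seq_len(n_cells)), species = species,
               timepoint_hpf = tp)
}

# hand-built TransportMap wrapper for fixture couplings
fixture_map <- function(gamma, t0, t1, src, tgt) {
  structure(list(gamma = gamma, epsilon = 0.05, lambda1 = 1, lambda2 = 50,
                 converged = TRUE, n_iter = 0L,
                 scalings = list(u = NULL, v = NULL),
                 source_timepoint = t0, target_timepoint = t1,
                 source_barcodes = src, target_barcodes = tgt),
            class = "TransportMap")
}
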