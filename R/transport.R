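#' Ground-cost matrix between two embedded cell sets
#'
#' Squared Euclidean distances in the shared embedding space, divided by the
#' median nonzero entry so the entropic regularization scale is comparable
#' across time-point pairs.
#'
#' @param emb_t,emb_t1 cells x d coordinate matrices (same basis).
#' @return nonnegative n_t x n_t1 matrix.
#' @export
cost_matrix <- function(emb_t, emb_t1) {
  a <- if (inherits(emb_t, "EmbeddingMatrix")) emb_t$coords else as.matrix(emb_t)
  b <- if (inherits(emb_t1, "EmbeddingMatrix")) emb_t1$coords else as.matrix(emb_t1)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty embedding slice")
  sq <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sq[sq < 0] <- 0
  nz <- sq[sq > 0]
  if (length(nz)) sq / median(nz) else sq
}

#' Unbalanced entropic optimal transport between consecutive time points
#'
#' Minimizes `<C, gamma> - eps*H(gamma) + lambda1*KL(gamma 1 || a) +
#' lambda2*KL(gamma^T 1 || b)` with `H(gamma) = -sum gamma*(log gamma - 1)`,
#' by generalized Sinkhorn scaling: `u <- (a / K v)^(lambda1/(lambda1+eps))`,
#' `v <- (b / K^T u)^(lambda2/(lambda2+eps))`, `K = exp(-C/eps)`,
#' `gamma = diag(u) K diag(v)`. The default parameters are the published
#' trajectory settings (eps 0.05, lambda1 1 on the growth-modelled source
#' marginal, lambda2 50 on the target marginal).
#'
#' @param C cost matrix (finite).
#' @param a,b nonnegative source/target weights with positive sums.
#' @param epsilon entropic regularization.
#' @param lambda1,lambda2 KL relaxation strengths for source/target marginals.
#' @param max_iter,tol stopping rule on the max marginal change.
#' @param source_timepoint,target_timepoint,source_barcodes,target_barcodes
#'   optional provenance carried on the result.
#' @return object of class `TransportMap`: list with `gamma`, the parameters,
#'   `converged`, `n_iter`, and the provenance fields.
#' @export
solve_unbalanced_ot <- function(C, a, b, epsilon = 0.05, lambda1 = 1, lambda2 = 50,
                                max_iter = 5000L, tol = 1e-8,
                                source_timepoint = NA_real_, target_timepoint = NA_real_,
                                source_barcodes = NULL, target_barcodes = NULL,
                                u0 = NULL, v0 = NULL) {
  C <- as.matrix(C)
  if (any(!is.finite(C))) stop("cost matrix must be finite")
  if (any(a < 0) || any(b < 0) || sum(a) <= 0 || sum(b) <= 0)
    stop("marginals must be nonnegative with positive sums")
  if (length(a) != nrow(C) || length(b) != ncol(C))
    stop("marginal lengths must match cost dimensions")
  K <- exp(-C / epsilon)
  if (any(K == 0) || any(!is.finite(K)))
    stop("non-finite/degenerate kernel: epsilon too small for the cost scale; rescale the cost")
  f1 <- lambda1 / (lambda1 + epsilon)
  f2 <- lambda2 / (lambda2 + epsilon)
  u <- if (is.null(u0)) rep(1, nrow(C)) else u0
  v <- if (is.null(v0)) rep(1, ncol(C)) else v0
  converged <- FALSE; it <- 0L
  prev_r <- rep(Inf, nrow(C)); prev_c <- rep(Inf, ncol(C))
  while (it < max_iter) {
    it <- it + 1L
    u <- (a / (K %*% v))^f1
    v <- (b / (crossprod(K, u)))^f2
    u <- as.vector(u); v <- as.vector(v)
    r <- u * as.vector(K %*% v)
    cc <- v * as.vector(crossprod(K, u))
    delta <- max(max(abs(r - prev_r)), max(abs(cc - prev_c)))
    prev_r <- r; prev_c <- cc
    if (is.finite(delta) && delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("unbalanced OT scaling did not converge in ", max_iter, " iterations")
  gamma <- (u %o% v) * K
  structure(list(gamma = gamma, epsilon = epsilon, lambda1 = lambda1,
                 lambda2 = lambda2, converged = converged, n_iter = it,
                 scalings = list(u = u, v = v),
                 source_timepoint = source_timepoint,
                 target_timepoint = target_timepoint,
                 source_barcodes = source_barcodes,
                 target_barcodes = target_barcodes),
            class = "TransportMap")
}

#' @export
print.TransportMap <- function(x, ...) {
  cat(sprintf("TransportMap %s -> %s hpf: %d x %d, mass %.4g, eps=%g, %s\n",
              x$source_timepoint, x$target_timepoint,
              nrow(x$gamma), ncol(x$gamma), sum(x$gamma), x$epsilon,
              if (x$converged) sprintf("converged in %d iters", x$n_iter)
              else "NOT converged"))
  invisible(x)
}

#' Objective value of the unbalanced entropic OT problem
#'
#' `<C,g> - eps*H(g) + lambda1*KL(g1||a) + lambda2*KL(g^T1||b)` with
#' `H(g) = -sum g (log g - 1)` and `KL(x||y) = sum x log(x/y) - x + y`.
#' Exposed for diagnostics and solver cross-checks.
#'
#' @param gamma coupling matrix.
#' @param C,a,b,epsilon,lambda1,lambda2 as in [solve_unbalanced_ot()].
#' @return scalar objective value.
#' @export
uot_objective <- function(gamma, C, a, b, epsilon, lambda1, lambda2) {
  g <- as.vector(gamma)
  ent <- -sum(ifelse(g > 0, g * (log(g) - 1), 0))
  kl <- function(x, y) sum(ifelse(x > 0, x * log(x / y), 0)) - sum(x) + sum(y)
  sum(C * gamma) - epsilon * ent +
    lambda1 * kl(rowSums(gamma), a) + lambda2 * kl(colSums(gamma), b)
}

#' Learn per-cell growth rates by iterated transport
#'
#' Initializes every cell at time t with the uniform division rate
#' `g = (N_{t+1}/N_t)^(1/dt)` (divisions assumed uniform between expected
#' cell-number estimates), then alternates: solve all consecutive transport
#' maps with source weights proportional to `g^dt` (total source mass
#' `N_{t+1}/N_t`, uniform targets), and update each cell's growth from the
#' mass it actually transported: `g_i <- ((gamma 1)_i / abar)^(1/dt) *
#' (N_{t+1}/N_t)^(1/dt)` with `abar` the uniform weight. Runs the published
#' 20 iterations by default.
#'
#' @param embeddings list of cells x d coordinate matrices, one per timepoint
#'   (chronological).
#' @param timepoints hpf values (hours; dt is their real difference).
#' @param expected_totals expected cell numbers N_t per timepoint.
#' @param config a [pipeline_config()] carrying epsilon/lambda1/lambda2.
#' @param n_iter growth-learning iterations.
#' @return list with `growth` (list of per-cell g per timepoint, last
#'   timepoint NULL), `maps` (list of `TransportMap`), `expected_totals`.
#' @export
learn_growth <- function(embeddings, timepoints, expected_totals,
                         config = pipeline_config(), n_iter = 20L) {
  P <- length(embeddings)
  if (P < 2) stop("need at least two timepoints")
  if (length(timepoints) != P || length(expected_totals) != P)
    stop("timepoints/expected_totals must match embeddings")
  if (any(expected_totals <= 0)) stop("expected totals must be positive")
  dts <- diff(timepoints)
  growth <- vector("list", P)
  for (p in seq_len(P - 1)) {
    ratio <- expected_totals[p + 1] / expected_totals[p]
    growth[[p]] <- rep(ratio^(1 / dts[p]), nrow(embeddings[[p]]))
  }
  maps <- vector("list", P - 1)
  costs <- lapply(seq_len(P - 1), function(p)
    cost_matrix(embeddings[[p]], embeddings[[p + 1]]))
  for (iter in seq_len(n_iter)) {
    for (p in seq_len(P - 1)) {
      n_s <- nrow(embeddings[[p]]); n_t <- nrow(embeddings[[p + 1]])
      ratio <- expected_totals[p + 1] / expected_totals[p]
      w <- growth[[p]]^dts[p]
      a <- w / sum(w) * ratio          # total source mass = expected growth
      b <- rep(ratio / n_t, n_t)       # target carries the same total, so
                                       # transported mass reflects expansion
      maps[[p]] <- solve_unbalanced_ot(
        costs[[p]], a, b, epsilon = config$epsilon,
        lambda1 = config$lambda1, lambda2 = config$lambda2,
        source_timepoint = timepoints[p], target_timepoint = timepoints[p + 1],
        source_barcodes = rownames(embeddings[[p]]),
        target_barcodes = rownames(embeddings[[p + 1]]),
        u0 = if (is.null(maps[[p]])) NULL else maps[[p]]$scalings$u,
        v0 = if (is.null(maps[[p]])) NULL else maps[[p]]$scalings$v)
      abar <- ratio / n_s
      gnew <- (rowSums(maps[[p]]$gamma) / abar)^(1 / dts[p]) * ratio^(1 / dts[p])
      growth[[p]] <- pmax(gnew, 1e-12)
    }
  }
  if (any(!vapply(maps, `[[`, logical(1), "converged")))
    warning("one or more transport maps did not converge in the final iteration")
  list(growth = growth, maps = maps, expected_totals = expected_totals,
       timepoints = timepoints)
}

#' Compose transport maps into a long-range transition matrix
#'
#' Row-normalizes each coupling into a Markov transition matrix and
#' chain-multiplies the contiguous maps from `from_t` to `to_t`. Rows of
#' cells with zero transported mass are flagged (attribute `zero_mass_rows`)
#' rather than renormalized.
#'
#' @param maps list of `TransportMap` (chronological).
#' @param from_t,to_t hpf endpoints; the chain must be contiguous.
#' @return row-stochastic matrix (source cells at from_t x cells at to_t).
#' @export
compose_maps <- function(maps, from_t, to_t) {
  src <- vapply(maps, `[[`, numeric(1), "source_timepoint")
  tgt <- vapply(maps, `[[`, numeric(1), "target_timepoint")
  chain <- list(); t_cur <- from_t
  while (t_cur < to_t) {
    k <- which(src == t_cur)
    if (!length(k)) stop("gap in transport chain at ", t_cur, " hpf")
    chain[[length(chain) + 1L]] <- maps[[k[1]]]
    t_cur <- tgt[k[1]]
  }
  if (t_cur != to_t) stop("chain overshoots to_t")
  if (!length(chain)) stop("from_t must be earlier than to_t")
  zero_rows <- NULL
  M <- NULL
  for (m in chain) {
    rs <- rowSums(m$gamma)
    Tm <- m$gamma / ifelse(rs > 0, rs, 1)
    if (is.null(M)) {
      M <- Tm
      zero_rows <- rs == 0
    } else {
      M <- M %*% Tm
    }
  }
  final <- rowSums(M)
  attr(M, "zero_mass_rows") <- which(zero_rows | final < 1e-12)
  rownames(M) <- chain[[1]]$source_barcodes
  colnames(M) <- chain[[length(chain)]]$target_barcodes
  M
}

#' Fate probabilities relative to terminal cell sets
#'
#' Pulls fate indicators at the reference time point back through the
#' composed transport maps: `P(F | x at t) = sum_{y in F} M[x, y]` with `M`
#' the t -> T transition matrix. When the fate sets partition the reference
#' cells, rows sum to 1.
#'
#' @param maps list of `TransportMap`.
#' @param fate_sets named list: fate name -> character vector of barcodes (or
#'   column indices) at the reference time point.
#' @param from_t source time point (hpf).
#' @param reference_t reference (fate) time point, e.g. the last common one.
#' @return object of class `FateMatrix`: list with `probs` (cells x fates),
#'   `fate_names`, `reference_timepoint`, `flagged` (zero-mass source rows).
#' @export
fate_probabilities <- function(maps, fate_sets, from_t, reference_t) {
  if (!length(fate_sets)) stop("no fate sets given")
  if (any(!vapply(fate_sets, length, integer(1)))) stop("empty fate set")
  M <- compose_maps(maps, from_t, reference_t)
  probs <- vapply(names(fate_sets), function(f) {
    sel <- fate_sets[[f]]
    cols <- if (is.character(sel)) match(sel, colnames(M)) else sel
    if (anyNA(cols)) stop("fate set '", f, "' references unknown cells")
    rowSums(M[, cols, drop = FALSE])
  }, numeric(nrow(M)))
  probs <- matrix(probs, nrow = nrow(M),
                  dimnames = list(rownames(M), names(fate_sets)))
  structure(list(probs = probs, fate_names = names(fate_sets),
                 reference_timepoint = reference_t,
                 source_timepoint = from_t,
                 flagged = attr(M, "zero_mass_rows")),
            class = "FateMatrix")
}

#' @export
print.FateMatrix <- function(x, ...) {
  cat(sprintf("FateMatrix: %d cells x %d fates (%s), reference %s hpf\n",
              nrow(x$probs), ncol(x$probs),
              paste(x$fate_names, collapse = ", "), x$reference_timepoint))
  invisible(x)
}
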