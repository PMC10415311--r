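# Assemble the supra-modularity matrix for categorical multi-slice
# community detection. Vertices are (area, slice) pairs, ordered
# slice-major: vertex (i, s) = (s-1)*N + i. Intra-slice blocks hold
# A_ijs - gamma_s * k_is k_js / (2 m_s) (slice diagonals zeroed before
# degrees are computed); inter-slice entries couple each area to itself
# in every other slice with weight omega. The normalizer is
# 2*mu = sum_s 2 m_s + omega * N * S * (S - 1).
supra_modularity <- function(network, gamma = 1, omega = 0.1) {
  slices <- unclass(network)
  S <- length(slices)
  areas <- attr(network, "areas") %||% rownames(slices[[1L]])
  N <- nrow(slices[[1L]])
  gamma <- rep_len(gamma, S)
  for (s in seq_len(S)) {
    if (!all(dim(slices[[s]]) == c(N, N)))
      stop("slices must share one node set")
    m <- slices[[s]]
    if (anyNA(m)) m[is.na(m)] <- 0
    diag(m) <- 0
    slices[[s]] <- m
  }
  B <- matrix(0, N * S, N * S)
  two_m_total <- 0
  for (s in seq_len(S)) {
    A <- slices[[s]]
    k <- rowSums(A)
    two_m <- sum(k)
    two_m_total <- two_m_total + two_m
    P <- if (two_m != 0) gamma[s] * outer(k, k) / two_m else 0 * A
    idx <- (s - 1L) * N + seq_len(N)
    B[idx, idx] <- A - P
  }
  if (S > 1L && omega != 0) {
    for (s in seq_len(S)) for (r in seq_len(S)) {
      if (s == r) next
      B[cbind((s - 1L) * N + seq_len(N), (r - 1L) * N + seq_len(N))] <- omega
    }
  }
  two_mu <- two_m_total + omega * N * S * (S - 1L)
  list(B = B, two_mu = two_mu, n_areas = N, n_slices = S, areas = areas)
}

#' Multi-slice modularity of a partition
#'
#' Exact evaluation of the categorical multi-slice quality function
#' `Q = 1/(2 mu) * sum_ijsr [ (A_ijs - gamma_s k_is k_js / 2 m_s) d_sr
#' + d_ij C_jsr ] d(g_is, g_jr)` with all-to-all identity interslice
#' coupling `C_jsr = omega` for `r != s`. With a single slice and
#' `omega = 0` this reduces to standard Newman-Girvan modularity.
#'
#' @param network a `multilayer_network` (list of area x area slices) or
#'   plain list of matrices.
#' @param partition community labels: an `n_areas x n_slices` matrix, a
#'   `multilayer_partition`, or a length-`n_areas` vector recycled across
#'   slices.
#' @param gamma per-slice resolution (default 1).
#' @param omega interslice coupling (default 0.1).
#' @return Q value (numeric scalar).
#' @export
multislice_q <- function(network, partition, gamma = 1, omega = 0.1) {
  sup <- supra_modularity(network, gamma, omega)
  g <- .flatten_partition(partition, sup$n_areas, sup$n_slices)
  delta <- outer(g, g, "==")
  sum(sup$B[delta]) / sup$two_mu
}

.flatten_partition <- function(partition, N, S) {
  if (inherits(partition, "multilayer_partition"))
    partition <- partition$assignment
  g <- if (is.matrix(partition)) {
    stopifnot(nrow(partition) == N, ncol(partition) == S)
    as.vector(partition)
  } else if (length(partition) == N) {
    rep(as.vector(partition), S)
  } else if (length(partition) == N * S) {
    as.vector(partition)
  } else stop("partition has wrong length")
  canonical_labels(g)
}

#' Optimize multi-slice communities (generalized Louvain)
#'
#' Greedy Louvain-style maximization of the multi-slice quality function:
#' repeated single-vertex moves over the supra-modularity matrix in
#' seed-shuffled order, followed by community aggregation, until no move
#' improves Q. The returned partition is a local optimum (no single
#' vertex move improves Q) and Q never decreases during the search.
#'
#' @param network a `multilayer_network` or list of slices.
#' @param gamma per-slice resolution (default 1).
#' @param omega interslice coupling (default 0.1).
#' @param seed integer seed (controls sweep order).
#' @param n_restarts independent seeded starts; the best-Q local optimum
#'   is kept (1 preserves maximal run-to-run diversity for consensus
#'   ensembles).
#' @return object of class `multilayer_partition`: list with
#'   `assignment` (areas x slices label matrix), `q`, and `params`.
#' @export
optimize_communities <- function(network, gamma = 1, omega = 0.1, seed = 1L,
                                 n_restarts = 5L) {
  sup <- supra_modularity(network, gamma, omega)
  g <- with_seed(seed, {
    best <- NULL; best_q <- -Inf
    for (r in seq_len(n_restarts)) {
      cand <- louvain_matrix(sup$B)
      q <- sum(sup$B[outer(cand, cand, "==")])
      if (q > best_q) { best_q <- q; best <- cand }
    }
    best
  })
  assignment <- matrix(canonical_labels(g), sup$n_areas, sup$n_slices)
  rownames(assignment) <- sup$areas
  q <- sum(sup$B[outer(g, g, "==")]) / sup$two_mu
  structure(list(assignment = assignment, q = q,
                 params = list(gamma = gamma, omega = omega, seed = seed)),
            class = "multilayer_partition")
}

#' @export
print.multilayer_partition <- function(x, ...) {
  cat("<multilayer_partition>", nrow(x$assignment), "areas x",
      ncol(x$assignment), "slices,",
      length(unique(as.vector(x$assignment))), "communities, Q =",
      signif(x$q, 4), "\n")
  invisible(x)
}

# Louvain-style optimization of sum(B[g_i == g_j]) for an arbitrary
# symmetric quality matrix B (diagonal terms are constant under moves).
# Alternates vertex-level local moves with community-level moves on the
# aggregated quotient until neither improves, so the result is a local
# optimum under both single-vertex moves and whole-community merges.
# Uses the caller's RNG state for sweep order.
louvain_matrix <- function(B, init = NULL) {
  n <- nrow(B)
  g <- canonical_labels(init %||% seq_len(n))
  repeat {
    res <- .local_move(B, g)
    g <- res$labels
    comms <- unique(g)
    moved2 <- FALSE
    if (length(comms) > 1L) {
      memb <- match(g, comms)
      S <- outer(memb, seq_along(comms), "==") * 1
      agg <- crossprod(S, B %*% S)
      agg <- (agg + t(agg)) / 2
      res2 <- .local_move(agg, seq_along(comms))
      moved2 <- res2$moved
      if (moved2) g <- res2$labels[memb]
    }
    if (!res$moved && !moved2) break
  }
  canonical_labels(g)
}

# One or more sweeps of greedy single-vertex moves on quality matrix B.
.local_move <- function(B, g) {
  n <- nrow(B)
  if (n <= 1L) return(list(labels = g, moved = FALSE))
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (v in sample.int(n)) {
      # gain of v joining community c: sum of B[v, w] over w in c, w != v
      links <- rowsum(B[v, -v], g[-v])
      cur <- g[v]
      gain_cur <- if (as.character(cur) %in% rownames(links))
        links[as.character(cur), 1L] else 0
      best_idx <- which.max(links[, 1L])
      best <- as.integer(rownames(links)[best_idx])
      if (links[best_idx, 1L] > gain_cur + 1e-12 && best != cur) {
        g[v] <- best
        moved <- TRUE; moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(labels = g, moved = moved_any)
}
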