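#' Module allegiance matrix
#'
#' Fraction of (slice, run) pairs in which two areas are assigned to the
#' same community. Accepts a single `multilayer_partition` (allegiance
#' across slices) or a list of runs (allegiance across slices x runs,
#' the default mode of [consensus_communities()]).
#'
#' @param partitions a `multilayer_partition` or list of them.
#' @return symmetric matrix in `[0, 1]` with unit diagonal, labeled by
#'   area.
#' @export
module_allegiance <- function(partitions) {
  if (inherits(partitions, "multilayer_partition"))
    partitions <- list(partitions)
  if (length(partitions) == 0L) stop("need >= 1 partition")
  a1 <- partitions[[1L]]$assignment
  N <- nrow(a1)
  acc <- matrix(0, N, N)
  total <- 0L
  for (p in partitions) {
    a <- p$assignment
    stopifnot(nrow(a) == N)
    for (s in seq_len(ncol(a))) {
      acc <- acc + outer(a[, s], a[, s], "==")
      total <- total + 1L
    }
  }
  out <- acc / total
  dimnames(out) <- list(rownames(a1), rownames(a1))
  out
}

#' Consensus communities across repeated multi-slice optimizations
#'
#' Runs the multi-slice optimizer `n_runs` times with distinct seeds,
#' summarizes co-assignment in a module allegiance matrix over runs and
#' slices, and then iteratively re-clusters the allegiance matrix (minus
#' its mean off-diagonal value, the permutation-null co-assignment
#' expectation) until repeated single-layer clusterings agree — the
#' classic iterative consensus clustering recipe. Returns a single
#' area-level partition.
#'
#' @param network a `multilayer_network` or list of slices.
#' @param n_runs number of independent optimization runs (paper-scale
#'   1000; reduce for quick runs).
#' @param gamma,omega multi-slice parameters.
#' @param seed integer seed.
#' @param n_consensus_runs clusterings per consensus iteration.
#' @param max_iter iteration cap; non-convergence returns the current
#'   partition with a warning.
#' @return object of class `partition`: named integer vector
#'   (area -> community) with attributes `allegiance`, `n_iter`,
#'   `converged`.
#' @export
consensus_communities <- function(network, n_runs = 1000L, gamma = 1,
                                  omega = 0.1, seed = 1L,
                                  n_consensus_runs = 20L, max_iter = 50L) {
  seeds <- child_seeds(seed, n_runs + max_iter * n_consensus_runs)
  runs <- lapply(seq_len(n_runs), function(i)
    optimize_communities(network, gamma, omega, seed = seeds[i],
                         n_restarts = 1L))
  alleg <- module_allegiance(runs)
  areas <- rownames(alleg) %||% paste0("area", seq_len(nrow(alleg)))

  cluster_alleg <- function(A, seed_) {
    D <- A - mean(A[upper.tri(A)])
    diag(D) <- 0
    with_seed(seed_, louvain_matrix(D))
  }

  labels <- NULL
  converged <- FALSE
  si <- n_runs
  for (iter in seq_len(max_iter)) {
    reps <- lapply(seq_len(n_consensus_runs), function(j)
      cluster_alleg(alleg, seeds[si + j]))
    si <- si + n_consensus_runs
    agree <- all(vapply(reps[-1L], function(r)
      adjusted_rand_index(r, reps[[1L]]) == 1, TRUE))
    labels <- reps[[1L]]
    if (agree) { converged <- TRUE; break }
    # rebuild allegiance from this iteration's clusterings and recurse
    alleg <- Reduce(`+`, lapply(reps, function(r)
      outer(r, r, "==") * 1)) / length(reps)
  }
  if (!converged)
    warning("consensus did not converge within ", max_iter,
            " iterations; returning current partition")
  structure(stats::setNames(canonical_labels(labels), areas),
            allegiance = alleg, n_iter = iter, converged = converged,
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  k <- length(unique(unclass(x)))
  cat("<partition>", length(x), "areas in", k, "communities\n")
  for (c_ in sort(unique(unclass(x))))
    cat(" ", c_, ":", paste(names(x)[unclass(x) == c_], collapse = ", "), "\n")
  invisible(x)
}
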