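#' Align an area partition with a modality matrix's label set
#'
#' Independent-modality matrices may not resolve every area (e.g. an
#' atlas that does not distinguish dorsal and ventral dentate gyrus, so
#' DGd and DGv collapse to one DG label). A merge map declares which
#' partition areas each matrix label aggregates; a merged label inherits
#' the community of its members, which must agree.
#'
#' @param partition named vector area -> community.
#' @param matrix labeled square matrix (a `modal_matrix` or plain).
#' @param merge_map named list matrix-label -> character vector of
#'   partition areas it merges. Default merges DGd + DGv into DG.
#' @return named integer vector over the matrix's labels.
#' @export
align_partition <- function(partition, matrix,
                            merge_map = list(DG = c("DGd", "DGv"))) {
  labels <- rownames(matrix)
  if (is.null(labels)) stop("matrix must have row labels")
  out <- stats::setNames(integer(length(labels)), labels)
  for (lb in labels) {
    members <- if (lb %in% names(partition)) lb
               else if (lb %in% names(merge_map)) merge_map[[lb]]
               else stop("matrix label '", lb, "' not in partition or merge map")
    comm <- unique(unclass(partition)[members])
    if (anyNA(comm) || length(comm) != 1L)
      stop("merged members of '", lb, "' fall in different communities; ",
           "community inheritance undefined")
    out[lb] <- comm
  }
  out
}

#' Strength fraction of a partition in a modality matrix
#'
#' Sum of within-community edge weights over the total edge weight
#' (off-diagonal entries, each unordered pair counted once).
#'
#' @param matrix symmetric labeled matrix.
#' @param partition named vector over the matrix's labels (aligned).
#' @param clip_negative set negative weights to 0 first (off by default;
#'   co-expression matrices may carry negatives).
#' @return S.F. value in `(0, 1]` for nonnegative matrices.
#' @export
strength_fraction <- function(matrix, partition, clip_negative = FALSE) {
  m <- .aligned_matrix(matrix, partition)
  if (clip_negative) m[m < 0] <- 0
  ut <- upper.tri(m)
  total <- sum(m[ut], na.rm = TRUE)
  if (total == 0) {
    warning("total edge weight is 0; strength fraction undefined")
    return(NA_real_)
  }
  g <- unclass(partition)[rownames(m)]
  within <- outer(g, g, "==")[ut]
  sum(m[ut][within], na.rm = TRUE) / total
}

#' Weighted Newman modularity of a partition
#'
#' `Q = 1/(2m) * sum_ij (A_ij - k_i k_j / 2m) d(g_i, g_j)` on the
#' matrix with zeroed diagonal. Single-slice special case of the
#' multi-slice quality function.
#'
#' @inheritParams strength_fraction
#' @return Q value.
#' @export
modularity_q <- function(matrix, partition) {
  m <- .aligned_matrix(matrix, partition)
  diag(m) <- 0
  k <- rowSums(m)
  two_m <- sum(k)
  if (two_m == 0) {
    warning("total edge weight is 0; modularity undefined")
    return(NA_real_)
  }
  g <- unclass(partition)[rownames(m)]
  B <- m - outer(k, k) / two_m
  sum(B[outer(g, g, "==")]) / two_m
}

.aligned_matrix <- function(matrix, partition) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m))) {
    if (length(partition) != nrow(m)) stop("partition/matrix size mismatch")
    dimnames(m) <- list(names(partition), names(partition))
  }
  if (!all(rownames(m) %in% names(partition)))
    stop("partition must cover all matrix labels (run align_partition first)")
  if (anyNA(m)) m[is.na(m)] <- 0
  m
}

#' Permutation test of partition quality in a modality matrix
#'
#' Null distribution: the chosen metric (strength fraction or modularity)
#' under uniformly shuffled area -> community assignments that preserve
#' the observed community sizes. One-sided
#' `p = (1 + #(null >= observed)) / (n_perm + 1)` — is the partition more
#' internally connected than chance?
#'
#' @param matrix symmetric labeled matrix.
#' @param partition aligned named partition over the matrix labels.
#' @param metric `"SF"` or `"Q"`.
#' @param n_perm number of shuffles (paper-scale 10,000).
#' @param seed integer seed.
#' @return list with `observed`, `p`, `null`, `metric`.
#' @export
permutation_test <- function(matrix, partition, metric = c("SF", "Q"),
                             n_perm = 10000L, seed = 1L) {
  metric <- match.arg(metric)
  if (n_perm < 100L) warning("n_perm < 100: p-value resolution is coarse")
  m <- .aligned_matrix(matrix, partition)
  g <- unclass(partition)[rownames(m)]
  fun <- if (metric == "SF") {
    ut <- upper.tri(m)
    vals <- m[ut]; total <- sum(vals)
    function(gg) sum(vals[outer(gg, gg, "==")[ut]]) / total
  } else {
    mm <- m; diag(mm) <- 0
    k <- rowSums(mm); two_m <- sum(k)
    B <- mm - outer(k, k) / two_m
    function(gg) sum(B[outer(gg, gg, "==")]) / two_m
  }
  obs <- fun(g)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    fun(sample(g)), 0))
  list(observed = obs, p = (1 + sum(null >= obs)) / (n_perm + 1),
       null = null, metric = metric)
}
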