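#' Network-level differential gene lists
#'
#' For each gene, the log2 ratio of its mean expression over a network's
#' areas to its mean over all remaining areas. Genes over-expressed by at
#' least a factor of 2 (`log2FC >= threshold_log2`, boundary inclusive)
#' or under-expressed by at least half (`<= -threshold_log2`) are listed
#' per network. Genes with a zero mean on either side are excluded and
#' counted.
#'
#' @param expr areas x genes nonnegative expression matrix.
#' @param partition named vector area -> community (labels must be a
#'   subset of the matrix's areas).
#' @param threshold_log2 fold threshold in log2 units (default 1).
#' @return named list per network: list with `log2fc` (named vector),
#'   `over`, `under` (gene name vectors), `n_excluded`.
#' @export
network_fold_genes <- function(expr, partition, threshold_log2 = 1.0) {
  expr <- as.matrix(expr)
  if (!all(names(partition) %in% rownames(expr)))
    stop("partition areas missing from expression matrix: ",
         paste(setdiff(names(partition), rownames(expr)), collapse = ", "))
  nets <- sort(unique(unclass(partition)))
  out <- lapply(nets, function(net) {
    inside <- names(partition)[unclass(partition) == net]
    outside <- setdiff(names(partition), inside)
    if (length(inside) == 0L) stop("network ", net, " is empty")
    mu_in <- colMeans(expr[inside, , drop = FALSE])
    mu_out <- colMeans(expr[outside, , drop = FALSE])
    ok <- mu_in > 0 & mu_out > 0
    lfc <- log2(mu_in[ok] / mu_out[ok])
    list(log2fc = lfc,
         over = names(lfc)[lfc >= threshold_log2],
         under = names(lfc)[lfc <= -threshold_log2],
         n_excluded = sum(!ok))
  })
  names(out) <- paste0("network", nets)
  out
}

#' Mitochondrial pathway scores
#'
#' Rescales each gene's expression across areas to mean 100 and SD 10
#' (a transformed z-score, so expression is directly comparable between
#' areas), then averages member-gene transformed values per pathway and
#' area. Pathways with no mapped gene in the matrix are dropped with a
#' report; constant genes are transformed to a flat 100 and flagged.
#'
#' @param expr areas x genes expression matrix, restricted to
#'   mitochondrial genes by the caller.
#' @param gene_to_pathway data.frame with columns `gene`, `pathway`
#'   (MitoCarta-style annotation; a gene may map to several pathways).
#' @param target_mean,target_sd transform parameters (100 and 10).
#' @return object of class `pathway_scores`: areas x pathways matrix with
#'   attributes `dropped_pathways`, `flat_genes`, `transform`.
#' @export
pathway_scores <- function(expr, gene_to_pathway,
                           target_mean = 100, target_sd = 10) {
  expr <- as.matrix(expr)
  stopifnot(all(c("gene", "pathway") %in% names(gene_to_pathway)))
  z <- apply(expr, 2L, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(target_mean, length(v))
    else target_mean + target_sd * (v - mean(v)) / s
  })
  rownames(z) <- rownames(expr)
  flat <- colnames(expr)[apply(expr, 2L, function(v) stats::sd(v) == 0)]
  map <- gene_to_pathway[gene_to_pathway$gene %in% colnames(expr), ]
  pathways <- unique(gene_to_pathway$pathway)
  kept <- intersect(pathways, unique(map$pathway))
  dropped <- setdiff(pathways, kept)
  scores <- sapply(kept, function(pw) {
    genes <- unique(map$gene[map$pathway == pw])
    rowMeans(z[, genes, drop = FALSE])
  })
  scores <- matrix(scores, nrow = nrow(expr),
                   dimnames = list(rownames(expr), kept))
  structure(scores, dropped_pathways = dropped, flat_genes = flat,
            transform = c(mean = target_mean, sd = target_sd),
            class = c("pathway_scores", "matrix", "array"))
}

#' Rank pathways by network-1 fold difference
#'
#' Mean pathway score over network-1 areas vs the mean over the combined
#' remaining networks; pathways sorted ascending by
#' `log2(mean_net1 / mean_rest)` (lowest in network 1 first). Pathways
#' with a nonpositive mean on either side are excluded and recorded.
#'
#' @param scores a `pathway_scores` matrix (areas x pathways).
#' @param partition named vector area -> community over the score areas.
#' @param network network of interest (default 1).
#' @return data.frame (pathway, mean_net, mean_rest, log2fc) sorted
#'   ascending, attribute `excluded`.
#' @export
rank_pathways <- function(scores, partition, network = 1L) {
  s <- as.matrix(scores)
  if (length(unique(unclass(partition))) < 2L)
    stop("need >= 2 networks represented")
  inside <- intersect(rownames(s), names(partition)[unclass(partition) == network])
  outside <- intersect(rownames(s), names(partition)[unclass(partition) != network])
  if (!length(inside) || !length(outside))
    stop("partition does not split the score areas")
  mu_in <- colMeans(s[inside, , drop = FALSE])
  mu_out <- colMeans(s[outside, , drop = FALSE])
  ok <- mu_in > 0 & mu_out > 0
  out <- data.frame(pathway = colnames(s)[ok],
                    mean_net = mu_in[ok], mean_rest = mu_out[ok],
                    log2fc = log2(mu_in[ok] / mu_out[ok]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$log2fc), ]
  attr(out, "excluded") <- colnames(s)[!ok]
  out
}

#' Mitotype ratio of two pathway scores
#'
#' Per-area ratio `score_a / score_b` quantifying molecular
#' specialization, plus the percentage difference of each area's ratio
#' relative to the cohort-mean ratio.
#'
#' @param scores a `pathway_scores` matrix.
#' @param pathway_a,pathway_b column names.
#' @return data.frame (area, ratio, pct_vs_mean); areas with a zero
#'   denominator are skipped.
#' @export
mitotype_ratio <- function(scores, pathway_a, pathway_b) {
  s <- as.matrix(scores)
  for (p in c(pathway_a, pathway_b))
    if (!p %in% colnames(s)) stop("pathway '", p, "' not in scores")
  den <- s[, pathway_b]
  keep <- den != 0
  ratio <- s[keep, pathway_a] / den[keep]
  data.frame(area = rownames(s)[keep], ratio = ratio,
             pct_vs_mean = 100 * (ratio / mean(ratio) - 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hierarchical clustering and principal-component projection of areas
#'
#' Agglomerative clustering (Ward's ward.D2 on Euclidean distances) of
#' areas by their score or expression profiles, plus the top-3
#' principal-component coordinates with explained-variance fractions.
#'
#' @param x areas x variables matrix (pathway scores or mito-gene
#'   expression).
#' @param standardize z-score each column first (per-pathway
#'   re-standardization mode).
#' @param n_components number of components to return (capped by rank).
#' @return list with `hclust`, `leaf_order` (area names), `projection`
#'   (areas x components), `explained_variance`.
#' @export
cluster_and_project <- function(x, standardize = FALSE, n_components = 3L) {
  m <- as.matrix(x)
  if (nrow(m) < 3L) stop("need >= 3 areas")
  if (standardize) {
    keep <- apply(m, 2L, stats::sd) > 0
    m <- scale(m[, keep, drop = FALSE])
  }
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(hclust = hc, leaf_order = rownames(m)[hc$order],
       projection = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)])
}
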