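#' Mapper configuration
#'
#' Parameters of the TDA Mapper pipeline: a 2-D filter embedding, an
#' overlapping grid cover (64 bins as an 8 x 8 grid, 70% overlap by
#' default; 49 and 81 bins give similar graphs), and single-linkage
#' partial clustering within bins using the classic edge-length histogram
#' gap heuristic.
#'
#' @param n_bins total bins of the 2-D cover; must be a perfect square.
#' @param overlap fractional bin overlap in `[0, 1)`.
#' @param n_hist_bins histogram bins for the clustering gap heuristic.
#' @param knn neighborhood size of the embedding filter.
#' @param seed integer seed (the spectral filter is deterministic; the
#'   seed is kept for pluggable stochastic filters).
#' @return object of class `mapper_config`.
#' @export
mapper_config <- function(n_bins = 64L, overlap = 0.70, n_hist_bins = 10L,
                          knn = 8L, seed = 1L) {
  g <- sqrt(n_bins)
  if (g != round(g)) stop("n_bins must be a perfect square for a 2-D grid")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  structure(list(n_bins = as.integer(n_bins), grid = as.integer(g),
                 overlap = overlap, n_hist_bins = as.integer(n_hist_bins),
                 knn = as.integer(knn), seed = as.integer(seed)),
            class = "mapper_config")
}

#' Stress-vs-naive delta matrix
#'
#' Builds the Mapper input: one row per (feature, brain area) pair (17
#' areas x 6 features = 102 rows) and one column per stressed animal,
#' each entry the stressed animal's value minus the naive-group mean for
#' that row. Missing cells are linearly interpolated within group along
#' the row order; rows with no naive data are dropped with a warning.
#'
#' @param cohort a `mito_cohort` or tidy cohort data.frame.
#' @param stress_group,naive_group group labels.
#' @return matrix with attributes `area` and `feature` per row.
#' @export
delta_matrix <- function(cohort, stress_group, naive_group = "naive") {
  tab <- if (inherits(cohort, "mito_cohort")) cohort$cohort else cohort
  tab <- tab[tab$site_class == "brain", ]
  for (g in c(stress_group, naive_group))
    if (!g %in% tab$group) stop("group '", g, "' absent from cohort")
  feats <- unique(tab$feature)
  areas <- unique(tab$site)
  rows <- expand.grid(site = areas, feature = feats,
                      stringsAsFactors = FALSE) # feature-major blocks
  rows <- rows[order(match(rows$feature, feats), match(rows$site, areas)), ]
  key <- paste(rows$feature, rows$site)

  pull <- function(group) {
    sub <- tab[tab$group == group, ]
    ids <- unique(sub$animal_id)
    m <- matrix(NA_real_, nrow(rows), length(ids),
                dimnames = list(key, ids))
    m[cbind(match(paste(sub$feature, sub$site), key),
            match(sub$animal_id, ids))] <- sub$value
    m
  }
  naive <- pull(naive_group)
  stress <- pull(stress_group)

  all_na <- rowSums(!is.na(naive)) == 0L
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " row(s) with no naive data")
    naive <- naive[!all_na, , drop = FALSE]
    stress <- stress[!all_na, , drop = FALSE]
    rows <- rows[!all_na, , drop = FALSE]
  }
  interp <- function(m) apply(m, 2L, function(col) {
    if (!anyNA(col)) return(col)
    if (all(is.na(col))) return(col)
    stats::approx(seq_along(col), col, xout = seq_along(col),
                  rule = 2)$y
  })
  naive <- interp(naive)
  stress <- interp(stress)
  delta <- stress - rowMeans(naive, na.rm = TRUE)
  structure(delta, area = rows$site, feature = rows$feature)
}

#' Neighborhood-preserving 2-D filter embedding
#'
#' The Mapper filter: a deterministic spectral neighborhood embedding
#' (Laplacian eigenmaps). Pairwise Euclidean distances between rows are
#' turned into a Gaussian affinity with locally adaptive bandwidth (the
#' distance to the `knn`-th neighbor), and the two nontrivial
#' eigenvectors of the normalized graph Laplacian give the 2-D filter
#' coordinates. Local neighborhoods are preserved: rows in separate
#' well-isolated clusters land in separable regions, and duplicated rows
#' get coincident coordinates.
#'
#' @param data numeric matrix, rows = points (>= 10 rows).
#' @param config a [mapper_config()].
#' @return n x 2 coordinate matrix.
#' @export
mapper_embed <- function(data, config = mapper_config()) {
  x <- as.matrix(data)
  if (nrow(x) < 10L) stop("need >= 10 rows to embed")
  if (all(apply(x, 2L, stats::sd, na.rm = TRUE) == 0))
    stop("constant data: no variance to embed")
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  k <- min(config$knn, n - 1L)
  # adaptive bandwidth: distance to the k-th nearest neighbor
  sigma <- apply(d, 1L, function(r) sort(r[-which.min(r)])[k])
  sigma <- pmax(sigma, 1e-8 * max(d, 1e-12))
  W <- exp(-d^2 / outer(sigma, sigma))
  diag(W) <- 0
  # sparsify to mutual-or-neighbor kNN to keep the embedding local
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    keep[i, nb] <- TRUE
  }
  keep <- keep | t(keep)
  W[!keep] <- 0
  deg <- pmax(rowSums(W), 1e-12)
  L <- diag(n) - diag(1 / sqrt(deg)) %*% W %*% diag(1 / sqrt(deg))
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  # smallest eigenvalues are last; skip the trivial constant direction
  idx <- c(n - 1L, n - 2L)
  coords <- diag(1 / sqrt(deg)) %*% eig$vectors[, idx, drop = FALSE]
  # deterministic sign convention
  for (j in 1:2) {
    s <- sign(coords[which.max(abs(coords[, j])), j])
    if (s < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(x), c("f1", "f2"))
  coords
}

#' Build the Mapper shape graph
#'
#' Covers the 2-D filter space with an overlapping grid (each base bin
#' expanded by the overlap fraction on both axes), performs single-linkage
#' partial clustering of each bin's members on their *original*
#' high-dimensional values (edge-length histogram gap heuristic), turns
#' every non-empty cluster into a node, and connects nodes from different
#' bins that share at least one row.
#'
#' @param coords n x 2 filter coordinates from [mapper_embed()].
#' @param data the original high-dimensional matrix (same row order).
#' @param config a [mapper_config()].
#' @return object of class `mapper_graph`: list with `nodes` (list of row
#'   index vectors), `node_bin`, `edges` (2-column matrix), `n_rows`, and
#'   `coords`.
#' @export
build_mapper <- function(coords, data, config = mapper_config()) {
  x <- as.matrix(data)
  n <- nrow(x)
  if (n == 0L) {
    return(structure(list(nodes = list(), node_bin = integer(),
                          edges = matrix(integer(), 0, 2), n_rows = 0L,
                          coords = coords), class = "mapper_graph"))
  }
  stopifnot(nrow(coords) == n)
  g <- config$grid
  ov <- config$overlap
  axis_bins <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) hi <- lo + 1e-9
    br <- seq(lo, hi, length.out = g + 1L)
    w <- diff(br)[1]
    data.frame(lo = br[-(g + 1L)], hi = br[-1L], ext = ov * w / 2)
  }
  bx <- axis_bins(coords[, 1]); by <- axis_bins(coords[, 2])
  members_in <- function(v, b, k, last) {
    if (ov == 0) {
      v >= b$lo[k] & (v < b$hi[k] | (last & v <= b$hi[k]))
    } else {
      v >= b$lo[k] - b$ext[k] & v <= b$hi[k] + b$ext[k]
    }
  }
  nodes <- list(); node_bin <- integer()
  bin_id <- 0L
  for (kx in seq_len(g)) {
    inx <- members_in(coords[, 1], bx, kx, kx == g)
    for (ky in seq_len(g)) {
      bin_id <- bin_id + 1L
      idx <- which(inx & members_in(coords[, 2], by, ky, ky == g))
      if (length(idx) == 0L) next
      for (cl in .partial_cluster(x[idx, , drop = FALSE], config$n_hist_bins)) {
        nodes[[length(nodes) + 1L]] <- idx[cl]
        node_bin <- c(node_bin, bin_id)
      }
    }
  }
  edges <- .shared_row_edges(nodes)
  structure(list(nodes = nodes, node_bin = node_bin, edges = edges,
                 n_rows = n, coords = coords), class = "mapper_graph")
}

# Single-linkage clustering with the classic Mapper gap heuristic: build
# a histogram of the merge heights over [0, max pairwise distance] with
# `nb` bins; cut at the lower edge of the first empty bin, if any.
.partial_cluster <- function(xs, nb) {
  m <- nrow(xs)
  if (m == 1L) return(list(1L))
  d <- stats::dist(xs)
  dmax <- max(d)
  if (dmax == 0) return(list(seq_len(m)))
  hc <- stats::hclust(d, method = "single")
  br <- seq(0, dmax * (1 + 1e-9), length.out = nb + 1L)
  counts <- graphics::hist(hc$height, breaks = br, plot = FALSE)$counts
  first_mass <- which(counts > 0L)[1L]
  empty <- which(counts == 0L & seq_along(counts) > first_mass)
  if (length(empty) == 0L) return(list(seq_len(m)))
  cutoff <- br[empty[1L]]
  labs <- stats::cutree(hc, h = cutoff)
  unname(split(seq_len(m), labs))
}

# Edges between nodes of different bins sharing at least one row:
# enumerate, per row, the pairs of nodes containing it.
.shared_row_edges <- function(nodes) {
  empty <- matrix(integer(), 0, 2, dimnames = list(NULL, c("from", "to")))
  nn <- length(nodes)
  if (nn < 2L) return(empty)
  row_id <- unlist(nodes, use.names = FALSE)
  node_id <- rep.int(seq_len(nn), lengths(nodes))
  by_row <- split(node_id, row_id)
  pairs <- lapply(by_row, function(ns) {
    if (length(ns) < 2L) return(NULL)
    t(utils::combn(sort(ns), 2L))
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  pairs <- unique(pairs)
  colnames(pairs) <- c("from", "to")
  pairs
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat("<mapper_graph>", length(x$nodes), "nodes,", nrow(x$edges),
      "edges, over", x$n_rows, "rows\n")
  invisible(x)
}
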