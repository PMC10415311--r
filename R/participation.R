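#' Participation coefficient of Mapper nodes
#'
#' Quantifies integration vs segregation of a shape graph annotated by
#' communities: for node i, `P_i = 1 - sum_s (kappa_is / k_i)^2`, where
#' `kappa_is` counts links from i to nodes of community s and `k_i` is
#' the degree. P is near 1 when links spread uniformly over communities
#' (integrated) and 0 when they stay within the node's own community
#' (segregated). Isolated nodes get P = 0; the graph-level value is the
#' mean over non-isolated nodes.
#'
#' Each node's community is the majority community of its member rows
#' (ties broken by the lowest community index).
#'
#' @param graph a `mapper_graph`.
#' @param row_communities community label per input row (e.g. the area
#'   label of each of the 102 delta-matrix rows).
#' @return list with `node_pc`, `node_community`, and `mean_pc`.
#' @export
participation_coefficient <- function(graph, row_communities) {
  if (length(row_communities) == 0L) stop("empty community mapping")
  if (length(row_communities) != graph$n_rows)
    stop("row_communities must have one label per input row")
  levels_ <- unique(row_communities)
  node_comm <- vapply(graph$nodes, function(rows) {
    tab <- table(factor(row_communities[rows], levels = levels_))
    names(tab)[which.max(tab)] # which.max takes the first (lowest index) tie
  }, "")
  nn <- length(graph$nodes)
  pc <- numeric(nn)
  if (nn && nrow(graph$edges)) {
    adj <- lapply(seq_len(nn), function(i) integer())
    for (e in seq_len(nrow(graph$edges))) {
      i <- graph$edges[e, 1L]; j <- graph$edges[e, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    for (i in seq_len(nn)) {
      k <- length(adj[[i]])
      if (k == 0L) next
      kappa <- table(node_comm[adj[[i]]])
      pc[i] <- 1 - sum((kappa / k)^2)
    }
    isolated <- lengths(adj) == 0L
  } else {
    isolated <- rep(TRUE, nn)
  }
  mean_pc <- if (all(isolated)) 0 else mean(pc[!isolated])
  list(node_pc = pc, node_community = node_comm, mean_pc = mean_pc,
       isolated = isolated)
}

#' Run the full Mapper + participation-coefficient pipeline on one matrix
#'
#' Convenience wrapper: embed, build the shape graph, and compute the
#' area-annotated participation coefficient.
#'
#' @param delta matrix with an `area` attribute (from [delta_matrix()]),
#'   or any matrix plus explicit `row_communities`.
#' @param config a [mapper_config()].
#' @param row_communities labels per row; defaults to `attr(delta, "area")`.
#' @return list with `graph`, `pc` (participation result), `mean_pc`.
#' @export
mapper_pc <- function(delta, config = mapper_config(),
                      row_communities = NULL) {
  row_communities <- row_communities %||% attr(delta, "area")
  if (is.null(row_communities)) stop("row_communities required")
  coords <- mapper_embed(delta, config)
  graph <- build_mapper(coords, delta, config)
  pc <- participation_coefficient(graph, row_communities)
  list(graph = graph, pc = pc, mean_pc = pc$mean_pc)
}
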