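#' Read and write pipeline file formats
#'
#' Plain-text interchange formats: tidy cohort CSV (animal_id, group,
#' site, site_class, feature, value), behavior CSV (animal_id, test,
#' score), labeled square matrix TSV (header row + first column of
#' labels), two-column partition CSV (area, community), and JSON
#' configuration. All readers validate the schema and name the offending
#' column or label in their errors.
#'
#' @param path file path.
#' @param x object to write.
#' @name mitonet-io
NULL

.check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}

#' @rdname mitonet-io
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("animal_id", "group", "site", "site_class",
                       "feature", "value"), "cohort file")
  bad <- setdiff(unique(df$site_class), c("brain", "tissue"))
  if (length(bad))
    stop("cohort file has unknown site_class value(s): ",
         paste(bad, collapse = ", "))
  df$value <- as.numeric(df$value)
  df
}

#' @rdname mitonet-io
#' @export
write_cohort_csv <- function(x, path) {
  tab <- if (inherits(x, "mito_cohort")) x$cohort else x
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mitonet-io
#' @param known_sites optional site vocabulary; unknown labels are
#'   rejected by name.
#' @export
read_behavior_csv <- function(path, known_sites = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("animal_id", "test", "score"), "behavior file")
  df$score <- as.numeric(df$score)
  df
}

#' @rdname mitonet-io
#' @export
write_behavior_csv <- function(x, path) {
  tab <- if (inherits(x, "mito_cohort")) x$behaviors else x
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mitonet-io
#' @export
read_square_tsv <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("matrix file is not square: ", nrow(m), " rows x ", ncol(m), " cols")
  if (!identical(rownames(m), colnames(m)))
    stop("matrix row labels do not match column labels")
  if (anyDuplicated(rownames(m)))
    stop("duplicate matrix label(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  storage.mode(m) <- "double"
  m
}

#' @rdname mitonet-io
#' @export
write_square_tsv <- function(x, path) {
  m <- as.matrix(x)
  utils::write.table(data.frame(label = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname mitonet-io
#' @export
read_partition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("area", "community"), "partition file")
  if (anyDuplicated(df$area))
    stop("duplicate area(s) in partition file: ",
         paste(unique(df$area[duplicated(df$area)]), collapse = ", "))
  structure(stats::setNames(as.integer(df$community), df$area),
            class = "partition")
}

#' @rdname mitonet-io
#' @export
write_partition_csv <- function(x, path) {
  utils::write.csv(data.frame(area = names(x), community = as.integer(x)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname mitonet-io
#' @export
write_config_json <- function(x, path) {
  # named atomic vectors become JSON objects so labels survive round trips
  conv <- function(v) {
    if (is.list(v)) lapply(v, conv)
    else if (is.atomic(v) && !is.null(names(v))) as.list(v)
    else v
  }
  jsonlite::write_json(conv(unclass(x)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname mitonet-io
#' @export
read_config_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a Mapper graph as GraphML
#'
#' Writes nodes (with bin id and member-row count) and edges in GraphML,
#' readable by igraph, Gephi, or Cytoscape.
#'
#' @param graph a `mapper_graph`.
#' @param path output file.
#' @export
write_graphml <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="bin" for="node" attr.name="bin" attr.type="int"/>')
  w('  <key id="size" for="node" attr.name="n_rows" attr.type="int"/>')
  w('  <graph edgedefault="undirected">')
  for (i in seq_along(graph$nodes)) {
    w('    <node id="n', i, '">')
    w('      <data key="bin">', graph$node_bin[i], '</data>')
    w('      <data key="size">', length(graph$nodes[[i]]), '</data>')
    w('    </node>')
  }
  if (nrow(graph$edges))
    for (e in seq_len(nrow(graph$edges)))
      w('    <edge source="n', graph$edges[e, 1L],
        '" target="n', graph$edges[e, 2L], '"/>')
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}
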