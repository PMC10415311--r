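#' Mitochondrial connectivity matrix over (site x feature) rows
#'
#' Across-animal Pearson correlation of every (site, feature) pair,
#' pairwise-complete so that whole-site missingness costs only the
#' affected entries. Entries resting on fewer than `min_n` overlapping
#' animals are set NA. With the default 17 brain areas and 6 features the
#' result is the 102 x 102 matrix; `include_tissues = TRUE` extends it to
#' all 22 sites. A hierarchical-clustering leaf order (Euclidean distance,
#' Ward's method) is attached as attribute `order`.
#'
#' @param cohort a `mito_cohort` or tidy cohort data.frame
#'   (animal_id, site, site_class, feature, value).
#' @param include_tissues include peripheral tissues as sites.
#' @param min_n minimum overlapping animals per entry (default 4).
#' @return A `connectivity_matrix`: symmetric correlation matrix with unit
#'   diagonal, row/col names `"site|feature"`, attributes `site`,
#'   `feature`, `n_used` (per-entry overlap counts), and `order`.
#' @export
feature_area_matrix <- function(cohort, include_tissues = FALSE, min_n = 4L) {
  tab <- if (inherits(cohort, "mito_cohort")) cohort$cohort else cohort
  if (!include_tissues) tab <- tab[tab$site_class == "brain", ]
  wide <- cohort_wide(tab)
  r <- suppressWarnings(stats::cor(wide, use = "pairwise.complete.obs"))
  n_used <- crossprod(!is.na(wide))
  r[n_used < min_n] <- NA_real_
  diag(r) <- 1
  parts <- strsplit(colnames(wide), "|", fixed = TRUE)
  site <- vapply(parts, `[`, "", 1L)
  feature <- vapply(parts, `[`, "", 2L)
  ord <- tryCatch({
    d <- stats::dist(ifelse(is.na(r), 0, r))
    stats::hclust(d, method = "ward.D2")$order
  }, error = function(e) seq_len(ncol(r)))
  structure(r, site = site, feature = feature, n_used = n_used,
            order = ord, class = c("connectivity_matrix", "matrix", "array"))
}

# Animals x (site|feature) wide matrix from the tidy cohort table.
cohort_wide <- function(tab) {
  ids <- unique(tab$animal_id)
  key <- paste(tab$site, tab$feature, sep = "|")
  cols <- unique(key)
  wide <- matrix(NA_real_, length(ids), length(cols),
                 dimnames = list(ids, cols))
  wide[cbind(match(tab$animal_id, ids), match(key, cols))] <- tab$value
  wide
}

#' Per-feature area-by-area correlation slices
#'
#' One weighted adjacency slice per mitochondrial feature: the pairwise
#' Pearson correlation between brain areas across animals, all slices
#' sharing one node ordering. These slices are the input to multi-slice
#' community detection.
#'
#' @inheritParams feature_area_matrix
#' @param features which features to slice (default: all in the cohort).
#' @return A `multilayer_network`: named list of symmetric area x area
#'   matrices with attribute `areas`.
#' @export
per_feature_slices <- function(cohort, features = NULL, min_n = 4L) {
  tab <- if (inherits(cohort, "mito_cohort")) cohort$cohort else cohort
  tab <- tab[tab$site_class == "brain", ]
  features <- features %||% unique(tab$feature)
  areas <- unique(tab$site)
  slices <- lapply(features, function(f) {
    sub <- tab[tab$feature == f, ]
    ids <- unique(sub$animal_id)
    wide <- matrix(NA_real_, length(ids), length(areas),
                   dimnames = list(ids, areas))
    wide[cbind(match(sub$animal_id, ids), match(sub$site, areas))] <- sub$value
    r <- suppressWarnings(stats::cor(wide, use = "pairwise.complete.obs"))
    n_used <- crossprod(!is.na(wide))
    r[n_used < min_n] <- NA_real_
    diag(r) <- 1
    r
  })
  names(slices) <- features
  structure(slices, areas = areas, class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat("<multilayer_network>", length(x), "slices x",
      length(attr(x, "areas")), "areas:",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Nodal degree: mean inter-area correlation per brain area
#'
#' For each area, the mean of its correlations with all other areas (self
#' excluded). When the matrix has (site x feature) rows, feature-level
#' entries are first averaged within each area pair.
#'
#' @param matrix a `connectivity_matrix`, or a plain symmetric area x area
#'   correlation matrix.
#' @return named numeric vector, one mean correlation per area.
#' @export
nodal_degree <- function(matrix) {
  am <- area_average_matrix(matrix)
  diag(am) <- NA
  sort(rowMeans(am, na.rm = TRUE), decreasing = TRUE)
}

# Collapse a (site|feature) correlation matrix to area level by averaging
# all feature-pair entries within each ordered area pair (self-pairs use
# only cross-feature entries, but nodal degree drops the diagonal anyway).
area_average_matrix <- function(matrix) {
  site <- attr(matrix, "site")
  if (is.null(site)) return(as.matrix(matrix))
  areas <- unique(site)
  m <- as.matrix(matrix)
  out <- matrix(NA_real_, length(areas), length(areas),
                dimnames = list(areas, areas))
  for (i in seq_along(areas)) for (j in seq_len(i)) {
    block <- m[site == areas[i], site == areas[j], drop = FALSE]
    if (i == j) diag(block) <- NA
    out[i, j] <- out[j, i] <- mean(block, na.rm = TRUE)
  }
  out
}

#' Permutation test of within- vs between-site modularity
#'
#' Statistic: mean(within-site entries) - mean(between-site entries) of a
#' (site x feature) correlation matrix, diagonal excluded. The null
#' shuffles the row/column site labels `n_perm` times;
#' `p = (1 + #(null >= observed)) / (n_perm + 1)` (one-sided: higher =
#' more modular).
#'
#' @param matrix a `connectivity_matrix` or symmetric matrix.
#' @param site_labels per-row site labels (defaults to the matrix's
#'   `site` attribute).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with `statistic`, `p`, `null` (the permuted statistics).
#' @export
within_between_permutation <- function(matrix, site_labels = NULL,
                                       n_perm = 2000L, seed = 1L) {
  site <- site_labels %||% attr(matrix, "site")
  if (is.null(site)) stop("site labels required")
  if (length(unique(site)) < 2L) stop("need >= 2 sites")
  if (n_perm < 100L) warning("n_perm < 100: p-value resolution is coarse")
  m <- as.matrix(matrix)
  ut <- upper.tri(m)
  vals <- m[ut]
  stat_for <- function(lab) {
    within <- outer(lab, lab, "==")[ut]
    mean(vals[within], na.rm = TRUE) - mean(vals[!within], na.rm = TRUE)
  }
  obs <- stat_for(site)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stat_for(sample(site)), 0))
  list(statistic = obs, p = (1 + sum(null >= obs)) / (n_perm + 1), null = null)
}
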