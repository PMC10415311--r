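#' Generate a synthetic cross-modal area-by-area matrix
#'
#' Stand-in for independent-modality matrices (gene co-expression, or a
#' structural connectome's normalized projection strengths) with a planted
#' block structure: entries between areas of the same community are drawn
#' around `within_w`, other entries around `between_w`, plus symmetric
#' Gaussian noise.
#'
#' @param partition named vector area -> community label.
#' @param within_w,between_w expected within/between-community entry
#'   (`within_w > between_w >= 0`).
#' @param noise_sd SD of added symmetric noise.
#' @param seed integer seed.
#' @param kind `"coexpression"` (unit diagonal, entries clipped to
#'   \[-1, 1\]) or `"connectome"` (nonnegative strengths, zero diagonal).
#' @return Symmetric labeled matrix of class `modal_matrix`.
#' @export
generate_modal_matrix <- function(partition, within_w, between_w,
                                  noise_sd = 0, seed = 1L,
                                  kind = c("coexpression", "connectome")) {
  kind <- match.arg(kind)
  if (!(within_w > between_w && between_w >= 0))
    stop("need within_w > between_w >= 0")
  areas <- names(partition)
  if (is.null(areas)) stop("partition must be a named vector (area -> community)")
  k <- length(areas)
  same <- outer(partition, partition, "==")
  base <- ifelse(same, within_w, between_w)
  m <- with_seed(seed, {
    noise <- matrix(stats::rnorm(k * k, sd = noise_sd), k, k)
    noise <- (noise + t(noise)) / 2
    base + noise
  })
  dimnames(m) <- list(areas, areas)
  if (kind == "coexpression") {
    m <- pmin(pmax(m, -1), 1)
    diag(m) <- 1
  } else {
    m <- pmax(m, 0)
    diag(m) <- 0
  }
  structure(m, kind = kind, class = c("modal_matrix", "matrix", "array"))
}
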