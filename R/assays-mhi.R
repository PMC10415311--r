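#' Mitochondrial Health Index (MHI)
#'
#' Integrates the five primary mitochondrial features of one site into an
#' index of respiratory-chain activity per mitochondrion:
#' `MHI = (CI + CII + CIV) / (CS + mtDNA density + 1) * 100`, where each
#' feature is first mean-centered across animals within the site by
#' dividing by its across-animal mean (so the cohort-average animal sits
#' at 1 on every feature). An animal with average values on all five
#' features therefore scores exactly (1+1+1)/(1+1+1)*100 = 100. The `+ 1`
#' balances the 3-term numerator against the 2-term content denominator.
#'
#' @param features matrix or data.frame (animals x features) with columns
#'   CI, CII, CIV, CS, mtdna_density. Rows with any missing feature get
#'   MHI = NA but still contribute nothing to the means.
#' @return numeric vector of per-animal MHI values (named by rownames).
#' @export
compute_mhi <- function(features) {
  features <- as.matrix(features)
  need <- c("CI", "CII", "CIV", "CS", "mtdna_density")
  if (!all(need %in% colnames(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  x <- features[, need, drop = FALSE]
  complete <- stats::complete.cases(x)
  if (sum(complete) < 2L)
    stop("need >= 2 animals with complete 5-feature vectors")
  mu <- colMeans(x, na.rm = TRUE)
  if (any(!is.finite(mu)) || any(mu == 0))
    stop("a feature has zero/undefined mean for this site; skipping")
  c_ <- sweep(x, 2L, mu, "/")
  mhi <- (c_[, "CI"] + c_[, "CII"] + c_[, "CIV"]) /
         (c_[, "CS"] + c_[, "mtdna_density"] + 1) * 100
  stats::setNames(as.numeric(mhi), rownames(features))
}
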