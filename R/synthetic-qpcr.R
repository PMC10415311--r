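#' Generate a synthetic qPCR plate of Ct triplicates
#'
#' Emulates duplex TaqMan reactions quantifying a mitochondrial (COX1) and
#' a nuclear (B2M) amplicon in triplicate. The noiseless delta-Ct encodes
#' the requested copy number under `mtDNAcn = 2^dCt * 2`, i.e.
#' `dCt = log2(true_cn / 2)`; replicate noise is Gaussian with SD
#' `cv * Ct`, and a fraction of samples get one grossly offset replicate
#' (flagged in the truth columns) to exercise triplicate QC.
#'
#' @param n_samples number of samples.
#' @param true_cn copy number per sample (scalar recycled, or length
#'   `n_samples`); must be > 0.
#' @param cv replicate coefficient of variation of the Ct values.
#' @param outlier_rate fraction of samples with one injected outlier
#'   replicate (+4 cycles on the mitochondrial amplicon).
#' @param seed integer seed.
#' @param n_baseline_ct noiseless nuclear-amplicon Ct (default 24).
#' @return data.frame with sample_id, mt_ct1..3, n_ct1..3, and truth
#'   columns `true_cn` and `outlier_injected`.
#' @export
generate_qpcr_plate <- function(n_samples, true_cn, cv = 0.01,
                                outlier_rate = 0, seed = 1L,
                                n_baseline_ct = 24) {
  stopifnot(n_samples >= 1, all(true_cn > 0), cv >= 0,
            outlier_rate >= 0, outlier_rate <= 1)
  true_cn <- rep_len(true_cn, n_samples)
  dct <- log2(true_cn / 2)
  n_ct0 <- rep(n_baseline_ct, n_samples)
  mt_ct0 <- n_ct0 - dct
  with_seed(seed, {
    noise <- function(ct0) sapply(1:3, function(i)
      ct0 * (1 + cv * stats::rnorm(n_samples)))
    mt <- noise(mt_ct0)
    nn <- noise(n_ct0)
    outlier <- stats::runif(n_samples) < outlier_rate
    if (any(outlier)) {
      rep_idx <- sample.int(3, sum(outlier), replace = TRUE)
      mt[cbind(which(outlier), rep_idx)] <-
        mt[cbind(which(outlier), rep_idx)] + 4
    }
    data.frame(
      sample_id = sprintf("S%03d", seq_len(n_samples)),
      mt_ct1 = mt[, 1], mt_ct2 = mt[, 2], mt_ct3 = mt[, 3],
      n_ct1 = nn[, 1], n_ct2 = nn[, 2], n_ct3 = nn[, 3],
      true_cn = true_cn, outlier_injected = outlier,
      stringsAsFactors = FALSE)
  })
}
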