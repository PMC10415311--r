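#' mtDNA copy number from Ct triplicates with QC
#'
#' Applies the triplicate QC pipeline, in order: (1) samples whose mean Ct
#' for either amplicon exceeds 33 are excluded; (2) if a triplicate CV
#' exceeds 0.02, the replicate farthest from the median is dropped and the
#' remaining duplicate used; (3) if the CV of what remains still exceeds
#' 0.1, the sample is discarded. Then `dCt = mean(nuclear Ct) - mean(mito
#' Ct)` and `mtDNAcn = 2^dCt * 2`.
#'
#' @param mt_cts up to 3 mitochondrial-amplicon Ct values.
#' @param n_cts up to 3 nuclear-amplicon Ct values.
#' @param ct_max exclusion cutoff on the mean Ct (default 33).
#' @param cv_check CV above which the outlier replicate is dropped (0.02).
#' @param cv_max CV above which the sample is discarded (0.1).
#' @return list with `mtdnacn` (NA when discarded), `delta_ct`, and `qc`
#'   reason string.
#' @export
ct_to_mtdnacn <- function(mt_cts, n_cts, ct_max = 33,
                          cv_check = 0.02, cv_max = 0.1) {
  clean <- function(cts) {
    cts <- cts[!is.na(cts)]
    if (length(cts) == 0L) return(list(mean = NA_real_, qc = "no Ct values"))
    if (any(cts <= 0)) return(list(mean = NA_real_, qc = "nonpositive Ct"))
    cv <- if (length(cts) >= 2L) stats::sd(cts) / mean(cts) else 0
    if (cv > cv_check && length(cts) >= 3L) {
      drop <- which.max(abs(cts - stats::median(cts)))
      cts <- cts[-drop]
      cv <- stats::sd(cts) / mean(cts)
    }
    if (cv > cv_max) return(list(mean = NA_real_, qc = "replicate CV > 0.1"))
    list(mean = mean(cts), qc = "pass")
  }
  mt <- clean(mt_cts); nn <- clean(n_cts)
  fail <- function(reason) list(mtdnacn = NA_real_, delta_ct = NA_real_, qc = reason)
  if (is.na(mt$mean)) return(fail(paste("mt:", mt$qc)))
  if (is.na(nn$mean)) return(fail(paste("nDNA:", nn$qc)))
  if (mt$mean > ct_max || nn$mean > ct_max)
    return(fail(sprintf("mean Ct > %g exclusion cutoff", ct_max)))
  dct <- nn$mean - mt$mean
  list(mtdnacn = 2^dct * 2, delta_ct = dct, qc = "pass")
}

#' mtDNA density from a mitochondrial Ct value
#'
#' Linearizes a QC-passed mitochondrial Ct into relative mtDNA abundance
#' per unit of tissue. Two modes are provided because the published
#' linearization, `2^Ct / (1/10^-12)`, *increases* with Ct — the opposite
#' of qPCR biology (more template means a lower Ct). `"verbatim"` returns
#' the formula exactly as printed; `"sign_corrected"` returns
#' `2^(-Ct) * 10^12`, which halves per extra cycle. The mode used is
#' recorded in the result's `mode` attribute.
#'
#' @param mt_ct mean mitochondrial Ct (vectorized).
#' @param mode `"verbatim"` or `"sign_corrected"`.
#' @return numeric vector of relative densities with attribute `mode`.
#' @export
ct_to_mtdna_density <- function(mt_ct, mode = c("verbatim", "sign_corrected")) {
  mode <- match.arg(mode)
  out <- switch(mode,
    verbatim = 2^mt_ct * 1e-12,
    sign_corrected = 2^(-mt_ct) * 1e12)
  attr(out, "mode") <- mode
  out
}
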