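# Measure sets and sign conventions per behavioral test. A multiplier of
# -1 flips a measure so that higher always means more avoidant/anxious:
# SI ratio and SI-zone time, OFT center measures, and EPM open-arm time
# all decrease with avoidance and are inverted; corner measures and NSF
# latency already increase with avoidance.
.behavior_measures <- list(
  OFT = c(center_time = -1, center_distance = -1),
  EPM = c(open_arm_time = -1),
  NSF = c(latency = 1),
  SI  = c(si_ratio = -1, corner_ratio = 1, si_zone_time = -1, corner_time = 1)
)

#' Composite behavioral z-score for one test
#'
#' Z-scores each raw measure across animals, applies the test's sign
#' conventions so that higher always indicates higher avoidance/anxiety,
#' and averages the signed z-scores into one composite per animal. NSF
#' latencies are right-censored at 600 s before z-scoring. Animals with
#' all measures missing get NA (never imputed).
#'
#' @param raw data.frame or matrix (animals x measures) whose columns are
#'   the test's measures (see `mitonet:::.behavior_measures`); row names
#'   (or an `animal_id` column) identify animals.
#' @param test one of `"OFT"`, `"EPM"`, `"NSF"`, `"SI"`.
#' @param nsf_cap right-censoring cap for NSF latency, seconds.
#' @return named numeric vector of composite scores (cohort mean 0).
#' @export
behavior_zscore <- function(raw, test = c("OFT", "EPM", "NSF", "SI"),
                            nsf_cap = 600) {
  test <- match.arg(test)
  raw <- as.data.frame(raw)
  ids <- if ("animal_id" %in% names(raw)) {
    a <- raw$animal_id; raw$animal_id <- NULL; a
  } else rownames(raw) %||% seq_len(nrow(raw))
  signs <- .behavior_measures[[test]]
  missing_cols <- setdiff(names(signs), names(raw))
  if (length(missing_cols))
    stop(test, " requires measure column(s): ",
         paste(missing_cols, collapse = ", "))
  x <- as.matrix(raw[, names(signs), drop = FALSE])
  if (sum(stats::complete.cases(x)) < 3L)
    stop("need >= 3 animals with measures for z-scoring")
  if (test == "NSF") x[, "latency"] <- pmin(x[, "latency"], nsf_cap)
  z <- scale(x)
  z <- sweep(z, 2L, signs, "*")
  stats::setNames(rowMeans(z, na.rm = FALSE), ids)
}
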