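#' Specific enzymatic activity from replicate absorbance slopes
#'
#' Converts replicate reporter-absorbance slopes into a specific activity:
#' mean of replicates minus the non-specific (negative control) slope,
#' times the extinction/dilution normalization factor. The technical CV of
#' the replicates is checked against a 10% cutoff; failing samples are
#' flagged (and excluded when `exclude_failing = TRUE`).
#'
#' @param replicate_slopes numeric vector of replicate slopes (OD/s);
#'   NAs dropped.
#' @param nonspecific_slope negative-control slope.
#' @param factor extinction-coefficient x dilution multiplier (> 0).
#' @param cv_cutoff replicate CV threshold (default 0.10).
#' @param exclude_failing if TRUE, samples failing the CV cutoff get
#'   `activity = NA`; otherwise the value is kept but flagged.
#' @return list with `activity`, `cv`, `flag` (TRUE when CV exceeds the
#'   cutoff), and `qc` reason string.
#' @export
specific_activity <- function(replicate_slopes, nonspecific_slope = 0,
                              factor = 1, cv_cutoff = 0.10,
                              exclude_failing = FALSE) {
  stopifnot(factor > 0, length(nonspecific_slope) == 1L)
  s <- replicate_slopes[!is.na(replicate_slopes)]
  if (length(s) == 0L)
    return(list(activity = NA_real_, cv = NA_real_, flag = TRUE,
                qc = "all replicates missing"))
  m <- mean(s)
  cv <- if (length(s) >= 2L && m != 0) stats::sd(s) / abs(m) else 0
  flag <- cv > cv_cutoff
  act <- (m - nonspecific_slope) * factor
  if (flag && exclude_failing) act <- NA_real_
  list(activity = act, cv = cv, flag = flag,
       qc = if (flag) sprintf("replicate CV %.3f exceeds %.2f cutoff", cv, cv_cutoff)
            else "pass")
}

#' Plate normalization by positive controls
#'
#' Each plate carries a positive control (heart homogenate); plates are
#' aligned by multiplying all activities on a plate by
#' `assay_reference / plate_control` so that a plate whose control sits at
#' the assay-wide reference level has factor 1. Plates with a nonpositive
#' control are excluded (values set NA) with a warning.
#'
#' @param activities numeric vector of activities.
#' @param plate_id plate identifier per activity.
#' @param positive_controls named vector plate_id -> control activity.
#' @param assay_reference reference level; defaults to the mean of the
#'   positive controls across plates.
#' @return list with `normalized` activities, `factors` (per plate), and
#'   `excluded_plates`.
#' @export
normalize_plate <- function(activities, plate_id, positive_controls,
                            assay_reference = NULL) {
  plate_id <- as.character(plate_id)
  plates <- unique(plate_id)
  if (!all(plates %in% names(positive_controls)))
    stop("positive control missing for plate(s): ",
         paste(setdiff(plates, names(positive_controls)), collapse = ", "))
  pc <- positive_controls[plates]
  bad <- !is.finite(pc) | pc <= 0
  if (is.null(assay_reference)) assay_reference <- mean(pc[!bad])
  factors <- assay_reference / pc
  factors[bad] <- NA_real_
  if (any(bad))
    warning("excluding plate(s) with nonpositive positive control: ",
            paste(plates[bad], collapse = ", "))
  out <- unname(activities * factors[match(plate_id, plates)])
  list(normalized = out, factors = stats::setNames(factors, plates),
       excluded_plates = plates[bad])
}
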