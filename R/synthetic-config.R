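#' Configuration for the synthetic cohort generator
#'
#' Describes the statistical world the generator emulates: a cohort of mice
#' in four exposure groups (naive, chronic corticosterone, chronic social
#' defeat stress, and CSDS followed by recovery), profiled across 17 brain
#' areas and 5 peripheral tissues on six mitochondrial features, with a
#' planted 3-community block structure over brain areas, stressor effect
#' sizes, behavior scores coupled to the network-1 mitochondrial signal,
#' and site-level missingness.
#'
#' Inter-area correlation is induced by shared per-animal latent factors:
#' one global brain factor, one factor per planted community, and one per
#' site. For two areas in the same block the expected correlation is
#' `within_block_r`; across blocks it is `between_block_r`. With the
#' default block sizes (6/7/4) and defaults 0.45/0.09 the overall mean
#' brain coupling is ~0.2 (`brain_mean_r`, a derived target recorded for
#' reference, not a free knob).
#'
#' @param n_per_group animals per group: a single count applied to all four
#'   groups, or a named vector over `c("naive","cort","csds","csds_rec")`.
#'   Default mirrors the study design (11/5/6/5, 27 animals).
#' @param areas ordered brain area names (17).
#' @param tissues ordered peripheral tissue names (5).
#' @param planted_partition named integer vector area -> community label.
#' @param within_block_r,between_block_r target inter-area correlations
#'   inside and across blocks; must satisfy `between_block_r < within_block_r < 1`.
#' @param within_area_r target correlation between two features of the same
#'   area (cross-feature co-regulation); defaults to
#'   `max(0.70, within_block_r)` and must lie in `[within_block_r, 1)`.
#' @param brain_mean_r documented overall brain coupling implied by the
#'   block targets (recomputed, not settable).
#' @param cort_effect,csds_effect per-area group shifts on the Hedges-g
#'   scale (shift = g * within-area SD). Defaults: CORT positive in ~60%
#'   of areas, CSDS negative in ~82%.
#' @param behavior_coupling named vector of signed correlations between
#'   each behavioral score and the network-1 mitochondrial mean
#'   (EPM/OFT positive, SI negative).
#' @param noise_cv between-animal coefficient of variation; named vector
#'   `c(brain = 0.36, tissue = 0.25)`.
#' @param missing_rate fraction of (animal, brain area) sites masked
#'   (whole-site loss, emulating cracked-section losses).
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_per_group = c(naive = 11, cort = 5, csds = 6, csds_rec = 5),
                             areas = mito_areas(),
                             tissues = mito_tissues(),
                             planted_partition = default_partition(),
                             within_block_r = 0.45,
                             between_block_r = 0.09,
                             within_area_r = NULL,
                             cort_effect = NULL,
                             csds_effect = NULL,
                             behavior_coupling = c(OFT = 0.40, EPM = 0.70,
                                                   NSF = 0.10, SI = -0.69),
                             noise_cv = c(brain = 0.36, tissue = 0.25),
                             missing_rate = 0.03,
                             seed = 1L) {
  groups <- c("naive", "cort", "csds", "csds_rec")
  if (length(n_per_group) == 1L && is.null(names(n_per_group))) {
    n_per_group <- stats::setNames(rep(as.integer(n_per_group), 4L), groups)
  }
  if (!all(groups %in% names(n_per_group)))
    stop("n_per_group must cover groups: ", paste(groups, collapse = ", "))
  n_per_group <- as.integer(n_per_group[groups])
  names(n_per_group) <- groups
  if (any(n_per_group < 3L))
    stop("n_per_group must be >= 3 in every group (correlation stages need >= 3 animals)")

  areas <- as.character(areas)
  tissues <- as.character(tissues)
  if (anyDuplicated(c(areas, tissues))) stop("area/tissue names must be unique")
  if (!setequal(names(planted_partition), areas))
    stop("planted_partition must cover every area exactly once")
  planted_partition <- planted_partition[areas]

  if (!(abs(within_block_r) < 1 && abs(between_block_r) < 1))
    stop("|within_block_r| and |between_block_r| must be < 1")
  if (within_block_r <= between_block_r)
    stop("within_block_r must exceed between_block_r")
  if (between_block_r < 0) stop("between_block_r must be >= 0")
  within_area_r <- within_area_r %||% max(0.70, within_block_r)
  if (within_area_r < within_block_r || within_area_r >= 1)
    stop("within_area_r must lie in [within_block_r, 1)")

  n_area <- length(areas)
  if (is.null(cort_effect)) {
    # positive in ~60% of areas (10/17), mild negative elsewhere
    cort_effect <- stats::setNames(rep(-0.20, n_area), areas)
    cort_effect[seq_len(ceiling(0.6 * n_area))] <- 0.35
  }
  if (is.null(csds_effect)) {
    # negative in ~82% of areas (14/17)
    csds_effect <- stats::setNames(rep(-0.50, n_area), areas)
    csds_effect[seq_len(n_area) > round(0.82 * n_area)] <- 0.20
  }
  stopifnot(setequal(names(cort_effect), areas), setequal(names(csds_effect), areas))
  cort_effect <- cort_effect[areas]
  csds_effect <- csds_effect[areas]

  tests <- c("OFT", "EPM", "NSF", "SI")
  if (!all(tests %in% names(behavior_coupling)))
    stop("behavior_coupling must name tests: ", paste(tests, collapse = ", "))
  behavior_coupling <- behavior_coupling[tests]
  if (any(abs(behavior_coupling) >= 1)) stop("|behavior_coupling| must be < 1")

  stopifnot(all(c("brain", "tissue") %in% names(noise_cv)), all(noise_cv > 0))
  stopifnot(missing_rate >= 0, missing_rate < 0.5)

  # implied overall brain coupling (reference value)
  blocks <- split(areas, planted_partition)
  n_within <- sum(vapply(blocks, function(b) choose(length(b), 2), 0))
  n_total <- choose(n_area, 2)
  brain_mean_r <- (n_within * within_block_r +
                   (n_total - n_within) * between_block_r) / n_total

  structure(list(
    n_per_group = n_per_group, areas = areas, tissues = tissues,
    planted_partition = planted_partition,
    within_block_r = within_block_r, between_block_r = between_block_r,
    within_area_r = within_area_r, brain_mean_r = brain_mean_r,
    cort_effect = cort_effect, csds_effect = csds_effect,
    behavior_coupling = behavior_coupling, noise_cv = noise_cv,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  animals:", sum(x$n_per_group), "(",
      paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group), collapse = ", "), ")\n")
  cat("  sites:", length(x$areas), "brain areas +", length(x$tissues), "tissues\n")
  cat("  planted blocks:", paste(table(x$planted_partition), collapse = "/"),
      " within_r =", x$within_block_r, " between_r =", x$between_block_r,
      " (mean brain r ~", round(x$brain_mean_r, 3), ")\n")
  cat("  noise CV: brain", x$noise_cv[["brain"]], "/ tissue", x$noise_cv[["tissue"]],
      "; missing_rate", x$missing_rate, "; seed", x$seed, "\n")
  invisible(x)
}
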