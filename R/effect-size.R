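#' Hedges' g with 95% confidence interval
#'
#' Small-sample-corrected standardized mean difference between two groups:
#' `g = J * (mean(a) - mean(b)) / s_pooled`, with the correction
#' `J = 1 - 3/(4 df - 1)`, `df = n_a + n_b - 2`. The asymptotic 95% CI
#' uses `SE^2 = (n_a + n_b)/(n_a n_b) + g^2 / (2 df)`. The `significant`
#' flag is TRUE when the CI excludes 0.
#'
#' @param group_a,group_b numeric vectors (>= 2 values each, NAs dropped).
#' @return list with `g`, `ci` (length-2), `se`, `significant`.
#' @export
hedges_g <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need >= 2 values per group")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0)
    return(list(g = NA_real_, ci = c(NA_real_, NA_real_), se = NA_real_,
                significant = FALSE, qc = "zero pooled variance"))
  J <- 1 - 3 / (4 * df - 1)
  g <- J * (mean(a) - mean(b)) / sqrt(sp2)
  se <- sqrt((na + nb) / (na * nb) + g^2 / (2 * df))
  ci <- g + c(-1, 1) * stats::qnorm(0.975) * se
  list(g = g, ci = ci, se = se,
       significant = ci[1] > 0 || ci[2] < 0, qc = "pass")
}

#' Gaussian fit and one-sample t-test of a value distribution
#'
#' Fits a Gaussian by maximum likelihood (sample mean, ML standard
#' deviation) to a set of effect sizes or correlations, and tests the raw
#' values against 0 with a two-tailed one-sample t-test.
#'
#' @param values numeric vector (>= 5 values, NAs dropped).
#' @return list with `mean`, `sd` (ML, divisor n), `t`, `df`, `p`.
#' @export
distribution_test <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 5L) stop("need >= 5 values")
  n <- length(v)
  if (stats::sd(v) == 0)
    return(list(mean = mean(v), sd = 0, t = NA_real_, df = n - 1L,
                p = NA_real_, qc = "constant input; t undefined"))
  tt <- stats::t.test(v, mu = 0)
  list(mean = mean(v), sd = stats::sd(v) * sqrt((n - 1) / n),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, qc = "pass")
}

#' Binomial direction test for stressor effects across brain areas
#'
#' For each mitochondrial feature, counts the brain areas in which the
#' stress group's mean lies above the naive group's mean, and tests that
#' count against 0.5 with a two-tailed exact binomial test.
#'
#' @param cohort a `mito_cohort` or its tidy `cohort` data.frame.
#' @param group stress group label to compare against `"naive"`.
#' @param naive_group reference group label.
#' @return data.frame with feature, n_areas, n_above, p.
#' @export
stressor_direction_test <- function(cohort, group, naive_group = "naive") {
  tab <- if (inherits(cohort, "mito_cohort")) cohort$cohort else cohort
  tab <- tab[tab$site_class == "brain", ]
  if (!naive_group %in% tab$group) stop("naive group absent from cohort")
  if (!group %in% tab$group) stop("group '", group, "' absent from cohort")
  feats <- unique(tab$feature)
  out <- lapply(feats, function(f) {
    sub <- tab[tab$feature == f, ]
    gm <- tapply(sub$value[sub$group == group],
                 sub$site[sub$group == group], mean, na.rm = TRUE)
    nm <- tapply(sub$value[sub$group == naive_group],
                 sub$site[sub$group == naive_group], mean, na.rm = TRUE)
    common <- intersect(names(gm), names(nm))
    above <- sum(gm[common] > nm[common], na.rm = TRUE)
    n <- sum(!is.na(gm[common]) & !is.na(nm[common]))
    p <- stats::binom.test(above, n, p = 0.5)$p.value
    data.frame(feature = f, n_areas = n, n_above = above, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
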