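# Per-feature baseline levels, order-of-magnitude placeholders in
# normalized activity units (the real per-area means are not published;
# see the methods vignette). mtDNA density is on a relative scale.
.feature_base <- c(CI = 4, CII = 2, CIV = 6, CS = 10, mtdna_density = 1)

#' Generate a synthetic mitochondrial phenotyping cohort
#'
#' Samples per-animal, per-site values for the five primary mitochondrial
#' features (CI, CII, CIV, CS activities and mtDNA density) under a latent
#' factor model that plants the configured community structure over brain
#' areas, applies group shifts for the stressor arms, computes MHI per site
#' with [compute_mhi()] (MHI is derived, never sampled), masks whole
#' (animal, area) sites at the configured missingness rate, and emits
#' behavioral composite scores coupled to the network-1 mitochondrial mean.
#'
#' Feature values are `mean * (1 + g*cv + cv*(a*F_block + b*F_global +
#' s*F_site + f*noise))` with variance shares chosen so that inter-area
#' correlations hit the configured block targets and two features of one
#' area correlate at `within_area_r`. Peripheral tissues get independent
#' site factors (no coupling to brain or to each other).
#'
#' @param config a [synthetic_config()].
#' @return An object of class `mito_cohort`: list with `cohort` (tidy
#'   data.frame: animal_id, group, site, site_class, feature, value),
#'   `behaviors` (animal_id, test, score), `animals`, and `truth`
#'   (planted partition, per-animal network-1 signal, masked sites).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be a synthetic_config object")
  cf <- config
  groups <- rep(names(cf$n_per_group), cf$n_per_group)
  n <- length(groups)
  ids <- sprintf("A%02d", seq_len(n))
  areas <- cf$areas; tissues <- cf$tissues
  feats <- names(.feature_base)
  comm <- cf$planted_partition
  n_comm <- length(unique(comm))

  cv_b <- cf$noise_cv[["brain"]]
  cv_t <- cf$noise_cv[["tissue"]]
  # variance shares (fractions of total relative variance cv^2)
  a2 <- cf$within_block_r - cf$between_block_r   # block factor
  b2 <- cf$between_block_r                       # global brain factor
  s2 <- cf$within_area_r - cf$within_block_r     # site factor
  f2 <- 1 - cf$within_area_r                     # feature-level residual

  out <- with_seed(cf$seed, {
    F_block <- matrix(stats::rnorm(n * n_comm), n, n_comm)
    F_global <- stats::rnorm(n)
    F_site <- matrix(stats::rnorm(n * length(areas)), n, length(areas),
                     dimnames = list(NULL, areas))
    T_site <- matrix(stats::rnorm(n * length(tissues)), n, length(tissues),
                     dimnames = list(NULL, tissues))

    # deterministic per-area level multipliers (0.7 .. 1.4)
    area_mult <- stats::setNames(
      seq(0.7, 1.4, length.out = length(areas)), areas)
    tissue_mult <- stats::setNames(
      seq(0.8, 1.6, length.out = length(tissues)), tissues)

    g_shift <- function(group, area) {
      switch(group,
        naive = 0,
        cort = cf$cort_effect[[area]],
        csds = cf$csds_effect[[area]],
        csds_rec = 0.2 * cf$csds_effect[[area]])
    }

    rows <- vector("list", length(areas) + length(tissues))
    k <- 0L
    for (ar in areas) {
      dev <- cv_b * (sqrt(a2) * F_block[, comm[[ar]]] + sqrt(b2) * F_global +
                     sqrt(s2) * F_site[, ar])
      shift <- vapply(seq_len(n), function(i) g_shift(groups[i], ar), 0) * cv_b
      vals <- sapply(feats, function(f) {
        mu <- .feature_base[[f]] * area_mult[[ar]]
        v <- mu * (1 + shift + dev + cv_b * sqrt(f2) * stats::rnorm(n))
        pmax(v, 0.01 * mu) # activities cannot go negative
      })
      k <- k + 1L
      rows[[k]] <- data.frame(animal_id = rep(ids, length(feats)),
                              group = rep(groups, length(feats)),
                              site = ar, site_class = "brain",
                              feature = rep(feats, each = n),
                              value = as.vector(vals),
                              stringsAsFactors = FALSE)
    }
    for (ti in tissues) {
      dev <- cv_t * sqrt(cf$within_area_r) * T_site[, ti]
      vals <- sapply(feats, function(f) {
        mu <- .feature_base[[f]] * tissue_mult[[ti]]
        v <- mu * (1 + dev + cv_t * sqrt(1 - cf$within_area_r) * stats::rnorm(n))
        pmax(v, 0.01 * mu)
      })
      k <- k + 1L
      rows[[k]] <- data.frame(animal_id = rep(ids, length(feats)),
                              group = rep(groups, length(feats)),
                              site = ti, site_class = "tissue",
                              feature = rep(feats, each = n),
                              value = as.vector(vals),
                              stringsAsFactors = FALSE)
    }
    cohort <- do.call(rbind, rows)

    # whole-site masking (cracked-section losses), brain areas only
    masked <- NULL
    if (cf$missing_rate > 0) {
      cells <- expand.grid(animal_id = ids, site = areas,
                           stringsAsFactors = FALSE)
      hit <- stats::runif(nrow(cells)) < cf$missing_rate
      masked <- cells[hit, , drop = FALSE]
      if (nrow(masked)) {
        key <- paste(cohort$animal_id, cohort$site)
        cohort$value[key %in% paste(masked$animal_id, masked$site)] <- NA_real_
      }
    }

    # MHI per site from the five sampled features (derived, not sampled)
    cohort <- rbind(cohort, .mhi_rows(cohort, ids, groups))

    # network-1 signal: mean standardized (area in block 1, feature) value
    net1 <- .network_signal(cohort, names(comm)[comm == 1L])

    beh <- .behavior_rows(cf, ids, groups, net1)
    list(cohort = cohort, behaviors = beh, masked = masked, net1 = net1)
  })

  structure(list(
    cohort = out$cohort,
    behaviors = out$behaviors,
    animals = data.frame(animal_id = ids, group = groups,
                         stringsAsFactors = FALSE),
    truth = list(partition = comm, network1_signal = out$net1,
                 masked_sites = out$masked),
    config = cf
  ), class = "mito_cohort")
}

# MHI rows for every site, computed across animals within site.
.mhi_rows <- function(cohort, ids, groups) {
  sites <- unique(cohort$site)
  out <- lapply(sites, function(s) {
    sub <- cohort[cohort$site == s, ]
    wide <- sapply(names(.feature_base), function(f)
      sub$value[sub$feature == f][match(ids, sub$animal_id[sub$feature == f])])
    rownames(wide) <- ids
    mhi <- tryCatch(compute_mhi(wide), error = function(e)
      rep(NA_real_, length(ids)))
    data.frame(animal_id = ids, group = groups, site = s,
               site_class = sub$site_class[1L], feature = "MHI",
               value = as.numeric(mhi), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Per-animal standardized mean over all (area in `areas1`, feature) values.
.network_signal <- function(cohort, areas1) {
  sub <- cohort[cohort$site %in% areas1, ]
  key <- interaction(sub$site, sub$feature, drop = TRUE)
  z <- stats::ave(sub$value, key, FUN = function(v)
    (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE))
  sig <- tapply(z, sub$animal_id, mean, na.rm = TRUE)
  sig <- (sig - mean(sig, na.rm = TRUE)) / stats::sd(sig, na.rm = TRUE)
  sig[unique(cohort$animal_id)]
}

# Behavioral scores coupled to the network-1 signal. Test availability
# mirrors the study design: SI accompanies the social-defeat arm, EPM and
# NSF the corticosterone arm, OFT is run on everyone.
.behavior_rows <- function(cf, ids, groups, net1) {
  n <- length(ids)
  avail <- list(
    OFT = rep(TRUE, n),
    EPM = groups %in% c("naive", "cort"),
    NSF = groups %in% c("naive", "cort"),
    SI  = groups %in% c("naive", "csds", "csds_rec"))
  rows <- lapply(names(cf$behavior_coupling), function(test) {
    rho <- cf$behavior_coupling[[test]]
    y <- rho * net1 + sqrt(1 - rho^2) * stats::rnorm(n)
    if (test == "NSF") {
      y <- pmin(pmax(300 + 120 * y, 0), 600) # latency (s), right-censored
    }
    y[!avail[[test]]] <- NA_real_
    data.frame(animal_id = ids, test = test, score = as.numeric(y),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.mito_cohort <- function(x, ...) {
  cat("<mito_cohort>", nrow(x$animals), "animals,",
      length(unique(x$cohort$site)), "sites,",
      length(unique(x$cohort$feature)), "features\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$animals$group)),
                                 table(x$animals$group)), collapse = ", "), "\n")
  cat("  missing site cells:",
      if (is.null(x$truth$masked_sites)) 0 else nrow(x$truth$masked_sites), "\n")
  invisible(x)
}
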