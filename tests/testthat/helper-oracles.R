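# Independent oracles and fixture builders, kept deliberately naive so
# they stay independent of the package's optimized code paths.

# All set partitions of n elements as restricted-growth label vectors.
all_partitions <- function(n) {
  out <- list()
  g <- integer(n)
  rec <- function(i, maxl) {
    if (i > n) {
      out[[length(out) + 1L]] <<- g
      return(invisible())
    }
    for (l in 1:(maxl + 1L)) {
      g[i] <<- l
      rec(i + 1L, max(maxl, l))
    }
  }
  rec(1L, 0L)
  out
}

# Brute-force multi-slice quality: direct quadruple-loop evaluation of
# the categorical coupling quality function.
oracle_multislice_q <- function(slices, g_mat, gamma = 1, omega = 0.1) {
  S <- length(slices)
  N <- nrow(slices[[1L]])
  two_m <- numeric(S)
  for (s in 1:S) {
    A <- slices[[s]]
    diag(A) <- 0
    slices[[s]] <- A
    two_m[s] <- sum(A)
  }
  tot <- 0
  for (s in 1:S) {
    A <- slices[[s]]
    for (i in 1:N) for (j in 1:N) {
      if (g_mat[i, s] != g_mat[j, s]) next
      null_t <- if (two_m[s] != 0)
        gamma * sum(A[i, ]) * sum(A[j, ]) / two_m[s] else 0
      tot <- tot + A[i, j] - null_t
    }
  }
  for (i in 1:N) for (s in 1:S) for (r in 1:S)
    if (s != r && g_mat[i, s] == g_mat[i, r]) tot <- tot + omega
  tot / (sum(two_m) + omega * N * S * (S - 1))
}

# Oracle supra-quality matrix built by explicit loops (for exhaustive
# maxima over many partitions without quadruple loops per partition).
oracle_supra_B <- function(slices, gamma = 1, omega = 0.1) {
  S <- length(slices)
  N <- nrow(slices[[1L]])
  B <- matrix(0, N * S, N * S)
  two_m <- numeric(S)
  for (s in 1:S) {
    A <- slices[[s]]
    diag(A) <- 0
    slices[[s]] <- A
    two_m[s] <- sum(A)
  }
  for (s in 1:S) {
    A <- slices[[s]]
    for (i in 1:N) for (j in 1:N) {
      null_t <- if (two_m[s] != 0)
        gamma * sum(A[i, ]) * sum(A[j, ]) / two_m[s] else 0
      B[(s - 1) * N + i, (s - 1) * N + j] <- A[i, j] - null_t
    }
  }
  for (i in 1:N) for (s in 1:S) for (r in 1:S)
    if (s != r) B[(s - 1) * N + i, (r - 1) * N + i] <- omega
  list(B = B, two_mu = sum(two_m) + omega * N * S * (S - 1))
}

# Random symmetric correlation-like slice with 2 planted blocks + noise.
random_block_slice <- function(n = 5, within = 0.6, between = 0.1,
                               noise = 0.25) {
  blocks <- rep(1:2, length.out = n)
  base <- ifelse(outer(blocks, blocks, "=="), within, between)
  e <- matrix(stats::rnorm(n * n, sd = noise), n, n)
  m <- base + (e + t(e)) / 2
  diag(m) <- 0
  m
}

# Planted delta matrices for the Mapper PC contrast: "integrated" rows
# share one response pattern across mice; "segregated" rows follow their
# planted community's pattern. Row communities are the planted networks.
make_planted_delta <- function(kind, seed, n_mice = 6, noise = 1) {
  part <- default_partition()
  areas <- mito_areas()
  set.seed(seed)
  rows <- expand.grid(site = areas, feature = paste0("f", 1:6),
                      stringsAsFactors = FALSE)
  shared <- stats::rnorm(n_mice)
  commpat <- matrix(stats::rnorm(3 * n_mice), 3)
  m <- t(sapply(seq_len(nrow(rows)), function(i) {
    base <- if (kind == "integrated") shared
            else commpat[part[[rows$site[i]]], ]
    as.numeric(base) + noise * stats::rnorm(n_mice)
  }))
  attr(m, "area") <- rows$site
  attr(m, "network") <- unname(part[rows$site])
  m
}

# Tiny deterministic tidy cohort: `values` is animals x sites, one
# feature, for hand-checkable connectivity tests.
toy_cohort_tab <- function(values, feature = "CI", site_class = "brain",
                           group = "naive") {
  ids <- rownames(values) %||% sprintf("A%02d", seq_len(nrow(values)))
  sites <- colnames(values)
  do.call(rbind, lapply(seq_along(sites), function(j)
    data.frame(animal_id = ids, group = group, site = sites[j],
               site_class = site_class, feature = feature,
               value = values[, j], stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
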