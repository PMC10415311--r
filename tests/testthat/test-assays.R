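test_that("specific_activity computes mean minus nonspecific times factor", {
  expect_equal(specific_activity(c(10, 10), 2, 1)$activity, 8)
  expect_equal(specific_activity(c(5, 5), 5, 1)$activity, 0)
  r <- specific_activity(c(10, 13)) # CV ~ 12.3%
  expect_true(r$flag)
  expect_match(r$qc, "exceeds")
  expect_true(is.na(specific_activity(c(10, 13), exclude_failing = TRUE)$activity))
  miss <- specific_activity(c(NA_real_, NA_real_))
  expect_true(is.na(miss$activity))
  expect_match(miss$qc, "missing")
})

test_that("normalize_plate aligns plates by their positive controls", {
  pc <- c(p1 = 10, p2 = 20)
  # assay reference defaults to mean(pc) = 15
  out <- normalize_plate(c(1, 1), c("p1", "p2"), pc)
  expect_equal(unname(out$factors), c(1.5, 0.75))
  # a plate at the reference level is unchanged
  out2 <- normalize_plate(c(3, 5), c("p1", "p1"), c(p1 = 10), assay_reference = 10)
  expect_equal(out2$normalized, c(3, 5))
  # control at 2x the reference halves the plate
  out3 <- normalize_plate(c(4, 8), c("p1", "p1"), c(p1 = 20), assay_reference = 10)
  expect_equal(out3$normalized, c(2, 4))
  # round trip: identical samples on plates with different control levels
  # align after normalization
  truth <- c(2, 3, 4)
  plate_a <- truth * 1.0; plate_b <- truth * 2.0 # plate b reads 2x high
  out4 <- normalize_plate(c(plate_a, plate_b),
                          rep(c("a", "b"), each = 3),
                          c(a = 5, b = 10))
  expect_equal(unname(out4$normalized[1:3]), unname(out4$normalized[4:6]))
  expect_warning(normalize_plate(1, "p", c(p = 0)), "nonpositive")
})

test_that("ct_to_mtdnacn applies the delta-Ct formula and QC ladder", {
  expect_equal(ct_to_mtdnacn(rep(20, 3), rep(20, 3))$mtdnacn, 2)
  expect_equal(ct_to_mtdnacn(rep(18, 3), rep(21, 3))$mtdnacn, 16)
  # exclusion cutoff: mean Ct > 33
  over <- ct_to_mtdnacn(rep(20, 3), rep(34, 3))
  expect_true(is.na(over$mtdnacn))
  expect_match(over$qc, "33")
  # one outlier replicate is dropped, duplicate used
  rep_ <- ct_to_mtdnacn(c(20, 20, 26), rep(22, 3))
  expect_equal(rep_$mtdnacn, 2^2 * 2)
  # irreparably noisy triplicate is discarded
  noisy <- ct_to_mtdnacn(c(10, 20, 30), rep(22, 3))
  expect_true(is.na(noisy$mtdnacn))
})

test_that("ct_to_mtdna_density provides verbatim and sign-corrected modes", {
  v0 <- ct_to_mtdna_density(0)
  expect_equal(as.numeric(v0), 1e-12)
  expect_equal(attr(v0, "mode"), "verbatim")
  v <- ct_to_mtdna_density(c(10, 11))
  expect_equal(v[1] / v[2], 1 / 2, ignore_attr = TRUE) # doubles per cycle
  s <- ct_to_mtdna_density(c(10, 11), mode = "sign_corrected")
  expect_equal(s[1] / s[2], 2, ignore_attr = TRUE) # halves per cycle
})

test_that("compute_mhi centers to 100 and scales linearly", {
  feats <- c("CI", "CII", "CIV", "CS", "mtdna_density")
  base <- matrix(c(4, 2, 6, 10, 1), 3, 5, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), feats))
  # identical animals: everyone is the mean -> all exactly 100
  expect_equal(unname(compute_mhi(base)), rep(100, 3))
  # one animal with doubled RC activities, content at mean -> 200
  m <- base
  m["b", c("CI", "CII", "CIV")] <- 2 * m["b", c("CI", "CII", "CIV")]
  mhi <- compute_mhi(m)
  centered <- sweep(m, 2, colMeans(m), "/")
  expect_equal(unname(mhi["b"]),
               unname(100 * sum(centered["b", 1:3]) /
                      (sum(centered["b", 4:5]) + 1)))
  expect_error(compute_mhi(base * 0), "zero")
  expect_error(compute_mhi(base[1, , drop = FALSE]), ">= 2")
})

test_that("MHI is invariant to rescaling any one feature", {
  feats <- c("CI", "CII", "CIV", "CS", "mtdna_density")
  set.seed(4)
  m <- matrix(rexp(8 * 5, 1 / 5), 8, 5, dimnames = list(NULL, feats))
  ref <- compute_mhi(m)
  for (f in feats) {
    m2 <- m
    m2[, f] <- m2[, f] * 37.5
    expect_equal(compute_mhi(m2), ref)
  }
})

test_that("behavior_zscore applies sign conventions and centers at 0", {
  # animal at the cohort mean on every measure scores 0
  oft <- data.frame(center_time = c(10, 20, 30),
                    center_distance = c(5, 10, 15))
  z <- behavior_zscore(oft, "OFT")
  expect_equal(unname(z[2]), 0)
  expect_equal(mean(z), 0)
  # more center time = less avoidant: lowest composite
  expect_lt(z[3], z[1])
  # SI: the most sociable animal (highest SI ratio and SI-zone time)
  # gets the lowest avoidance composite
  si <- data.frame(si_ratio = c(2.0, 1.0, 0.5),
                   corner_ratio = c(0.5, 1.0, 2.0),
                   si_zone_time = c(100, 60, 20),
                   corner_time = c(10, 40, 80))
  zs <- behavior_zscore(si, "SI")
  expect_equal(unname(which.min(zs)), 1L)
  # NSF latencies are censored at 600 before z-scoring
  nsf <- data.frame(latency = c(100, 300, 900, 1200))
  zn <- behavior_zscore(nsf, "NSF")
  expect_equal(unname(zn[3]), unname(zn[4])) # both censored to 600
  expect_error(behavior_zscore(oft[1:2, ], "OFT"), ">= 3")
  expect_error(behavior_zscore(data.frame(x = 1:5), "EPM"), "open_arm_time")
})

test_that("hedges_g matches the J-corrected textbook computation", {
  # identical groups: g = 0, nonsignificant
  same <- hedges_g(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$g, 0)
  expect_false(same$significant)
  # clear separation: large |g|, CI excludes 0
  sep <- hedges_g(c(0, 0.01, 0, 0.01), c(1, 1.01, 1, 0.99))
  expect_gt(abs(sep$g), 8)
  expect_true(sep$significant)
  # reference computation on a fixed 5 vs 6 table
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6, 7)
  df <- 9
  sp <- sqrt((4 * var(a) + 5 * var(b)) / df)
  g_ref <- (1 - 3 / (4 * df - 1)) * (mean(a) - mean(b)) / sp
  expect_equal(hedges_g(a, b)$g, g_ref)
  # zero pooled variance flagged
  expect_true(is.na(hedges_g(c(1, 1), c(2, 2))$g))
})
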