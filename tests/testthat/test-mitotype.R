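toy_expr <- function() {
  areas <- paste0("ar", 1:6)
  genes <- paste0("g", 1:8)
  set.seed(3)
  m <- matrix(rexp(48, 1 / 10), 6, 8, dimnames = list(areas, genes))
  m
}

toy_part <- function() stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), paste0("ar", 1:6))

test_that("network fold lists apply the inclusive log2 threshold", {
  areas <- c("a", "b", "c")
  expr <- matrix(c(2, 2, 1,    # g1: net {a,b} mean 2, rest 1 -> lfc 1
                   3, 3, 3,    # g2: uniform -> lfc 0
                   1, 1, 8,    # g3: under-expressed
                   0, 0, 5),   # g4: zero mean in network -> excluded
                 3, 4, dimnames = list(areas, paste0("g", 1:4)))
  part <- stats::setNames(c(1L, 1L, 2L), areas)
  res <- network_fold_genes(expr, part)
  expect_equal(unname(res$network1$log2fc["g1"]), 1)
  expect_true("g1" %in% res$network1$over) # boundary inclusive
  expect_false("g2" %in% c(res$network1$over, res$network1$under))
  expect_true("g3" %in% res$network1$under)
  expect_equal(res$network1$n_excluded, 1L)
  # hand-computed value
  expect_equal(unname(res$network1$log2fc["g3"]), log2(1 / 8))
  # threshold 1 lists are subsets of threshold 0.5 lists
  res05 <- network_fold_genes(expr, part, threshold_log2 = 0.5)
  expect_true(all(res$network1$over %in% res05$network1$over))
  expect_true(all(res$network1$under %in% res05$network1$under))
})

test_that("pathway scores transform genes to mean 100 sd 10 then average", {
  expr <- toy_expr()
  map <- data.frame(gene = paste0("g", 1:8),
                    pathway = rep(c("pwA", "pwB", "pwC", "pwD"), each = 2))
  sc <- pathway_scores(expr, map)
  expect_equal(dim(sc), c(6L, 4L))
  # per-gene transform invariant: each gene column mean 100, sd 10
  z <- 100 + 10 * scale(expr)[, 1]
  # single-gene pathway equals the transformed gene
  map1 <- data.frame(gene = "g1", pathway = "solo")
  solo <- pathway_scores(expr, map1)
  expect_equal(unname(solo[, "solo"]), unname(z), ignore_attr = TRUE)
  # pathway column means are 100 by linearity
  expect_equal(unname(colMeans(sc)), rep(100, 4))
  # hand computation: 2-gene pathway is the mean of the transforms
  zz <- apply(expr[, c("g1", "g2")], 2, function(v)
    100 + 10 * (v - mean(v)) / sd(v))
  expect_equal(unname(sc[, "pwA"]), unname(rowMeans(zz)))
})

test_that("pathway scores are invariant to per-gene affine rescaling", {
  expr <- toy_expr()
  map <- data.frame(gene = paste0("g", 1:8),
                    pathway = rep(c("pwA", "pwB"), each = 4))
  ref <- pathway_scores(expr, map)
  expr2 <- sweep(sweep(expr, 2, runif(8, 1, 5), "*"), 2, runif(8, 0, 3), "+")
  expect_equal(as.matrix(pathway_scores(expr2, map)), as.matrix(ref),
               ignore_attr = TRUE)
  # unmapped pathways dropped with report; constant gene flagged
  map2 <- rbind(map, data.frame(gene = "absent", pathway = "pwGone"))
  sc2 <- pathway_scores(expr, map2)
  expect_equal(attr(sc2, "dropped_pathways"), "pwGone")
  expr3 <- cbind(expr, gflat = 7)
  sc3 <- pathway_scores(expr3, rbind(map, data.frame(gene = "gflat",
                                                     pathway = "pwFlat")))
  expect_equal(unname(sc3[, "pwFlat"]), rep(100, 6))
  expect_equal(attr(sc3, "flat_genes"), "gflat")
})

test_that("pathway ranking orders by network log2 fold and antisymmetry holds", {
  expr <- toy_expr()
  map <- data.frame(gene = paste0("g", 1:8),
                    pathway = rep(c("pwA", "pwB", "pwC", "pwD"), each = 2))
  sc <- pathway_scores(expr, map)
  part <- toy_part()
  rk <- rank_pathways(sc, part, network = 1)
  expect_equal(rk$pathway[order(rk$log2fc)], rk$pathway)
  # hand-check one fold value
  pw <- rk$pathway[1]
  hand <- log2(mean(sc[1:3, pw]) / mean(sc[4:6, pw]))
  expect_equal(rk$log2fc[1], hand)
  # swapping the networks negates every fold
  rk2 <- rank_pathways(sc, part, network = 2)
  m1 <- stats::setNames(rk$log2fc, rk$pathway)
  m2 <- stats::setNames(rk2$log2fc, rk2$pathway)
  expect_equal(m1[names(m2)], -m2)
  # a pathway elevated only in network 1 ranks last (highest fold)
  sc2 <- cbind(sc, pwHot = c(200, 200, 200, 50, 50, 50))
  rk3 <- rank_pathways(sc2, part)
  expect_equal(rk3$pathway[nrow(rk3)], "pwHot")
})

test_that("mitotype ratios quantify per-area specialization", {
  sc <- matrix(100, 4, 2, dimnames = list(paste0("ar", 1:4), c("pA", "pB")))
  r <- mitotype_ratio(sc, "pA", "pB")
  expect_equal(r$ratio, rep(1, 4))
  expect_equal(r$pct_vs_mean, rep(0, 4))
  sc2 <- sc
  sc2["ar2", "pA"] <- 200
  r2 <- mitotype_ratio(sc2, "pA", "pB")
  expect_equal(r2$ratio[r2$area == "ar2"], 2)
  expect_equal(r2$ratio[r2$area == "ar1"], 1)
  expect_error(mitotype_ratio(sc, "pA", "nope"), "not in scores")
})

test_that("clustering and projection separate block-structured areas", {
  set.seed(8)
  a <- matrix(rnorm(3 * 10, 0), 3, 10)
  b <- matrix(rnorm(3 * 10, 6), 3, 10)
  x <- rbind(a, a[1, , drop = FALSE], b) # area 4 duplicates area 1
  rownames(x) <- paste0("ar", 1:7)
  cp <- cluster_and_project(x)
  # identical areas are adjacent leaves
  ord <- cp$leaf_order
  expect_equal(abs(which(ord == "ar1") - which(ord == "ar4")), 1)
  # blocks separate on component 1
  pc1 <- cp$projection[, 1]
  expect_true(max(pc1[1:4]) < min(pc1[5:7]) || min(pc1[1:4]) > max(pc1[5:7]))
  # centered projection
  expect_equal(unname(colMeans(cp$projection)), rep(0, 3))
  expect_length(cp$explained_variance, 3L)
  expect_error(cluster_and_project(x[1:2, ]), ">= 3")
})
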