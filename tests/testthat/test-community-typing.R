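test_that("prevalence filter keeps the inclusive boundary and drops rare features", {
  m <- matrix(0, 10, 3, dimnames = list(paste0("S", 1:10), c("a", "b", "c")))
  m[1:2, "a"] <- 1   # present in exactly 20% of samples
  m[1, "b"] <- 1     # present in 10%
  ft <- featureTable(m, "otu")
  kept <- featureNames(prevalenceFilter(ft, 0.20))
  expect_identical(kept, "a")
  expect_error(prevalenceFilter(ft, 0.9), "lower the threshold")
  # filtering never increases feature count and is monotone in the threshold
  cohort <- defaultCohort()
  n1 <- ncol(abundances(prevalenceFilter(cohort$otu, 0.1)))
  n2 <- ncol(abundances(prevalenceFilter(cohort$otu, 0.3)))
  expect_lte(n2, n1)
  expect_lte(n1, ncol(abundances(cohort$otu)))
})

test_that("Spearman sample matrix matches hand-computed values", {
  m <- rbind(S1 = c(1, 2, 3), S2 = c(2, 1, 3), S3 = c(1, 2, 3), S4 = c(3, 2, 1))
  colnames(m) <- paste0("f", 1:3)
  rho <- spearmanMatrix(featureTable(m, "otu"))
  expect_equal(rho["S1", "S2"], 0.5)     # 1 - 6*2/(3*8)
  expect_equal(rho["S1", "S3"], 1)       # duplicated sample
  expect_equal(rho["S1", "S4"], -1)      # reversed ranks
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 4))
  mc <- rbind(S1 = c(1, 1, 1), S2 = c(1, 2, 3))
  colnames(mc) <- paste0("f", 1:3)
  expect_error(spearmanMatrix(featureTable(mc, "otu")), "S1")
})

test_that("Ward clustering recovers duplicated-sample blocks exactly", {
  set.seed(4)
  base <- matrix(runif(2 * 50), 2, 50)
  m <- base[rep(1:2, each = 5), ] + matrix(rnorm(500, 0, 1e-3), 10)
  dimnames(m) <- list(paste0("S", 1:10), paste0("f", 1:50))
  rho <- spearmanMatrix(featureTable(m, "otu"))
  asg <- wardClusterSamples(rho, "auto", kMax = 5)
  expect_equal(clusterK(asg), 2L)
  expect_equal(randARI(clusterLabels(asg), rep(1:2, each = 5)), 1)
  expect_error(wardClusterSamples(rho, 11), "exceeds")
  # clustering is invariant to sample order
  perm <- sample(10)
  asg2 <- wardClusterSamples(rho[perm, perm], 2)
  expect_equal(randARI(clusterLabels(asg2)[rownames(rho)],
                       clusterLabels(asg)), 1)
})

test_that("within-cluster BH validation separates coherent from random clusters", {
  set.seed(8)
  coherent <- matrix(rep(runif(200), each = 4), 4) + 1 +
    matrix(rnorm(800, 0, 1e-3), 4)
  random <- matrix(runif(4 * 200), 4)
  m <- rbind(coherent, random)
  dimnames(m) <- list(paste0("S", 1:8), paste0("f", 1:200))
  labels <- factor(rep(c("C1", "C2"), each = 4))
  names(labels) <- rownames(m)
  asg <- new("ClusterAssignment", labels = labels, k = 2L,
             tree = list(), silhouette = numeric(0),
             validity = data.frame(), manova = list())
  val <- validateClustersBH(featureTable(m, "otu"), asg, alpha = 0.05)@validity
  expect_true(val$valid[val$cluster == "C1"])
  expect_false(val$valid[val$cluster == "C2"])
  expect_equal(val$n_pairs, c(6L, 6L))
})

test_that("permanova matches the stated p under perfect separation and rejects bad input", {
  d <- matrix(1, 20, 20)
  d[1:10, 1:10] <- 0; d[11:20, 11:20] <- 0; diag(d) <- 0
  dimnames(d) <- list(paste0("S", 1:20), paste0("S", 1:20))
  res <- permanova(d, rep(c("a", "b"), each = 10), nPerm = 199, seed = 1)
  expect_equal(res$p, 1 / 200)
  expect_equal(res$R2, 1)
  expect_error(permanova(d, rep("a", 20), nPerm = 99), "2 groups")
  bad <- d; bad[1, 2] <- 5
  expect_error(permanova(bad, rep(c("a", "b"), each = 10)), "symmetric")
  # pseudo-F invariant to relabeling, and equal to vegan's adonis2
  set.seed(2)
  dd <- as.matrix(dist(matrix(rnorm(40), 10)))
  dimnames(dd) <- list(paste0("S", 1:10), paste0("S", 1:10))
  g <- rep(c("x", "y"), 5)
  f1 <- permanova(dd, g, nPerm = 99, seed = 3)$pseudoF
  f2 <- permanova(dd, ifelse(g == "x", "y", "x"), nPerm = 99, seed = 3)$pseudoF
  expect_equal(f1, f2)
  ref <- vegan::adonis2(as.dist(dd) ~ grp, data = data.frame(grp = g),
                        permutations = 99)
  expect_equal(f1, ref$F[1], tolerance = 1e-10)
})

test_that("Shannon diversity matches closed forms and majorization", {
  m <- rbind(S1 = c(1, 1, 1, 1), S2 = c(4, 0, 0, 0), S3 = c(2, 1, 1, 0))
  colnames(m) <- paste0("f", 1:4)
  ad <- alphaDiversity(featureTable(m, "otu"))
  expect_equal(ad["S1", "shannon"], 2)
  expect_equal(ad["S2", "shannon"], 0)
  expect_equal(ad["S2", "observed"], 1)
  expect_equal(ad["S3", "shannon"], 1.5)   # (0.5, 0.25, 0.25)
  z <- matrix(0, 1, 2, dimnames = list("S1", c("f1", "f2")))
  expect_error(alphaDiversity(featureTable(z, "otu")), "all-zero")
  # concentrating mass strictly decreases entropy
  set.seed(5)
  for (i in 1:10) {
    p <- as.numeric(rmultinom(1, 100, runif(6))) + 1
    q <- p; q[which.max(p)] <- q[which.max(p)] + q[which.min(p)] - 1
    q[which.min(p)] <- 1
    m2 <- rbind(S1 = p, S2 = q); colnames(m2) <- paste0("f", 1:6)
    ad2 <- alphaDiversity(featureTable(m2, "otu"))
    expect_gte(ad2["S1", "shannon"], ad2["S2", "shannon"])
  }
})

test_that("group comparison reproduces the exact 3v3 Wilcoxon minimum p", {
  vals <- c(1, 2, 3, 101, 102, 103)
  grp <- rep(c("a", "b"), each = 3)
  gc <- groupCompare(vals, grp)
  expect_equal(gc$pairwise$p, 0.1)         # 2 / choose(6, 3)
  expect_equal(gc$groups$n, c(3L, 3L))
  expect_equal(gc$groups$median, c(2, 102))
  expect_error(groupCompare(vals, rep("a", 6)), "2 non-empty groups")
  # identical groups: omnibus far from significant
  gc2 <- groupCompare(rep(c(1, 2, 3), 2), grp)
  expect_gt(gc2$omnibus$p, 0.5)
})
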