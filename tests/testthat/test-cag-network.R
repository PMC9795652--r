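test_that("genus filter applies the strict 0.1% rule in at least two samples", {
  m <- rbind(S1 = c(0.001, 0.002, 0.5, 0.4), S2 = c(0.001, 0.002, 0.0005, 0.9),
             S3 = c(0.001, 0.0005, 0.0005, 0.9), S4 = c(0.001, 0.0005, 0.0005, 0.9))
  colnames(m) <- c("exact", "twice", "once", "always")
  # pad with qualifying genera so the >=3 survivor rule is met
  m <- cbind(m, keep1 = rep(0.01, 4), keep2 = rep(0.02, 4))
  ft <- featureTable(m, "genus", isRelative = TRUE)
  kept <- featureNames(filterGenera(ft))
  expect_false("exact" %in% kept)   # exactly 0.001 everywhere: strict >
  expect_true("twice" %in% kept)    # 0.002 in exactly 2 samples
  expect_false("once" %in% kept)    # above threshold in 1 sample only
  expect_true(all(c("always", "keep1", "keep2") %in% kept))
  expect_error(filterGenera(featureTable(m[, c("exact", "once", "keep1")], "genus",
                                         isRelative = TRUE)),
               "fewer than 3")
})

test_that("Kendall tau and p-values match cor.test on monotone and tied data", {
  m <- cbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4), z = c(2, 4, 6, 8))
  m <- rbind(m, m + 0.5)  # 8 samples
  rownames(m) <- paste0("S", 1:8)
  net <- kendallNetwork(featureTable(m, "genus", isRelative = FALSE), alpha = 0.05)
  ap <- net$allPairs
  expect_equal(ap$tau[ap$genus1 == "x" & ap$genus2 == "z"], 1)
  # hand count for the 4-point pattern replicated twice stays positive
  tau_xy <- ap$tau[ap$genus1 == "x" & ap$genus2 == "y"]
  expect_equal(tau_xy, cor(m[, "x"], m[, "y"], method = "kendall"))
  # vectorized p equals cor.test's normal approximation, with and without ties
  set.seed(14)
  mm <- cbind(a = rnorm(30), b = rnorm(30), c = sample(1:4, 30, TRUE),
              d = sample(1:3, 30, TRUE))
  rownames(mm) <- paste0("S", 1:30)
  net2 <- kendallNetwork(featureTable(abs(mm) + 0.01, "genus"), alpha = 0.05)
  for (r in seq_len(nrow(net2$allPairs))) {
    pr <- net2$allPairs[r, ]
    ct <- suppressWarnings(
      cor.test(abs(mm[, pr$genus1]) + 0.01, abs(mm[, pr$genus2]) + 0.01,
               method = "kendall", exact = FALSE))
    expect_equal(pr$p, ct$p.value, tolerance = 1e-10)
    expect_equal(pr$tau, unname(ct$estimate), tolerance = 1e-10)
  }
})

test_that("tau = 2/3 for the classic 4-point discordance example", {
  # x=(1,2,3,4), y=(1,3,2,4): 5 concordant vs 1 discordant pair
  expect_equal(cor(c(1, 2, 3, 4), c(1, 3, 2, 4), method = "kendall"), 2 / 3)
  m <- cbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4), z = c(4, 3, 2, 1))
  rownames(m) <- paste0("S", 1:4)
  net <- kendallNetwork(featureTable(m, "genus"), alpha = 0.05)
  expect_equal(net$allPairs$tau[net$allPairs$genus1 == "x" &
                                  net$allPairs$genus2 == "y"], 2 / 3)
})

test_that("constant genera are flagged undefined, edges stay positive and gated", {
  m <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(2, 3, 4, 5, 6, 7),
             flat = rep(1, 6))
  rownames(m) <- paste0("S", 1:6)
  net <- kendallNetwork(featureTable(m, "genus"), alpha = 0.05)
  expect_identical(net$undefined, "flat")
  expect_true(all(is.na(net$allPairs$tau[net$allPairs$genus1 == "flat" |
                                           net$allPairs$genus2 == "flat"])))
  expect_true(all(net$edges$tau > 0))
  expect_true(all(net$edges$q <= 0.05))
})

test_that("Storey q-values are monotone, bounded by pi0 scaling, and fall back to BH", {
  set.seed(15)
  p <- c(runif(180), rbeta(60, 0.2, 8))
  q <- storeyQvalues(p)
  ord <- order(p)
  expect_true(all(diff(q$qvalue[ord]) >= -1e-12))
  expect_true(all(q$qvalue >= p * q$pi0 - 1e-12))
  expect_true(q$pi0 <= 1 && q$pi0 > 0)
  expect_message(qs <- storeyQvalues(runif(10)), "Benjamini-Hochberg")
  expect_equal(qs$pi0, 1)
})

test_that("BH fallback q-values equal p.adjust exactly", {
  set.seed(16)
  p <- runif(20)
  expect_message(q <- storeyQvalues(p))
  expect_equal(q$qvalue, p.adjust(p, method = "BH"))
})

test_that("CAG assignment groups correlated genera and names by dominant genus", {
  set.seed(17)
  base1 <- runif(30); base2 <- runif(30)
  m <- cbind(Big = base1 * 10, Small = base1 * 0.5 + rnorm(30, 0, 1e-4),
             OtherBig = base2 * 8, OtherSmall = base2 * 0.3 + rnorm(30, 0, 1e-4))
  m <- abs(m) + 1e-6
  rownames(m) <- paste0("S", 1:30)
  part <- assignCags(featureTable(m, "genus"), k = 2)
  mem <- cagMembership(part)
  expect_equal(mem[["Big"]], mem[["Small"]])
  expect_equal(mem[["OtherBig"]], mem[["OtherSmall"]])
  expect_setequal(unname(cagNames(part)), c("Big", "OtherBig"))
  expect_error(assignCags(featureTable(m, "genus"), k = 10), "exceeds")
  # perfectly correlated genera end up together at any k < n
  part3 <- assignCags(featureTable(m, "genus"), k = 3)
  expect_equal(cagMembership(part3)[["Big"]], cagMembership(part3)[["Small"]])
})

test_that("planted co-abundance blocks are recovered and named canonically", {
  cohort <- defaultCohort()
  gen <- filterGenera(cohort$genus)
  part <- assignCags(gen, k = 5)
  ari <- randARI(cagMembership(part),
                 cohort$truth$genusBlock[names(cagMembership(part))])
  expect_gte(ari, 0.9)
  expect_setequal(unname(cagNames(part)),
                  c("Bifidobacterium", "Ruminococcus", "Dorea",
                    "Prevotella", "Bacteroides"))
})

test_that("Wiggum disc sizes follow the over-abundance definition", {
  m <- rbind(S1 = c(0.04, 0.1), S2 = c(0.04, 0.1),
             S3 = c(0.00, 0.1), S4 = c(0.00, 0.1))
  colnames(m) <- c("g1", "g2")
  ft <- featureTable(m, "genus", isRelative = TRUE)
  part <- new("CagPartition",
              membership = c(g1 = "CAG1", g2 = "CAG1"),
              cagNames = c(CAG1 = "g2"),
              edges = data.frame(genus1 = character(0), genus2 = character(0),
                                 tau = numeric(0), p = numeric(0), q = numeric(0)),
              discSizes = matrix(numeric(0), 0, 0))
  labels <- factor(c("A", "A", "B", "B"))
  names(labels) <- rownames(m)
  part <- wiggumStats(ft, labels, part)
  ds <- discSizes(part)
  expect_equal(ds["g1", "A"], 2)   # cluster mean 0.04 vs cohort 0.02
  expect_equal(ds["g1", "B"], 0)   # absent from cluster B
  expect_equal(unname(ds["g2", ]), c(1, 1))
  # cluster = whole cohort: every disc is 1
  one <- factor(rep("A", 4)); names(one) <- rownames(m)
  expect_true(all(abs(discSizes(wiggumStats(ft, one, part)) - 1) < 1e-12))
})

test_that("CAG network exports to GraphML with attributes", {
  cohort <- defaultCohort()
  gen <- filterGenera(cohort$genus)
  net <- kendallNetwork(gen, alpha = 0.05)
  part <- assignCags(gen, k = 5, edges = net$edges)
  labels <- cohort$truth$cluster
  part <- wiggumStats(gen, labels, part)
  g <- cagGraph(part)
  expect_equal(igraph::vcount(g), length(cagMembership(part)))
  expect_equal(igraph::ecount(g), nrow(cagEdges(part)))
  path <- withr::local_tempfile(fileext = ".graphml")
  writeCagGraphML(part, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})
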