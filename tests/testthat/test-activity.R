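test_that("RNA:DNA normalization applies the zero policy", {
  rna <- rbind(S1 = c(10, 0, 3), S2 = c(4, 2, 0))
  dna <- rbind(S1 = c(5, 7, 0), S2 = c(2, 2, 0))
  colnames(rna) <- colnames(dna) <- c("p1|spA", "p1|spB", "p2|spA")
  act <- rnaDnaNormalize(pairedOmics(featureTable(rna, "pathway"),
                                     featureTable(dna, "pathway")))
  r <- activityRatios(act)
  expect_equal(r["S1", "p1|spA"], 2)
  expect_equal(r["S1", "p1|spB"], 0)
  expect_true(is.na(r["S1", "p2|spA"]))   # DNA 0, RNA 3: undefined, flagged
  expect_true(is.na(r["S2", "p2|spA"]))   # DNA 0, RNA 0: undefined
  ro <- rnaOnly(act)
  expect_equal(nrow(ro), 1)
  expect_equal(ro$feature, "p2|spA")
  expect_equal(ro$sample_id, "S1")
  expect_identical(act@species, c("spA", "spB", "spA"))
  expect_identical(act@pathway, c("p1", "p1", "p2"))
})

test_that("normalization is invariant to per-sample scaling", {
  set.seed(20)
  rna <- matrix(rexp(12) + 0.1, 3, dimnames = list(paste0("S", 1:3),
                                                   c("p1|a", "p2|a", "p1|b", "p2|b")))
  dna <- matrix(rexp(12) + 0.1, 3, dimnames = dimnames(rna))
  a1 <- activityRatios(rnaDnaNormalize(pairedOmics(featureTable(rna, "pathway"),
                                                   featureTable(dna, "pathway"))))
  a2 <- activityRatios(rnaDnaNormalize(pairedOmics(
    featureTable(rna * 7, "pathway"), featureTable(dna * 7, "pathway"))))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("log2 over-abundance matches its closed forms", {
  # cluster A mean ratio 16, cohort mean 4 -> ratio 4, log2 = 2; a tiny
  # third feature keeps the pseudocount negligible
  ratios <- cbind(f1 = c(16, 16, rep(1, 8)),
                  f2 = rep(2, 10),
                  tiny = rep(1e-6, 10))
  rownames(ratios) <- paste0("S", 1:10)
  # choose cluster sizes so cohort mean of f1 is 4: 2 samples at 16, 8 at 1
  labels <- factor(c("A", "A", rep("B", 8)))
  names(labels) <- rownames(ratios)
  act <- rnaDnaNormalize(pairedFromRatios(ratios))
  l2 <- log2Overabundance(act, labels)
  expect_equal(l2["A", "f1"], 2, tolerance = 1e-4)
  expect_equal(l2["A", "f2"], 0, tolerance = 1e-6)  # cluster mean = cohort mean
  expect_equal(l2["B", "f2"], 0, tolerance = 1e-6)
})

test_that("active-species counting enforces the strict threshold and ceiling rule", {
  # one species, one category with 3 pathways; cluster A has 1 sample,
  # cluster B has 9, so cluster/cohort ratios are controllable
  mk <- function(rA, rB) c(rA, rep(rB, 9))
  ratios <- cbind("path1|sp" = mk(10, 0.1),    # log2 over-abundance >> 1
                  "path2|sp" = mk(1, 1),       # exactly 0
                  "path3|sp" = mk(1, 1),
                  "tiny|sp" = rep(1e-8, 10))
  rownames(ratios) <- paste0("S", 1:10)
  labels <- factor(c("A", rep("B", 9))); names(labels) <- rownames(ratios)
  act <- rnaDnaNormalize(pairedFromRatios(ratios))
  cmap <- data.frame(pathway = c("path1", "path2", "path3"),
                     category = "carb")
  out <- countActiveSpecies(act, labels, cmap)
  # ceiling(3/3) = 1 pathway above threshold suffices
  expect_equal(out$n_active[out$cluster == "A" & out$category == "carb"], 1)
  expect_equal(out$n_active[out$cluster == "B" & out$category == "carb"], 0)

  # a log2 value of exactly 1 is NOT counted (strict >): build ratio 2x cohort
  # cluster A (5) at 2, cluster B (5) at ~0 gives cluster/cohort = 2 exactly
  r2 <- cbind("p|sp" = c(rep(2, 5), rep(0, 5)), "tiny|sp" = rep(1e-9, 10))
  rownames(r2) <- paste0("S", 1:10)
  lab2 <- factor(rep(c("A", "B"), each = 5)); names(lab2) <- rownames(r2)
  act2 <- rnaDnaNormalize(pairedFromRatios(r2))
  l2 <- log2Overabundance(act2, lab2)
  expect_lte(l2["A", "p|sp"], 1)  # pseudocount keeps it at or just below 1
  out2 <- countActiveSpecies(act2, lab2, data.frame(pathway = "p", category = "x"))
  expect_equal(out2$n_active[out2$cluster == "A"], 0)

  # species with all-undefined ratios is inactive everywhere; with unequal
  # cluster sizes the live species clears the threshold in its small cluster
  r3 <- cbind("p|dead" = rep(NA_real_, 10), "p|live" = c(8, rep(0.1, 9)),
              "tiny|live" = rep(1e-9, 10))
  rownames(r3) <- paste0("S", 1:10)
  lab3 <- factor(c("A", rep("B", 9))); names(lab3) <- rownames(r3)
  act3 <- rnaDnaNormalize(pairedFromRatios(r3))
  out3 <- countActiveSpecies(act3, lab3, data.frame(pathway = "p", category = "x"))
  expect_equal(out3$n_active[out3$cluster == "A"], 1)  # only the live species
  # raising the threshold never increases counts
  out3b <- countActiveSpecies(act3, lab3, data.frame(pathway = "p", category = "x"),
                              log2Threshold = 5)
  expect_lte(out3b$n_active[out3b$cluster == "A"],
             out3$n_active[out3$cluster == "A"])
})

test_that("KO panel ratios recover uniform and planted patterns", {
  # uniform expression: all entries 1
  ratios <- matrix(2, 8, 2, dimnames = list(paste0("S", 1:8),
                                            c("K00001|spA", "K00002|spB")))
  labels <- factor(rep(c("A", "B"), each = 4)); names(labels) <- rownames(ratios)
  kp <- koPanelRatios(pairedFromRatios(ratios), labels,
                      panel = c("K00001", "K00002", "K99999"))
  expect_true(all(abs(kp$ratio_vs_cohort - 1) < 1e-12))
  expect_identical(attr(kp, "missing"), "K99999")
  expect_warning(empty <- koPanelRatios(pairedFromRatios(ratios), labels,
                                        panel = character(0)), "empty")
  expect_equal(nrow(empty), 0)

  # default cohort: K00076 transcribed by E. coli only in C1
  cohort <- defaultCohort()
  kp2 <- koPanelRatios(cohort$paired, cohort$truth$cluster)
  k76 <- kp2[kp2$ko == "K00076" & kp2$species == "Escherichia_coli", ]
  expect_gt(k76$ratio_vs_cohort[k76$cluster == "C1"], 2)
  expect_true(all(k76$ratio_vs_cohort[k76$cluster != "C1"] < 0.05))
})
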