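test_that("simulated tree has one leaf per OTU and genus monophyly", {
  cfg <- synthConfig(rngSeed = 3L)
  tree <- simulateTree(cfg)
  ab <- simulateAbundances(cfg)
  otus <- featureNames(ab$table)
  expect_setequal(tree$tip.label, otus)
  # genus monophyly for a few multi-OTU genera
  byGenus <- split(names(ab$truth$otuGenus), ab$truth$otuGenus)
  for (g in names(byGenus)[vapply(byGenus, length, 1L) > 1][1:5])
    expect_true(ape::is.monophyletic(tree, byGenus[[g]]))
  expect_identical(ape::write.tree(simulateTree(cfg)), ape::write.tree(tree))
})

test_that("block multipliers of zero remove the block's genera", {
  bm <- matrix(1, 4, 5)
  bm[2, 1] <- 0  # Bifidobacterium block absent from C2
  cfg <- synthConfig(rngSeed = 9L, blockMultipliers = bm)
  ab <- simulateAbundances(cfg)
  rel <- relAbundance(ab$table)
  bifOtus <- names(ab$truth$otuGenus)[
    ab$truth$genusBlock[ab$truth$otuGenus] == "Bifidobacterium"]
  inC2 <- ab$truth$cluster == "C2"
  expect_equal(sum(rel[inC2, bifOtus]), 0)
  expect_gt(mean(rel[!inC2, bifOtus]), 0)
})

test_that("within-block genus correlations exceed between-block correlations", {
  cohort <- defaultCohort()
  gen <- filterGenera(cohort$genus)
  tau <- suppressWarnings(stats::cor(abundances(gen), method = "kendall"))
  blk <- cohort$truth$genusBlock[colnames(tau)]
  same <- outer(blk, blk, "==") & upper.tri(tau)
  diff <- (!outer(blk, blk, "==")) & upper.tri(tau)
  expect_gt(mean(tau[same], na.rm = TRUE), mean(tau[diff], na.rm = TRUE) + 0.3)
})

test_that("planted alpha-diversity contrast: C1 more diverse than C2", {
  cohort <- defaultCohort()
  ad <- alphaDiversity(cohort$otu)
  byCl <- tapply(ad$shannon, cohort$truth$cluster, mean)
  expect_gt(byCl[["C1"]], byCl[["C2"]])
})

test_that("YFAS instrument rules hold in simulated metadata", {
  md <- defaultCohort()$metadata
  expect_true(all(md$yfas_symptoms >= 0))
  expect_true(all(md$yfas_symptoms[md$yfas_diagnosis] >= 3))
  expect_true(all(md$weight_group[md$yfas_diagnosis] == "OB"))
})

test_that("null behavioral slope yields calibrated non-significance", {
  # beta = 0: planted scores independent of the axis; the association stage
  # should reject at about the nominal 5% rate
  set.seed(99)
  axes <- matrix(rnorm(300), 100, 3,
                 dimnames = list(sprintf("S%03d", 1:100), paste0("PCo", 1:3)))
  rej <- 0; B <- 40
  cfg <- synthConfig(rngSeed = 1L, betaUE = 0)
  truth <- list(cluster = factor(rep(c("C1", "C2", "C3", "C4"), 25),
                                 levels = paste0("C", 1:4)))
  names(truth$cluster) <- rownames(axes)
  for (i in seq_len(B)) {
    cfg$rngSeed <- 1000L + i
    md <- simulateMetadata(cfg, truth, pco2 = axes[, 2])
    qa <- quantileAssoc(md, axes, "tfeq_ue", nAxes = 2)
    if (qa$p[qa$axis == "PCo2"] <= 0.05) rej <- rej + 1
  }
  expect_lte(rej / B, 0.15)
})

test_that("default behavioral slope is recovered in sign and significance", {
  cohort <- defaultCohort()
  qa <- quantileAssoc(cohort$metadata, cohort$ordination,
                      c("tfeq_ue", "bite_symptom"), nAxes = 3)
  ue <- qa[qa$variable == "tfeq_ue" & qa$axis == "PCo2", ]
  expect_lt(ue$beta, 0)
  expect_lte(ue$p_adj, 0.05)
  # recovered raw slope near the planted one
  expect_equal(ue$beta, cohort$truth$rawBetaUE, tolerance = 0.25)
})

test_that("FFQ archetypes are exact at zero perturbation and recoverable at default noise", {
  cfg0 <- synthConfig(rngSeed = 21L, ffqConcentration = Inf)
  ab0 <- simulateAbundances(cfg0)
  ffq0 <- simulateFfq(cfg0, ab0$truth)
  shares <- sweep(abundances(ffq0$ffq), 1, rowSums(abundances(ffq0$ffq)), "/")
  arch <- microtype:::.dietArchetypes()
  for (s in sample(rownames(shares), 5))
    expect_equal(unname(shares[s, ]), unname(arch[as.character(ffq0$archetype[s]), ]),
                 tolerance = 1e-12)
  ca0 <- correspondenceAxis(ffq0$ffq)
  dg0 <- dietaryGroups(ca0, 3)
  expect_equal(randARI(dietGroups(dg0), ffq0$archetype), 1)

  cohort <- defaultCohort()
  dg <- dietaryGroups(correspondenceAxis(cohort$ffq), 3)
  expect_gte(randARI(dietGroups(dg), cohort$truth$diet), 0.8)
})

test_that("food annotations satisfy the macro-energy identity", {
  ann <- defaultFoodAnnotations()
  expect_equal(ann$kcal, 4 * ann$protein_g + 4 * ann$carb_g + 9 * ann$fat_g)
  expect_true(all(ann$hv >= 0 & ann$hv <= 1))
})

test_that("lipid panel plants the cluster contrasts and stays positive", {
  cohort <- defaultCohort()
  lip <- abundances(cohort$lipids)
  cl <- cohort$truth$cluster
  expect_true(all(lip > 0))
  for (l in c("acetate", "propionate", "butyrate")) {
    gc <- groupCompare(lip[, l], cl)
    expect_lt(gc$omnibus$p, 0.05)
    m <- gc$groups$median
    expect_gt(mean(m[1:2]), mean(m[3:4]))  # SCFAs higher in C1/C2
  }
  for (l in c("coprostanol", "sitostanol_5b", "campestanol_5b")) {
    m <- tapply(lip[, l], cl, median)
    expect_gt(mean(m[c("C3", "C4")]), mean(m[c("C1", "C2")]))
  }
  expect_gt(median(lip[cl == "C2", "cholesterol"]),
            median(lip[cl != "C2", "cholesterol"]))
})

test_that("zero lipid effect gives a null panel", {
  rej <- 0; B <- 30
  for (i in seq_len(B)) {
    cfg <- synthConfig(rngSeed = 2000L + i, lipidEffect = 0)
    ab <- simulateAbundances(cfg)
    lip <- simulateLipidome(cfg, ab$truth)
    gc <- groupCompare(abundances(lip)[, "butyrate"], ab$truth$cluster,
                       pairwisePosthoc = FALSE)
    if (gc$omnibus$p <= 0.05) rej <- rej + 1
  }
  expect_lte(rej / B, 0.2)
})

test_that("uniform expression gives unit RNA:DNA ratios; DNA zeros are carried", {
  cfg <- synthConfig(rngSeed = 31L, exprDefaults = FALSE, exprNoiseSd = 0.05)
  ab <- simulateAbundances(cfg)
  paired <- simulateTranscriptome(cfg, ab$truth)
  act <- rnaDnaNormalize(paired)
  mu <- colMeans(activityRatios(act), na.rm = TRUE)
  expect_true(all(abs(mu[is.finite(mu)] - 1) < 0.1))
  # the planted RNA-without-DNA feature is present, not dropped
  expect_true("Tryptophan_metabolism|Subdoligranulum_spp" %in%
                colnames(abundances(paired@dna)))
  expect_gt(nrow(rnaOnly(act)), 0)
})
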