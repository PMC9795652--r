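#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir directory with otu_table.tsv, tree.nwk, metadata.csv, ffq.tsv,
#'   food_annotations.tsv, lipids.tsv, rna.tsv, dna.tsv.
#' @return list of class `"microtypeCohort"` (without ground truth).
#' @export
readCohort <- function(dir) {
  need <- c("otu_table.tsv", "tree.nwk", "metadata.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) stop("missing input file(s): ", paste(miss, collapse = ", "))
  otu <- readFeatureTable(file.path(dir, "otu_table.tsv"), "otu")
  md <- readSampleMetadata(file.path(dir, "metadata.csv"))
  sdiff <- c(setdiff(sampleNames(otu), rownames(md)),
             setdiff(rownames(md), sampleNames(otu)))
  if (length(sdiff))
    stop("sample ids differ between OTU table and metadata: ",
         paste(sdiff, collapse = ", "))
  opt <- function(f, level) {
    p <- file.path(dir, f)
    if (file.exists(p)) readFeatureTable(p, level) else NULL
  }
  ffq <- opt("ffq.tsv", "food")
  ann <- if (file.exists(file.path(dir, "food_annotations.tsv")))
    utils::read.delim(file.path(dir, "food_annotations.tsv"),
                      stringsAsFactors = FALSE) else NULL
  rna <- opt("rna.tsv", "pathway"); dna <- opt("dna.tsv", "pathway")
  structure(list(
    otu = otu,
    genus = if (length(taxonomy(otu))) aggregateByTaxonomy(otu) else NULL,
    tree = readTree(file.path(dir, "tree.nwk")),
    metadata = md, ffq = ffq, foodAnnotations = ann,
    lipids = opt("lipids.tsv", "lipid"),
    paired = if (!is.null(rna) && !is.null(dna)) pairedOmics(rna, dna) else NULL,
    truth = NULL, config = NULL), class = "microtypeCohort")
}

.writeMatrixTsv <- function(m, path, rowLabel = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- rowLabel
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full downstream pipeline
#'
#' Executes typing, ordination, CAG, diet, activity, sPLS and association
#' stages in order on a cohort (simulated via [simulateCohort()] or read
#' via [readCohort()]), writes machine-readable stage outputs plus a run
#' manifest capturing seed, thresholds and package version, and returns
#' every stage result invisibly.
#'
#' @param cohort a `"microtypeCohort"` list.
#' @param config an [analysisConfig()].
#' @param outDir output directory (`NULL` = no files written).
#' @return list of stage results, invisibly when writing.
#' @export
runPipeline <- function(cohort, config = analysisConfig(), outDir = NULL) {
  res <- list()
  seed <- config$rngSeed

  ## --- community typing -------------------------------------------------
  otuRel <- featureTable(relAbundance(cohort$otu), level = "otu",
                         taxonomy = taxonomy(cohort$otu), isRelative = TRUE)
  filtered <- prevalenceFilter(otuRel, config$prevalenceThreshold,
                               renormalize = config$renormalizeAfterFilter)
  rho <- spearmanMatrix(filtered)
  assignment <- wardClusterSamples(rho, k = config$nClusters, kMax = config$kMax)
  assignment <- validateClustersBH(filtered, assignment,
                                   alpha = config$fdrAlpha,
                                   pairFraction = config$validityPairFraction)
  man <- permanova(1 - rho, clusterLabels(assignment),
                   nPerm = config$nPermutations, seed = seed)
  assignment@manova <- man
  res$typing <- assignment
  res$alpha <- alphaDiversity(cohort$otu, base = config$shannonLogBase)

  ## --- beta ordination --------------------------------------------------
  duw <- unifrac(cohort$otu, cohort$tree, weighted = FALSE)
  dw <- unifrac(cohort$otu, cohort$tree, weighted = TRUE,
                normalized = config$weightedNormalized)
  ord <- pcoa(duw)
  res$unifrac <- list(unweighted = duw, weighted = dw)
  res$permanovaUnifrac <- permanova(duw, clusterLabels(assignment),
                                    nPerm = config$nPermutations, seed = seed + 1L)
  if (!is.null(cohort$ffq))
    ord <- envfitVectors(ord, cohort$ffq, nPerm = config$nPermutations,
                         seed = seed + 2L, alpha = config$fdrAlpha)
  res$ordination <- ord

  ## --- co-abundance groups ----------------------------------------------
  if (!is.null(cohort$genus)) {
    gen <- filterGenera(cohort$genus, config$genusRelAbundThreshold,
                        config$genusMinSamples)
    net <- kendallNetwork(gen, alpha = config$fdrAlpha)
    part <- assignCags(gen, k = config$nCags, edges = net$edges)
    part <- wiggumStats(gen, assignment, part)
    res$cag <- list(partition = part, network = net)
  }

  ## --- dietary patterns -------------------------------------------------
  if (!is.null(cohort$ffq)) {
    ca <- correspondenceAxis(cohort$ffq)
    diet <- dietaryGroups(ca, k = 3L)
    diet@hfd <- hfdIndex(cohort$ffq, cohort$foodAnnotations)
    res$diet <- diet
    res$nutrients <- nutrientSummaries(cohort$ffq, cohort$foodAnnotations)
    res$dietCrosstab <- dietClusterCrosstab(diet, assignment, cohort$metadata)
  }

  ## --- transcriptional activity ------------------------------------------
  if (!is.null(cohort$paired)) {
    act <- rnaDnaNormalize(cohort$paired)
    res$activity <- act
    res$log2Overabundance <- log2Overabundance(act, assignment)
    res$activeCounts <- countActiveSpecies(act, assignment)
    res$koPanel <- koPanelRatios(cohort$paired, assignment)
  }

  ## --- multi-omics sPLS --------------------------------------------------
  if (!is.null(cohort$paired) && !is.null(cohort$lipids)) {
    Xblock <- prevalenceFilterFeatures(cohort$paired@rna, config$splsPrevalence)
    model <- splsFit(Xblock, cohort$lipids, ncomp = config$splsNcomp,
                     keepX = config$splsKeepX)
    res$spls <- list(model = model, heatmap = splsCluster(model))
  }

  ## --- host associations --------------------------------------------------
  md <- clinicalIndices(cohort$metadata)
  md$behavior_group <- yfasStratify(md)
  res$clinical <- md
  behav <- intersect(c("bite_symptom", "tfeq_ue", "bmi", "homa_ir", "pss"),
                     names(md))
  res$associations <- quantileAssoc(md, ord, behav, nAxes = 3L,
                                    alpha = config$fdrAlpha, seed = seed + 3L)
  if ("weight_group" %in% names(md)) {
    tab <- table(md$weight_group, clusterLabels(assignment)[rownames(md)])
    res$weightByCluster <- list(table = tab,
                                fisher = fisher2xk(tab, seed = seed + 4L))
  }

  ## --- outputs ------------------------------------------------------------
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) utils::write.table(df, file.path(outDir, f),
                                            sep = "\t", quote = FALSE,
                                            row.names = FALSE)
    w(data.frame(sample_id = names(clusterLabels(assignment)),
                 cluster = as.character(clusterLabels(assignment))),
      "cluster_assignments.tsv")
    w(res$alpha, "alpha_diversity.tsv")
    jsonlite::write_json(
      list(spearman = assignment@manova, unifrac = res$permanovaUnifrac),
      file.path(outDir, "permanova.json"), auto_unbox = TRUE, digits = NA)
    hc <- assignment@tree$hclust
    jsonlite::write_json(list(merge = hc$merge, height = hc$height,
                              order = hc$order, labels = hc$labels),
                         file.path(outDir, "dendrogram.json"), digits = NA)
    .writeMatrixTsv(duw, file.path(outDir, "unifrac_unweighted.tsv"), "sample_id")
    .writeMatrixTsv(dw, file.path(outDir, "unifrac_weighted.tsv"), "sample_id")
    .writeMatrixTsv(ordinationPoints(ord), file.path(outDir, "pcoa_coords.tsv"),
                    "sample_id")
    w(data.frame(axis = seq_along(eigenvalues(ord)), eigenvalue = eigenvalues(ord)),
      "pcoa_eigs.tsv")
    if (nrow(fittedVectors(ord))) w(fittedVectors(ord), "envfit.tsv")
    if (!is.null(res$cag)) {
      part <- res$cag$partition
      w(data.frame(genus = names(cagMembership(part)),
                   cag = unname(cagMembership(part)),
                   cag_name = unname(cagNames(part)[cagMembership(part)])),
        "cag_assignments.tsv")
      w(res$cag$network$allPairs, "kendall_pairs.tsv")
      .writeMatrixTsv(discSizes(part), file.path(outDir, "wiggum_stats.tsv"), "genus")
      writeCagGraphML(part, file.path(outDir, "edges.graphml"))
    }
    if (!is.null(res$diet)) {
      w(data.frame(sample_id = names(dietGroups(res$diet)),
                   diet_group = as.character(dietGroups(res$diet)),
                   ca_axis1 = unname(axisScores(res$diet)),
                   hfd = unname(res$diet@hfd[names(dietGroups(res$diet))])),
        "diet_groups.tsv")
      w(res$nutrients, "nutrients.tsv")
      w(res$dietCrosstab, "diet_cluster_crosstab.tsv")
    }
    if (!is.null(res$activity)) {
      .writeMatrixTsv(activityRatios(res$activity),
                      file.path(outDir, "activity_ratios.tsv"), "sample_id")
      .writeMatrixTsv(res$log2Overabundance,
                      file.path(outDir, "cluster_log2.tsv"), "cluster")
      w(res$activeCounts, "active_counts.tsv")
      w(res$koPanel, "ko_panel.tsv")
    }
    if (!is.null(res$spls)) {
      .writeMatrixTsv(splsLoadings(res$spls$model, "X"),
                      file.path(outDir, "spls_loadings_X.tsv"), "feature")
      .writeMatrixTsv(splsLoadings(res$spls$model, "Y"),
                      file.path(outDir, "spls_loadings_Y.tsv"), "feature")
      .writeMatrixTsv(splsScores(res$spls$model, "X"),
                      file.path(outDir, "spls_scores.tsv"), "sample_id")
      w(data.frame(axis = c(rep("row", length(res$spls$heatmap$rowOrder)),
                            rep("col", length(res$spls$heatmap$colOrder))),
                   feature = c(res$spls$heatmap$rowOrder,
                               res$spls$heatmap$colOrder)),
        "spls_heatmap_order.tsv")
    }
    w(res$associations, "associations.tsv")
    utils::write.csv(res$clinical, file.path(outDir, "derived_clinical.csv"),
                     row.names = FALSE)
    w(data.frame(sample_id = rownames(res$clinical),
                 behavior_group = as.character(res$clinical$behavior_group)),
      "behavior_groups.tsv")
    jsonlite::write_json(
      list(fisher_weight_by_cluster = res$weightByCluster$fisher,
           cramers_v_weight_by_cluster = cramersV(res$weightByCluster$table)),
      file.path(outDir, "categorical_tests.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(package = "microtype",
           version = as.character(utils::packageVersion("microtype")),
           r_version = R.version.string,
           seed = seed,
           config = config[setdiff(names(config), "splsKeepX")],
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
           orientation = "samples-in-rows in memory; samples-in-columns on disk"),
      file.path(outDir, "run_manifest.json"), auto_unbox = TRUE)
    return(invisible(res))
  }
  res
}
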