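#' Analysis configuration
#'
#' Collects every tunable threshold of the downstream pipeline.  Defaults are
#' the working values of the analysis: OTU prevalence filter 20% (inclusive),
#' genus filter relative abundance > 0.1% (strict) in at least 2 samples,
#' FDR 0.05, 999 permutations, Shannon index in bits (log base 2).
#'
#' @param prevalenceThreshold fraction of samples an OTU must be present in.
#' @param genusRelAbundThreshold relative abundance a genus must exceed.
#' @param genusMinSamples number of samples in which it must exceed it.
#' @param nClusters `"auto"` (silhouette-selected) or an integer k.
#' @param kMax largest k tried when `nClusters = "auto"`.
#' @param nCags number of co-abundance groups to cut.
#' @param nPermutations permutations for PERMANOVA / envfit (>= 99).
#' @param fdrAlpha FDR level gating network edges and BH significance.
#' @param rngSeed mandatory seed for every stochastic stage.
#' @param shannonLogBase base of the Shannon index logarithm.
#' @param validityPairFraction fraction of within-cluster pairs that must be
#'   BH-significant for a cluster to be flagged valid.
#' @param renormalizeAfterFilter re-normalize proportions after the
#'   prevalence filter (default `FALSE`: retained proportions keep their
#'   meaning in the original community).
#' @param weightedNormalized use the normalized weighted UniFrac variant.
#' @param splsNcomp,splsKeepX sPLS components and per-component X sparsity
#'   (`NULL` keepX = all features).
#' @param splsPrevalence prevalence threshold for metatranscriptomic features
#'   entering the sPLS X block.
#' @return list of class `"analysisConfig"`.
#' @export
analysisConfig <- function(prevalenceThreshold = 0.20,
                           genusRelAbundThreshold = 0.001,
                           genusMinSamples = 2L,
                           nClusters = "auto", kMax = 8L,
                           nCags = 5L,
                           nPermutations = 999L,
                           fdrAlpha = 0.05,
                           rngSeed = 1L,
                           shannonLogBase = 2,
                           validityPairFraction = 0.95,
                           renormalizeAfterFilter = FALSE,
                           weightedNormalized = TRUE,
                           splsNcomp = 2L, splsKeepX = NULL,
                           splsPrevalence = 0.5) {
  stopifnot(prevalenceThreshold >= 0, prevalenceThreshold <= 1,
            genusRelAbundThreshold >= 0, genusRelAbundThreshold <= 1,
            fdrAlpha > 0, fdrAlpha <= 1,
            splsPrevalence >= 0, splsPrevalence <= 1,
            nPermutations >= 99L,
            !is.null(rngSeed))
  structure(list(prevalenceThreshold = prevalenceThreshold,
                 genusRelAbundThreshold = genusRelAbundThreshold,
                 genusMinSamples = as.integer(genusMinSamples),
                 nClusters = nClusters, kMax = as.integer(kMax),
                 nCags = as.integer(nCags),
                 nPermutations = as.integer(nPermutations),
                 fdrAlpha = fdrAlpha, rngSeed = as.integer(rngSeed),
                 shannonLogBase = shannonLogBase,
                 validityPairFraction = validityPairFraction,
                 renormalizeAfterFilter = renormalizeAfterFilter,
                 weightedNormalized = weightedNormalized,
                 splsNcomp = as.integer(splsNcomp), splsKeepX = splsKeepX,
                 splsPrevalence = splsPrevalence),
            class = "analysisConfig")
}

.CLUSTERS <- c("C1", "C2", "C3", "C4")
.BLOCKS <- c("Bifidobacterium", "Ruminococcus", "Dorea", "Prevotella", "Bacteroides")
.KO_PANEL <- c("K01442", "K00076", "K07007", "K03778", "K00170",
               "K00172", "K01667", "K01046", "K01995", "K01580")

.defaultBlockMultipliers <- function() {
  m <- matrix(1, 4, 5, dimnames = list(.CLUSTERS, .BLOCKS))
  m["C2", "Bifidobacterium"] <- 0.02
  m["C3", "Bifidobacterium"] <- 0.02
  m["C3", c("Prevotella", "Ruminococcus")] <- 3
  m["C4", "Bacteroides"] <- 0.02
  m["C4", "Bifidobacterium"] <- 3
  m
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator plants: 100 premenopausal
#' women in four community clusters at proportions 0.31/0.33/0.22/0.14 with
#' normal-weight probabilities 0.48/0.28/0.36/0.36 per cluster; 40 genera in
#' five co-abundance blocks (each named for its dominant genus); cluster x
#' block abundance multipliers that remove the Bifidobacterium block in
#' C2/C3, double Prevotella and Ruminococcus in C3, and trade Bacteroides
#' for a tripled Bifidobacterium block in C4; behavioral scores tied
#' negatively to ordination axis 2; three dietary archetypes; a
#' cluster-patterned lipid panel; and per-(species, pathway, cluster)
#' expression multipliers including a KO panel transcribed only in specific
#' clusters.
#'
#' @param nSamples cohort size.
#' @param clusterProportions length-4 proportions summing to 1.
#' @param nwProbability per-cluster probability of NW weight status.
#' @param blockMultipliers 4 x 5 matrix of cluster x block abundance
#'   multipliers (>= 0).
#' @param generaPerBlock genera simulated per co-abundance block.
#' @param otusPerGenus integer range (min, max) of OTUs per genus.
#' @param latentLoading within-block latent-factor loading on the log scale
#'   (drives positive within-block Kendall correlation).
#' @param noiseSd residual log-abundance noise.
#' @param otuSplitConcentration Dirichlet concentration tying each cluster's
#'   within-genus OTU split to the genus's base split; lower values give the
#'   community states more divergent strain-level (OTU) composition.
#' @param depth sequencing depth per sample (multinomial reads, >= 1000).
#' @param betaUE,betaBITE planted slopes of TFEQ-UE and BITE symptom scores
#'   on ordination axis 2, in score points per axis standard deviation
#'   (negative by default: lower PCo2, higher scores).
#' @param ffqConcentration Dirichlet concentration around dietary archetypes
#'   (`Inf` reproduces archetypes exactly).
#' @param lipidEffect scale of the planted lipid contrasts (0 = null panel).
#' @param exprNoiseSd log-normal noise sd on RNA levels.
#' @param exprMultipliers data.frame (species, pathway, cluster, multiplier)
#'   of planted expression multipliers appended to (and overriding cells of)
#'   the default layout.
#' @param exprDefaults include the default expression layout (set `FALSE`
#'   with `exprMultipliers = NULL` for uniform expression E = 1).
#' @param koPanel KO identifiers included as gene-family features.
#' @param rngSeed mandatory generator seed.
#' @return list of class `"synthConfig"`.
#' @export
synthConfig <- function(nSamples = 100L,
                        clusterProportions = c(0.31, 0.33, 0.22, 0.14),
                        nwProbability = c(0.48, 0.28, 0.36, 0.36),
                        blockMultipliers = .defaultBlockMultipliers(),
                        generaPerBlock = 8L,
                        otusPerGenus = c(3L, 10L),
                        latentLoading = 0.3,
                        noiseSd = 0.25,
                        otuSplitConcentration = 1.5,
                        depth = 5000L,
                        betaUE = -1.5, betaBITE = -1.2,
                        ffqConcentration = 60,
                        lipidEffect = 1,
                        exprNoiseSd = 0.25,
                        exprMultipliers = NULL,
                        exprDefaults = TRUE,
                        koPanel = .KO_PANEL,
                        rngSeed = 42L) {
  stopifnot(abs(sum(clusterProportions) - 1) < 1e-9,
            length(clusterProportions) == 4L,
            all(nwProbability >= 0 & nwProbability <= 1),
            all(blockMultipliers >= 0),
            depth >= 1000L,
            !is.null(rngSeed))
  if (is.null(dimnames(blockMultipliers)))
    dimnames(blockMultipliers) <- list(.CLUSTERS, .BLOCKS)
  structure(list(nSamples = as.integer(nSamples),
                 clusterProportions = setNames(clusterProportions, .CLUSTERS),
                 nwProbability = setNames(nwProbability, .CLUSTERS),
                 blockMultipliers = blockMultipliers,
                 generaPerBlock = as.integer(generaPerBlock),
                 otusPerGenus = as.integer(otusPerGenus),
                 latentLoading = latentLoading, noiseSd = noiseSd,
                 otuSplitConcentration = otuSplitConcentration,
                 depth = as.integer(depth),
                 betaUE = betaUE, betaBITE = betaBITE,
                 ffqConcentration = ffqConcentration,
                 lipidEffect = lipidEffect,
                 exprNoiseSd = exprNoiseSd,
                 exprMultipliers = exprMultipliers,
                 exprDefaults = exprDefaults,
                 koPanel = koPanel,
                 rngSeed = as.integer(rngSeed)),
            class = "synthConfig")
}
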