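## Synthetic multi-omics cohort generator.  Every simulate* stage derives its
## randomness from config$rngSeed plus a fixed stage offset, so single stages
## and the whole cohort are reproducible independently.

.SPECIES <- c("Faecalibacterium_prausnitzii", "Bifidobacterium_longum",
              "Bifidobacterium_adolescentis", "Ruminococcus_bromii",
              "Eubacterium_rectale", "Akkermansia_muciniphila",
              "Bacteroides_vulgatus", "Subdoligranulum_spp",
              "Escherichia_coli", "Anaerostipes_hadrus")

.PATHWAYS <- c("Glycolysis", "Galactose_metabolism",
               "Secondary_bile_acid_biosynthesis", "Glycerolipid_metabolism",
               "Propanoate_metabolism", "Butanoate_metabolism",
               "Pyruvate_metabolism", "Cysteine_methionine_metabolism",
               "Glycine_serine_threonine_metabolism",
               "Pentose_phosphate_pathway", "Fatty_acid_biosynthesis",
               "Tryptophan_metabolism", "Xenobiotics_degradation")

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

.largestRemainder <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    idx <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[idx] <- k[idx] + 1
  }
  as.integer(k)
}

## Deterministic cohort layout (genus catalogue, OTUs per genus, OTU split
## weights, species x pathway incidence).  Uses its own seed offset so that
## simulateTree and simulateAbundances agree on the same layout.
.cohortLayout <- function(config) {
  set.seed(config$rngSeed + 7L)
  blocks <- colnames(config$blockMultipliers)
  gpb <- config$generaPerBlock
  genera <- unlist(lapply(blocks, function(b)
    c(b, paste0(b, "_g", seq_len(gpb - 1L) + 1L))))
  genusBlock <- setNames(rep(blocks, each = gpb), genera)
  # namesake genus dominates its block; weights fall off within the block
  within <- c(2.5, 1 / (2:gpb)^0.7)
  blockWeight <- setNames(c(2, 1.5, 1, 1.5, 1.2), .BLOCKS)[genusBlock[genera]]
  genusWeight <- setNames(rep(within, length(blocks)) * blockWeight, genera)
  nOtus <- setNames(sample(seq(config$otusPerGenus[1], config$otusPerGenus[2]),
                           length(genera), replace = TRUE), genera)
  otuGenus <- setNames(rep(genera, nOtus),
                       unlist(lapply(genera, function(g)
                         paste0(g, ".OTU", seq_len(nOtus[g])))))
  # base within-genus OTU split, and a per-cluster split drawn around it:
  # community states differ in strain-level (OTU) composition, which leaves
  # all genus-level quantities untouched
  otuSplit <- lapply(genera, function(g) {
    w <- as.numeric(.rdirichlet(1, rep(2, nOtus[g])))
    setNames(w, names(otuGenus)[otuGenus == g])
  })
  names(otuSplit) <- genera
  clusterSplit <- lapply(.CLUSTERS, function(cc) {
    s <- lapply(genera, function(g)
      setNames(as.numeric(.rdirichlet(1, config$otuSplitConcentration *
                                        length(otuSplit[[g]]) * otuSplit[[g]])),
               names(otuSplit[[g]])))
    names(s) <- genera
    s
  })
  names(clusterSplit) <- .CLUSTERS
  # species x pathway incidence (fixed); cells the expression layout relies
  # on are forced present
  inc <- matrix(stats::rbinom(length(.SPECIES) * length(.PATHWAYS), 1, 0.75),
                length(.SPECIES), length(.PATHWAYS),
                dimnames = list(.SPECIES, .PATHWAYS))
  inc["Faecalibacterium_prausnitzii", "Secondary_bile_acid_biosynthesis"] <- 1
  inc["Ruminococcus_bromii", "Glycerolipid_metabolism"] <- 1
  inc["Bifidobacterium_longum", "Galactose_metabolism"] <- 1
  inc["Bacteroides_vulgatus", "Butanoate_metabolism"] <- 1
  inc["Subdoligranulum_spp", "Tryptophan_metabolism"] <- 0  # RNA-only cell
  koInc <- matrix(0L, length(.SPECIES), length(config$koPanel),
                  dimnames = list(.SPECIES, config$koPanel))
  for (ko in config$koPanel)
    koInc[sample(length(.SPECIES), 3L), ko] <- 1L
  koInc["Escherichia_coli", "K00076"] <- 1L
  koInc["Anaerostipes_hadrus", "K01442"] <- 1L
  koInc["Faecalibacterium_prausnitzii", "K07007"] <- 1L
  list(genera = genera, genusBlock = genusBlock, genusWeight = genusWeight,
       nOtus = nOtus, otuGenus = otuGenus, otuSplit = otuSplit,
       clusterSplit = clusterSplit, incidence = cbind(inc, koInc))
}

#' Simulate the OTU phylogeny
#'
#' A pure-birth genus backbone with exponential branch lengths; per-genus OTU
#' subtrees are grafted onto the backbone tips, so genus monophyly holds by
#' construction.
#'
#' @param config a [synthConfig()].
#' @return a rooted [ape::phylo] tree whose tips are OTU ids.
#' @export
simulateTree <- function(config) {
  layout <- .cohortLayout(config)
  set.seed(config$rngSeed + 1L)
  tree <- ape::rphylo(length(layout$genera), birth = 1, death = 0)
  tree$tip.label <- layout$genera
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 2)
  for (g in layout$genera) {
    otus <- names(layout$otuGenus)[layout$otuGenus == g]
    if (length(otus) == 1L) {
      tree$tip.label[tree$tip.label == g] <- otus
    } else {
      sub <- ape::rphylo(length(otus), birth = 1, death = 0)
      sub$tip.label <- otus
      sub$edge.length <- stats::rexp(nrow(sub$edge), rate = 10)
      tree <- ape::bind.tree(tree, sub, where = which(tree$tip.label == g))
    }
  }
  tree
}

#' Simulate the OTU count table with planted cluster and block structure
#'
#' Per sample `s` in cluster `c`, genus log-abundance is
#' `log(w_g) + log(M[c, b(g)]) + lambda * f[b(g), s] + eps`, where `f` is a
#' per-(block, sample) latent factor driving positive within-block Kendall
#' correlation, `M` the cluster x block multiplier matrix, and `eps` Gaussian
#' noise.  Genus mass is split over its OTUs by a cluster-specific Dirichlet
#' draw around a fixed base split (community states differ in strain-level
#' composition; `otuSplitConcentration` controls how much) and counts are
#' drawn multinomially at the configured depth.  A multiplier of exactly 0
#' removes the block deterministically.
#'
#' @param config a [synthConfig()].
#' @return list with `table` (OTU-level count [FeatureTable-class] with genus
#'   taxonomy) and `truth` (per-sample cluster, per-genus block, per-OTU
#'   genus, latent factors).
#' @export
simulateAbundances <- function(config) {
  layout <- .cohortLayout(config)
  set.seed(config$rngSeed + 2L)
  n <- config$nSamples
  samples <- sprintf("S%03d", seq_len(n))
  counts <- .largestRemainder(n, config$clusterProportions)
  if (any(counts == 0)) stop("cohort too small for the cluster proportions")
  cluster <- factor(sample(rep(.CLUSTERS, counts)), levels = .CLUSTERS)
  names(cluster) <- samples
  blocks <- colnames(config$blockMultipliers)
  fac <- matrix(stats::rnorm(n * length(blocks)), n,
                dimnames = list(samples, blocks))
  mult <- config$blockMultipliers[as.character(cluster), , drop = FALSE]
  genera <- layout$genera
  logA <- matrix(0, n, length(genera), dimnames = list(samples, genera))
  for (g in genera) {
    b <- layout$genusBlock[[g]]
    m <- mult[, b]
    logA[, g] <- ifelse(m == 0, -Inf,
                        log(layout$genusWeight[[g]]) + log(m) +
                          config$latentLoading * fac[, b] +
                          stats::rnorm(n, 0, config$noiseSd))
  }
  A <- exp(logA)
  genusRel <- A / rowSums(A)
  otus <- names(layout$otuGenus)
  probs <- matrix(0, n, length(otus), dimnames = list(samples, otus))
  for (cc in levels(cluster)) {
    rows <- which(cluster == cc)
    for (g in genera)
      probs[rows, names(layout$otuSplit[[g]])] <-
        genusRel[rows, g] %o% layout$clusterSplit[[cc]][[g]]
  }
  cnt <- t(apply(probs, 1L, function(p) stats::rmultinom(1, config$depth, p)))
  dimnames(cnt) <- dimnames(probs)
  lowPrev <- mean(colMeans(cnt > 0) < 0.05)
  if (config$depth < 2000L && lowPrev > 0.5)
    warning("sequencing depth too low to realize the planted prevalence structure")
  tab <- featureTable(cnt, level = "otu",
                      taxonomy = layout$otuGenus, isRelative = FALSE)
  truth <- list(cluster = cluster, genusBlock = layout$genusBlock,
                otuGenus = layout$otuGenus, latentFactors = fac,
                blockMultipliers = config$blockMultipliers)
  list(table = tab, truth = truth)
}

#' Aggregate an OTU table to genus level
#'
#' Sums counts over the taxonomy mapping and returns relative abundances.
#' @param table an OTU-level [FeatureTable-class] with taxonomy.
#' @return genus-level relative-abundance [FeatureTable-class].
#' @export
aggregateByTaxonomy <- function(table) {
  tax <- taxonomy(table)
  if (!length(tax)) stop("table has no taxonomy mapping")
  m <- abundances(table)
  groups <- tax[colnames(m)]
  agg <- t(rowsum(t(m), group = groups))
  rel <- agg / rowSums(agg)
  featureTable(rel, level = "genus", isRelative = TRUE)
}

#' Simulate host metadata tied to the ordination
#'
#' Weight status is Bernoulli per cluster at the configured NW probabilities;
#' TFEQ-UE and BITE symptom scores are linear in ordination axis 2 (slopes
#' `betaUE`, `betaBITE` in score points per axis standard deviation,
#' negative by default; the implied raw per-unit slope is recorded in the
#' returned truth as `rawBetaUE`/`rawBetaBITE`) with an age term and symmetric
#' noise; YFAS symptom counts follow cluster- and weight-dependent Poisson
#' distributions with diagnosis only possible at 3+ symptoms; glucose and
#' insulin are drawn so that the OB group skews insulin-resistant (about 40%
#' above the HOMA-IR 2.5 threshold) while NW stays below it.
#'
#' @param config a [synthConfig()].
#' @param truth truth list from [simulateAbundances()], with a `pco2`
#'   element (per-sample ordination axis-2 score) added by [simulateCohort()]
#'   or supplied via `pco2`.
#' @param pco2 optional named numeric overriding `truth$pco2`.
#' @return metadata data.frame (one row per sample).
#' @export
simulateMetadata <- function(config, truth, pco2 = truth$pco2) {
  if (is.null(pco2))
    stop("simulateMetadata needs per-sample ordination axis-2 scores ",
         "(truth$pco2); run simulateCohort() or pass pco2=")
  set.seed(config$rngSeed + 3L)
  cluster <- truth$cluster
  samples <- names(cluster)
  n <- length(samples)
  pco2 <- pco2[samples]
  nw <- stats::rbinom(n, 1, config$nwProbability[as.character(cluster)]) == 1
  weight <- factor(ifelse(nw, "NW", "OB"), levels = c("NW", "OB"))
  age <- pmin(pmax(stats::rnorm(n, 35, 8), 18), 55)
  bmi <- ifelse(nw, pmin(pmax(stats::rnorm(n, 21.5, 1.5), 18.5), 24.6),
                pmin(pmax(stats::rnorm(n, 31, 3), 25.6), 39.8))
  axSd <- stats::sd(pco2)
  rawBetaUE <- if (axSd > 0) config$betaUE / axSd else 0
  rawBetaBITE <- if (axSd > 0) config$betaBITE / axSd else 0
  tfeq_ue <- 17 + rawBetaUE * pco2 + 0.05 * (age - 35) + stats::rnorm(n, 0, 2.5)
  bite_symptom <- 6.5 + rawBetaBITE * pco2 + 0.03 * (age - 35) + stats::rnorm(n, 0, 3)
  lamYfas <- ifelse(nw, 1.1,
                    c(C1 = 2.2, C2 = 3.2, C3 = 3.0, C4 = 3.3)[as.character(cluster)])
  yfas_symptoms <- pmin(stats::rpois(n, lamYfas), 7L)
  yfas_diagnosis <- !nw & yfas_symptoms >= 3L & stats::runif(n) < 0.45
  glucose <- ifelse(nw, stats::rnorm(n, 82, 5), stats::rnorm(n, 88, 6))
  glucose <- pmax(glucose, 65)
  insulin <- exp(ifelse(nw, stats::rnorm(n, log(3.7), 0.35),
                        stats::rnorm(n, log(10), 0.55)))
  md <- data.frame(
    sample_id = samples,
    weight_group = weight,
    bmi = round(bmi, 1),
    age = round(age, 1),
    fasting_glucose = round(glucose, 1),
    fasting_insulin = round(insulin, 2),
    glucose_auc = round(glucose * 150 * exp(stats::rnorm(n, 0, 0.08))),
    insulin_auc = round(insulin * 700 * exp(stats::rnorm(n, 0, 0.2))),
    tfeq_ue = round(tfeq_ue, 2),
    tfeq_cr = round(14.4 + 2 * !nw + stats::rnorm(n, 0, 4), 2),
    tfeq_ee = round(7.6 + 1.5 * !nw + stats::rnorm(n, 0, 2.8), 2),
    bite_symptom = round(bite_symptom, 2),
    bite_severity = round(pmax(2 + 3 * !nw + stats::rnorm(n, 0, 3), 0), 2),
    yfas_symptoms = yfas_symptoms,
    yfas_diagnosis = yfas_diagnosis,
    pss = round(16 + stats::rnorm(n, 0, 6), 1),
    row.names = samples)
  validateMetadata(md)
  md
}

.foodAnnotationRows <- function() {
  # kcal is exactly 4p + 4c + 9f so macro-energy identities hold by construction
  f <- function(food, p, c, fat, fiber, hv)
    data.frame(food = food, protein_g = p, carb_g = c, fat_g = fat,
               kcal = 4 * p + 4 * c + 9 * fat, fiber_g = fiber, hv = hv)
  rbind(
    f("wholegrain_bread", 3, 15, 1, 3, 0.90),
    f("vegetables", 2, 5, 0.5, 4, 1.00),
    f("fruit", 1, 12, 0.3, 2.5, 0.95),
    f("legumes", 7, 20, 1, 7, 1.00),
    f("fish", 20, 0, 5, 0, 0.90),
    f("olive_oil", 0, 0, 10, 0, 0.85),
    f("nuts", 5, 5, 15, 3, 0.90),
    f("yoghurt", 5, 6, 3, 0, 0.70),
    f("milk", 6, 9, 5, 0, 0.60),
    f("cheese", 12, 1, 15, 0, 0.40),
    f("eggs", 12, 1, 10, 0, 0.60),
    f("meat", 20, 0, 12, 0, 0.45),
    f("sliced_ham", 15, 1, 8, 0, 0.30),
    f("sweet_snacks", 3, 30, 12, 1, 0.10),
    f("biscuits", 4, 35, 10, 1.5, 0.15),
    f("sweetened_drinks", 0, 25, 0, 0, 0.05),
    f("fried_potatoes", 3, 30, 12, 2.5, 0.20),
    f("salty_snacks", 4, 28, 14, 1.5, 0.15),
    f("seasonings_condiments", 1, 3, 8, 0.2, 0.25),
    f("homemade_sandwiches", 10, 30, 10, 2, 0.40))
}

#' Per-item food annotations used by the FFQ generator
#'
#' Twenty food items with per-portion energy, macronutrients, fiber and a
#' health value in \[0, 1\].  Macro energy (4/4/9 kcal per g) sums exactly to
#' the item energy.
#' @return data.frame with rownames = food ids.
#' @export
defaultFoodAnnotations <- function() {
  ann <- .foodAnnotationRows()
  rownames(ann) <- ann$food
  ann
}

.dietArchetypes <- function() {
  foods <- defaultFoodAnnotations()$food
  arch <- rbind(
    D1 = c(0.5, 0.5, 0.5, 0.2, 0.2, 0.5, 0.2, 0.5, 0.8, 0.3, 1.2, 0.3, 0.3,
           2.5, 2.5, 1.8, 0.8, 0.5, 0.5, 0.8),
    D2 = c(0.8, 1.0, 0.8, 0.5, 1.2, 1.0, 0.8, 0.4, 0.3, 0.4, 0.8, 2.0, 1.5,
           0.3, 0.3, 0.3, 1.2, 1.5, 1.0, 1.8),
    D3 = c(1.0, 1.0, 1.0, 0.6, 0.8, 1.2, 1.0, 1.8, 1.8, 2.2, 0.6, 0.6, 0.5,
           0.5, 0.5, 0.3, 0.5, 0.5, 1.2, 0.6))
  colnames(arch) <- foods
  arch / rowSums(arch)
}

#' Simulate food-frequency questionnaire data
#'
#' Each sample is assigned one of three dietary archetypes (a low-diversity
#' sweets-and-carbohydrate diet, a high-protein diet, and a dairy-centred
#' high-fat diet).  Per-sample frequencies are a Dirichlet perturbation of
#' the archetype share profile, scaled by a total-consumption factor that is
#' higher for clusters C2-C4.
#'
#' @param config a [synthConfig()].
#' @param truth truth list (for per-sample cluster labels).
#' @return list with `ffq` (food-level [FeatureTable-class] of daily
#'   consumption frequencies), `annotations` (see
#'   [defaultFoodAnnotations()]), and `archetype` (named factor, the planted
#'   dietary group).
#' @export
simulateFfq <- function(config, truth) {
  set.seed(config$rngSeed + 4L)
  cluster <- truth$cluster
  samples <- names(cluster)
  n <- length(samples)
  arch <- .dietArchetypes()
  assign <- factor(sample(rownames(arch), n, replace = TRUE,
                          prob = c(0.4, 0.3, 0.3)), levels = rownames(arch))
  names(assign) <- samples
  energyFactor <- ifelse(cluster == "C1", 1, 1.15)
  shares <- t(vapply(seq_len(n), function(i) {
    p <- arch[assign[i], ]
    if (is.finite(config$ffqConcentration))
      as.numeric(.rdirichlet(1, config$ffqConcentration * length(p) * p))
    else p
  }, numeric(ncol(arch))))
  totalFreq <- 12 * energyFactor * exp(stats::rnorm(n, 0, 0.08))
  freq <- shares * totalFreq
  dimnames(freq) <- list(samples, colnames(arch))
  list(ffq = featureTable(freq, level = "food", isRelative = FALSE),
       annotations = defaultFoodAnnotations(), archetype = assign)
}

.LIPIDS <- data.frame(
  lipid = c("acetate", "propionate", "butyrate",
            "cholesterol", "coprostanol", "cholestanol_5a", "sitosterol",
            "sitostanol_5b", "campestanol_5b", "campesterol",
            "cholic_acid", "chenodeoxycholic_acid", "deoxycholic_acid",
            "lithocholic_acid", "ursodeoxycholic_acid"),
  base = c(60, 25, 20, 3, 6, 0.5, 1.5, 0.4, 0.15, 0.5,
           0.3, 0.25, 1.2, 0.8, 0.1))

.lipidMultipliers <- function(effect) {
  m <- matrix(1, 4, nrow(.LIPIDS), dimnames = list(.CLUSTERS, .LIPIDS$lipid))
  scfa <- c("acetate", "propionate", "butyrate")
  m[c("C1", "C2"), scfa] <- 2
  m[c("C3", "C4"), "coprostanol"] <- 2
  m[c("C3", "C4"), "sitostanol_5b"] <- 4
  m[c("C3", "C4"), "campestanol_5b"] <- 1.8
  m["C2", c("cholesterol", "cholic_acid", "chenodeoxycholic_acid")] <- 2
  m["C4", c("deoxycholic_acid", "lithocholic_acid")] <- 1.8
  m^effect
}

#' Simulate the fecal lipid panel
#'
#' Log-normal panels per cluster: SCFAs elevated in C1/C2; converted sterols
#' (coprostanol, 5-beta-sitostanol, 5-beta-campestanol) elevated in C3/C4;
#' cholesterol and the primary bile acids (cholic, chenodeoxycholic) elevated
#' in C2; secondary bile acids additionally elevated in C4 so total bile
#' acids are highest in C2 and C4.  `lipidEffect = 0` gives a null panel.
#'
#' @param config a [synthConfig()].
#' @param truth truth list (cluster labels).
#' @return lipid-level [FeatureTable-class] (concentrations, ug per mg dry
#'   weight scale).
#' @export
simulateLipidome <- function(config, truth) {
  set.seed(config$rngSeed + 5L)
  cluster <- truth$cluster
  samples <- names(cluster)
  mult <- .lipidMultipliers(config$lipidEffect)
  mu <- log(outer(rep(1, length(samples)), .LIPIDS$base)) +
    log(mult[as.character(cluster), , drop = FALSE])
  vals <- exp(mu + stats::rnorm(length(mu), 0, 0.4))
  dimnames(vals) <- list(samples, .LIPIDS$lipid)
  featureTable(vals, level = "lipid", isRelative = FALSE)
}

.defaultExprMultipliers <- function() {
  rbind(
    # the dominant planted coupling: secondary bile acid biosynthesis is the
    # strongest lipid-linked transcriptional signal in the C3/C4 states
    data.frame(species = "Faecalibacterium_prausnitzii",
               pathway = "Secondary_bile_acid_biosynthesis",
               cluster = c("C3", "C4"), multiplier = c(6, 8)),
    data.frame(species = "Ruminococcus_bromii",
               pathway = "Glycerolipid_metabolism",
               cluster = "C4", multiplier = 4),
    data.frame(species = "Escherichia_coli", pathway = "K00076",
               cluster = c("C2", "C3", "C4"), multiplier = 0),
    data.frame(species = "Anaerostipes_hadrus", pathway = "K01442",
               cluster = "C2", multiplier = 3),
    data.frame(species = "Ruminococcus_bromii", pathway = "K07007",
               cluster = "C3", multiplier = 2),
    # residual low-level transcription (keeps the smallest nonzero ratio,
    # and hence the log2 pseudocount, realistically small)
    data.frame(species = "Faecalibacterium_prausnitzii", pathway = "K07007",
               cluster = "C4", multiplier = 0.1))
}

#' Simulate paired metagenome/metatranscriptome pathway tables
#'
#' DNA-level abundance of a "pathway|species" feature is the species
#' abundance times a fixed species x pathway incidence matrix with mild
#' log-normal noise; RNA-level abundance is DNA times the planted expression
#' multiplier for that (species, pathway, cluster) cell times noise.  The KO
#' panel rides along as gene-family features; by default K00076 is
#' transcribed by E. coli only in cluster C1.  Species-unstratified totals
#' are appended per pathway, and one feature carries RNA without DNA in C1
#' samples to exercise the ratio stage's zero policy.
#'
#' @param config a [synthConfig()].
#' @param truth truth list (cluster labels).
#' @return a [PairedOmics-class] object.
#' @export
simulateTranscriptome <- function(config, truth) {
  layout <- .cohortLayout(config)
  set.seed(config$rngSeed + 6L)
  cluster <- truth$cluster
  samples <- names(cluster)
  n <- length(samples)
  base <- setNames(c(2.5, 1.8, 1.8, 1.6, 1.6, 1.2, 2.0, 1.4, 0.8, 0.8), .SPECIES)
  spMult <- matrix(1, 4, length(.SPECIES), dimnames = list(.CLUSTERS, .SPECIES))
  spMult["C2", "Akkermansia_muciniphila"] <- 0.4
  spMult["C2", "Ruminococcus_bromii"] <- 0.5
  spMult["C4", "Bifidobacterium_adolescentis"] <- 2.5
  spMult["C4", "Eubacterium_rectale"] <- 2
  spMult[c("C3", "C4"), "Faecalibacterium_prausnitzii"] <- 0.6
  spMult["C1", "Anaerostipes_hadrus"] <- 0.3  # subdominant outside C2-C4
  spAbund <- exp(log(outer(rep(1, n), base)) +
                 stats::rnorm(n * length(base), 0, 0.6)) *
    spMult[as.character(cluster), , drop = FALSE]
  dimnames(spAbund) <- list(samples, .SPECIES)

  em <- rbind(if (isTRUE(config$exprDefaults)) .defaultExprMultipliers(),
              config$exprMultipliers)
  if (is.null(em)) em <- data.frame(species = character(0), pathway = character(0),
                                    cluster = character(0), multiplier = numeric(0))
  inc <- layout$incidence
  keys <- character(0); dnaCols <- list(); rnaCols <- list()
  allPaths <- colnames(inc)
  for (p in allPaths) {
    for (s in .SPECIES) {
      if (inc[s, p] == 0) next
      key <- paste0(p, "|", s)
      dna <- spAbund[, s] * exp(stats::rnorm(n, 0, 0.2))
      eMult <- rep(1, n)
      hit <- em$species == s & em$pathway == p
      if (any(hit))
        for (r in which(hit))
          eMult[as.character(cluster) == em$cluster[r]] <- em$multiplier[r]
      rna <- dna * eMult * exp(stats::rnorm(n, 0, config$exprNoiseSd))
      keys <- c(keys, key); dnaCols[[key]] <- dna; rnaCols[[key]] <- rna
    }
  }
  # planted RNA-without-DNA feature (detection-artifact regime, C1 samples)
  key <- "Tryptophan_metabolism|Subdoligranulum_spp"
  dna <- rep(0, n)
  rna <- ifelse(cluster == "C1", exp(stats::rnorm(n, log(0.05), 0.3)), 0)
  keys <- c(keys, key); dnaCols[[key]] <- dna; rnaCols[[key]] <- rna
  dnaM <- do.call(cbind, dnaCols); rnaM <- do.call(cbind, rnaCols)
  dimnames(dnaM) <- dimnames(rnaM) <- list(samples, keys)
  # species-unstratified totals per pathway
  pathOf <- sub("\\|.*$", "", keys)
  totD <- t(rowsum(t(dnaM), pathOf)); totR <- t(rowsum(t(rnaM), pathOf))
  dnaM <- cbind(dnaM, totD); rnaM <- cbind(rnaM, totR)
  pairedOmics(featureTable(rnaM, level = "pathway", isRelative = FALSE),
              featureTable(dnaM, level = "pathway", isRelative = FALSE))
}

#' Generate the full labeled synthetic cohort
#'
#' Runs every generator stage in order, computes the unweighted-UniFrac PCoA
#' that the metadata stage's behavioral slopes are planted on, aggregates
#' the OTU table to genus level, and fills the metadata's nutrient columns
#' from the FFQ.
#'
#' @param config a [synthConfig()].
#' @return list of class `"microtypeCohort"`: `otu`, `genus`, `tree`,
#'   `metadata`, `ffq`, `foodAnnotations`, `lipids`, `paired`, `ordination`,
#'   and `truth` (with planted labels and coefficients).
#' @export
simulateCohort <- function(config) {
  tree <- simulateTree(config)
  ab <- simulateAbundances(config)
  ord <- pcoa(unifrac(ab$table, tree, weighted = FALSE))
  truth <- ab$truth
  truth$pco2 <- ordinationPoints(ord)[, 2L]
  truth$betaUE <- config$betaUE
  truth$betaBITE <- config$betaBITE
  truth$rawBetaUE <- config$betaUE / stats::sd(truth$pco2)
  truth$rawBetaBITE <- config$betaBITE / stats::sd(truth$pco2)
  md <- simulateMetadata(config, truth)
  ffq <- simulateFfq(config, truth)
  truth$diet <- ffq$archetype
  lipids <- simulateLipidome(config, truth)
  paired <- simulateTranscriptome(config, truth)
  nutr <- nutrientSummaries(ffq$ffq, ffq$annotations)
  md$energy_kcal_day <- round(nutr$energy_kcal, 1)
  md$fiber_g_day <- round(nutr$fiber_g, 2)
  md$protein_g <- round(nutr$protein_g, 1)
  md$carb_g <- round(nutr$carb_g, 1)
  md$fat_g <- round(nutr$fat_g, 1)
  structure(list(otu = ab$table, genus = aggregateByTaxonomy(ab$table),
                 tree = tree, metadata = md, ffq = ffq$ffq,
                 foodAnnotations = ffq$annotations, lipids = lipids,
                 paired = paired, ordination = ord, truth = truth,
                 config = config),
            class = "microtypeCohort")
}

#' @export
print.microtypeCohort <- function(x, ...) {
  cat(sprintf("microtypeCohort: %d samples, %d OTUs / %d genera, seed %d\n",
              nrow(abundances(x$otu)), ncol(abundances(x$otu)),
              ncol(abundances(x$genus)), x$config$rngSeed))
  invisible(x)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' @param cohort a cohort from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeFeatureTable(cohort$otu, file.path(dir, "otu_table.tsv"))
  writeTree(cohort$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  writeFeatureTable(cohort$ffq, file.path(dir, "ffq.tsv"))
  utils::write.table(cohort$foodAnnotations, file.path(dir, "food_annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeFeatureTable(cohort$lipids, file.path(dir, "lipids.tsv"))
  writeFeatureTable(cohort$paired@rna, file.path(dir, "rna.tsv"))
  writeFeatureTable(cohort$paired@dna, file.path(dir, "dna.tsv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(cluster = as.list(setNames(as.character(truth$cluster), names(truth$cluster))),
         diet = as.list(setNames(as.character(truth$diet), names(truth$diet))),
         genusBlock = as.list(truth$genusBlock),
         otuGenus = as.list(truth$otuGenus),
         betaUE = truth$betaUE, betaBITE = truth$betaBITE),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
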