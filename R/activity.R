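#' RNA:DNA normalization of paired pathway tables
#'
#' `ratio = RNA / DNA` per ("pathway|species", sample) cell, quantifying
#' expression independent of gene copy number.  Zero policy: DNA = 0 and
#' RNA = 0 is undefined (NA, excluded from aggregation); DNA = 0 with
#' RNA > 0 is also undefined but surfaced in the `rnaOnly` side table, since
#' transcripts without detectable gene copies are a signal worth inspecting.
#' An optional smoothing pseudocount (added to both numerator and
#' denominator) is off by default.
#'
#' @param paired a [PairedOmics-class].
#' @param pseudocount numeric added to RNA and DNA before the ratio
#'   (default 0 = policy above).
#' @return an [ActivityTable-class].
#' @export
rnaDnaNormalize <- function(paired, pseudocount = 0) {
  rna <- abundances(paired@rna); dna <- abundances(paired@dna)
  if (any(rna < 0) || any(dna < 0)) stop("negative abundances")
  if (pseudocount > 0) {
    ratios <- (rna + pseudocount) / (dna + pseudocount)
    rnaOnlyIdx <- which(dna == 0 & rna > 0, arr.ind = TRUE)
  } else {
    ratios <- rna / dna
    ratios[dna == 0] <- NA_real_
    rnaOnlyIdx <- which(dna == 0 & rna > 0, arr.ind = TRUE)
  }
  rnaOnly <- data.frame(
    sample_id = rownames(rna)[rnaOnlyIdx[, 1L]],
    feature = colnames(rna)[rnaOnlyIdx[, 2L]],
    rna = rna[rnaOnlyIdx])
  keys <- colnames(rna)
  hasSpecies <- grepl("|", keys, fixed = TRUE)
  new("ActivityTable", ratios = ratios,
      pathway = sub("\\|.*$", "", keys),
      species = ifelse(hasSpecies, sub("^.*\\|", "", keys), "(total)"),
      rnaOnly = rnaOnly)
}

.clusterFactor <- function(clusters, samples) {
  labels <- if (is(clusters, "ClusterAssignment")) clusterLabels(clusters)
  else factor(clusters)
  labels[samples]
}

#' Per-cluster log2 transcriptional over-abundance
#'
#' `log2((mean ratio in cluster + eps) / (mean ratio in cohort + eps))` per
#' feature, with the pseudocount `eps` set to half the smallest non-zero
#' ratio in the table (applied to both terms so the value is 0 whenever the
#' cluster matches the cohort).  Means are over defined (non-NA) ratios.
#'
#' @param activity an [ActivityTable-class].
#' @param clusters a [ClusterAssignment-class] or named factor.
#' @return numeric matrix, clusters x features.
#' @export
log2Overabundance <- function(activity, clusters) {
  r <- activityRatios(activity)
  labels <- droplevels(.clusterFactor(clusters, rownames(r)))
  nz <- r[!is.na(r) & r > 0]
  eps <- if (length(nz)) min(nz) / 2 else 0.5
  cohort <- colMeans(r, na.rm = TRUE)
  out <- t(vapply(levels(labels), function(cl) {
    mu <- colMeans(r[labels == cl, , drop = FALSE], na.rm = TRUE)
    log2((mu + eps) / (cohort + eps))
  }, numeric(ncol(r))))
  dimnames(out) <- list(levels(labels), colnames(r))
  out
}

#' Default pathway-to-metabolic-category map
#'
#' Static map from the packaged pathway catalogue to the four KEGG-style
#' metabolic categories (carbohydrate, amino acid, lipid, xenobiotic);
#' override by passing your own map to [countActiveSpecies()].
#' @return data.frame with `pathway` and `category`.
#' @export
defaultPathwayCategories <- function() {
  path <- system.file("extdata", "pathway_categories.tsv", package = "microtype")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Count transcriptionally active species per cluster and category
#'
#' A species is "active" in a (cluster, category) cell when its log2
#' over-abundance exceeds 1 (strictly) in at least one third (ceiling) of
#' the pathways comprising that category.  Pathways missing from the
#' category map are ignored; empty categories are skipped with a warning.
#'
#' @param activity an [ActivityTable-class].
#' @param clusters a [ClusterAssignment-class] or named factor.
#' @param categoryMap data.frame (`pathway`, `category`), default
#'   [defaultPathwayCategories()].
#' @param log2Threshold activity threshold (strict).
#' @return data.frame: cluster, category, n_active (spider-plot table),
#'   with the per-species flags in `attr(, "flags")`.
#' @export
countActiveSpecies <- function(activity, clusters,
                               categoryMap = defaultPathwayCategories(),
                               log2Threshold = 1) {
  l2 <- log2Overabundance(activity, clusters)
  species <- activity@species
  pathway <- activity@pathway
  strat <- species != "(total)"
  cats <- unique(categoryMap$category)
  flags <- list()
  rows <- list()
  for (cl in rownames(l2)) {
    for (ca in cats) {
      paths <- categoryMap$pathway[categoryMap$category == ca]
      m <- length(paths)
      if (m == 0L) { warning("empty category: ", ca); next }
      need <- ceiling(m / 3)
      sp <- unique(species[strat])
      active <- vapply(sp, function(s) {
        idx <- strat & species == s & pathway %in% paths
        vals <- l2[cl, idx]
        sum(vals > log2Threshold, na.rm = TRUE) >= need
      }, logical(1))
      flags[[paste(cl, ca, sep = ".")]] <- active
      rows[[length(rows) + 1L]] <- data.frame(cluster = cl, category = ca,
                                              n_active = sum(active))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "flags") <- flags
  out
}

#' KO-panel RNA:DNA ratios per cluster relative to the cohort
#'
#' For each KO gene family in the panel and each species transcribing it,
#' the cluster mean RNA:DNA ratio divided by the cohort mean ratio
#' (heatmap-ready).  Species rows are ordered by Ward clustering on
#' 1 - Spearman correlation of their DNA-normalized transcript profiles.
#' Panel entries absent from the input are reported in
#' `attr(, "missing")`, not fatal.
#'
#' @param paired a [PairedOmics-class].
#' @param clusters a [ClusterAssignment-class] or named factor.
#' @param panel character vector of KO identifiers (default the bile-acid /
#'   neuroactive panel).
#' @return data.frame: ko, species, cluster, ratio_vs_cohort (ordered by
#'   the species clustering).
#' @export
koPanelRatios <- function(paired, clusters, panel = .KO_PANEL) {
  if (!length(panel)) { warning("empty KO panel"); return(data.frame()) }
  act <- rnaDnaNormalize(paired)
  r <- activityRatios(act)
  labels <- droplevels(.clusterFactor(clusters, rownames(r)))
  sel <- act@pathway %in% panel & act@species != "(total)"
  missing <- setdiff(panel, act@pathway)
  r <- r[, sel, drop = FALSE]
  if (!ncol(r)) {
    warning("no panel entries found in the input")
    out <- data.frame()
    attr(out, "missing") <- missing
    return(out)
  }
  cohort <- colMeans(r, na.rm = TRUE)
  ratio <- t(vapply(levels(labels), function(cl)
    colMeans(r[labels == cl, , drop = FALSE], na.rm = TRUE) / cohort,
    numeric(ncol(r))))
  dimnames(ratio) <- list(levels(labels), colnames(r))
  # species ordering by Ward / 1 - Spearman on transcript-ratio profiles
  spOf <- act@species[sel]
  spU <- unique(spOf)
  ordSp <- spU
  if (length(spU) > 2L) {
    prof <- vapply(spU, function(s)
      rowMeans(r[, spOf == s, drop = FALSE], na.rm = TRUE), numeric(nrow(r)))
    prof[is.na(prof)] <- 0
    keep <- apply(prof, 2L, stats::sd) > 0
    if (sum(keep) > 2L) {
      rho <- stats::cor(prof[, keep], method = "spearman")
      hc <- stats::hclust(stats::as.dist(1 - rho), method = "ward.D2")
      ordSp <- c(colnames(prof[, keep, drop = FALSE])[hc$order],
                 spU[!spU %in% colnames(prof)[keep]])
    }
  }
  long <- do.call(rbind, lapply(colnames(ratio), function(key) {
    data.frame(ko = sub("\\|.*$", "", key),
               species = sub("^.*\\|", "", key),
               cluster = rownames(ratio),
               ratio_vs_cohort = ratio[, key])
  }))
  long <- long[order(match(long$species, ordSp), long$ko, long$cluster), ]
  rownames(long) <- NULL
  attr(long, "missing") <- missing
  long
}
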