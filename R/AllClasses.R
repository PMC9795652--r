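#' @import methods
NULL

.LEVELS <- c("otu", "genus", "species", "pathway", "food", "lipid")

#' FeatureTable: samples-by-features abundance matrix
#'
#' The central container of the pipeline: a non-negative numeric matrix with
#' samples in rows and features (OTUs, genera, species, pathways, food items
#' or lipids) in columns, an optional taxonomy lineage per feature, and a flag
#' recording whether values are proportions.  Relative tables must have row
#' sums in (0, 1]; sums strictly below 1 arise legitimately after feature
#' filtering, because proportions are never re-normalized after filtering
#' (retained proportions keep their meaning with respect to the original
#' community).
#'
#' @slot values numeric matrix, samples x features, non-negative, finite.
#' @slot level character scalar, one of `"otu"`, `"genus"`, `"species"`,
#'   `"pathway"`, `"food"`, `"lipid"`.
#' @slot taxonomy named character vector mapping feature ids to lineage
#'   strings (may be empty).
#' @slot isRelative logical scalar; `TRUE` when values are proportions.
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(values = "matrix", level = "character",
                 taxonomy = "character", isRelative = "logical"))

setValidity("FeatureTable", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry sample (row) and feature (column) names")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicated sample ids")
  if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicated feature ids")
  if (any(!is.finite(v))) msg <- c(msg, "non-finite abundance values")
  else if (any(v < 0)) msg <- c(msg, "negative abundance values")
  if (length(object@level) != 1L || !object@level %in% .LEVELS)
    msg <- c(msg, sprintf("level must be one of %s", paste(.LEVELS, collapse = ", ")))
  if (length(object@isRelative) != 1L || is.na(object@isRelative))
    msg <- c(msg, "isRelative must be TRUE or FALSE")
  else if (object@isRelative && nrow(v) > 0L) {
    rs <- rowSums(v)
    if (any(rs <= 0)) msg <- c(msg, "relative table has all-zero sample rows")
    else if (any(rs > 1 + 1e-9))
      msg <- c(msg, "relative table has row sums above 1")
  }
  if (length(object@taxonomy) &&
      !all(names(object@taxonomy) %in% colnames(v)))
    msg <- c(msg, "taxonomy names must be feature ids")
  if (length(msg)) msg else TRUE
})

#' PairedOmics: aligned RNA-level and DNA-level pathway tables
#'
#' Holds HUMAnN2-style stratified pathway abundances ("pathway|species" row
#' keys, stored here as feature columns) measured at the RNA (transcript) and
#' DNA (gene) level on the same samples.  DNA zeros are recorded, never
#' dropped, so the ratio stage can apply its explicit zero policy.
#'
#' @slot rna,dna `FeatureTable` objects at pathway level sharing sample and
#'   feature sets.
#' @exportClass PairedOmics
setClass("PairedOmics", representation(rna = "FeatureTable", dna = "FeatureTable"))

setValidity("PairedOmics", function(object) {
  msg <- character()
  if (!identical(rownames(object@rna@values), rownames(object@dna@values)))
    msg <- c(msg, "rna and dna must share the same samples in the same order")
  if (!identical(colnames(object@rna@values), colnames(object@dna@values)))
    msg <- c(msg, "rna and dna must share the same feature keys in the same order")
  if (length(msg)) msg else TRUE
})

#' ClusterAssignment: community steady-state typing result
#'
#' @slot labels named factor, sample -> cluster label (C1..Ck).
#' @slot k integer, number of clusters cut.
#' @slot tree list holding the full `hclust` object so any k can be re-cut.
#' @slot silhouette named numeric, mean silhouette width per candidate k.
#' @slot validity data.frame of per-cluster within-group diagnostics.
#' @slot manova list with pseudo-F and p from the permutational MANOVA.
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(labels = "factor", k = "integer", tree = "list",
                 silhouette = "numeric", validity = "data.frame",
                 manova = "list"))

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be at least 2")
  if (is.null(names(object@labels))) msg <- c(msg, "labels must be named by sample")
  if (nlevels(droplevels(object@labels)) != object@k)
    msg <- c(msg, "labels must cover exactly k clusters")
  if (length(msg)) msg else TRUE
})

#' OrdinationResult: PCoA coordinates with fitted covariate vectors
#'
#' @slot points numeric matrix, samples x retained (positive-eigenvalue) axes.
#' @slot eig numeric, all eigenvalues in descending order (negatives included).
#' @slot varExplained numeric, per retained axis, share of the positive
#'   eigenvalue sum.
#' @slot vectors data.frame of fitted covariate arrows (direction cosines,
#'   R-squared, permutation p); empty until [envfitVectors()] is run.
#' @exportClass OrdinationResult
setClass("OrdinationResult",
  representation(points = "matrix", eig = "numeric",
                 varExplained = "numeric", vectors = "data.frame"))

setValidity("OrdinationResult", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@eig))) msg <- c(msg, "eigenvalues must be in descending order")
  if (ncol(object@points) > sum(object@eig > 0))
    msg <- c(msg, "coordinates may only span positive-eigenvalue axes")
  if (length(msg)) msg else TRUE
})

#' CagPartition: genus co-abundance groups with network statistics
#'
#' @slot membership named character, genus -> CAG id.
#' @slot cagNames named character, CAG id -> dominant-genus display name.
#' @slot edges data.frame of retained network edges (genus pair, Kendall
#'   tau-b, p, q); only tau > 0 and q <= alpha edges are stored.
#' @slot discSizes numeric matrix, genus x cluster over-abundance ratios
#'   (cluster mean relative abundance over cohort mean); empty until
#'   [wiggumStats()] is run.
#' @exportClass CagPartition
setClass("CagPartition",
  representation(membership = "character", cagNames = "character",
                 edges = "data.frame", discSizes = "matrix"))

setValidity("CagPartition", function(object) {
  msg <- character()
  if (is.null(names(object@membership))) msg <- c(msg, "membership must be named by genus")
  if (!all(object@membership %in% names(object@cagNames)))
    msg <- c(msg, "every CAG id must have a name")
  if (nrow(object@edges)) {
    if (any(object@edges$tau <= 0)) msg <- c(msg, "stored edges must have tau > 0")
  }
  if (length(object@discSizes) && any(object@discSizes < 0, na.rm = TRUE))
    msg <- c(msg, "disc sizes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ActivityTable: DNA-normalized transcription measures
#'
#' Per-sample RNA:DNA ratios for "pathway|species" features.  Features where
#' DNA = 0 but RNA > 0 carry an undefined ratio (NA) and are additionally
#' surfaced in the `rnaOnly` side table; DNA = 0 and RNA = 0 is undefined and
#' excluded from aggregation.
#'
#' @slot ratios numeric matrix, samples x features, RNA:DNA ratios (NA where
#'   undefined).
#' @slot pathway,species character vectors parallel to the feature columns.
#' @slot rnaOnly data.frame listing (sample, feature) cells with RNA > 0 but
#'   DNA = 0.
#' @exportClass ActivityTable
setClass("ActivityTable",
  representation(ratios = "matrix", pathway = "character",
                 species = "character", rnaOnly = "data.frame"))

setValidity("ActivityTable", function(object) {
  msg <- character()
  if (length(object@pathway) != ncol(object@ratios) ||
      length(object@species) != ncol(object@ratios))
    msg <- c(msg, "pathway/species annotations must match feature columns")
  if (any(object@ratios < 0, na.rm = TRUE)) msg <- c(msg, "ratios must be >= 0 or NA")
  if (length(msg)) msg else TRUE
})

#' SplsModel: sparse partial least squares fit
#'
#' @slot Xloadings,Yloadings numeric matrices (features x components) of
#'   unit-norm loading vectors; X loadings carry the sparsity pattern.
#' @slot Xscores,Yscores numeric matrices (samples x components).
#' @slot keepX integer vector, number of X features retained per component.
#' @slot explainedCov numeric, covariance of the score pair per component.
#' @exportClass SplsModel
setClass("SplsModel",
  representation(Xloadings = "matrix", Yloadings = "matrix",
                 Xscores = "matrix", Yscores = "matrix",
                 keepX = "integer", explainedCov = "numeric"))

setValidity("SplsModel", function(object) {
  msg <- character()
  nz <- colSums(object@Xloadings != 0)
  if (any(nz > object@keepX)) msg <- c(msg, "X loading sparsity exceeds keepX")
  nrm <- sqrt(colSums(object@Xloadings^2))
  if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "X loadings must be unit-norm")
  if (length(msg)) msg else TRUE
})

#' DietAssignment: dietary groups from correspondence analysis
#'
#' @slot groups named factor, sample -> dietary group (D1..Dk, ordered by
#'   group mean axis-1 score).
#' @slot axisScores named numeric, per-sample principal coordinate on CA
#'   axis 1.
#' @slot inertia numeric, per-axis share of total inertia.
#' @slot hfd named numeric, per-sample Healthy Food Diversity index (empty
#'   until computed).
#' @exportClass DietAssignment
setClass("DietAssignment",
  representation(groups = "factor", axisScores = "numeric",
                 inertia = "numeric", hfd = "numeric"))

setValidity("DietAssignment", function(object) {
  msg <- character()
  if (!identical(names(object@groups), names(object@axisScores)))
    msg <- c(msg, "groups and axisScores must cover the same samples")
  if (any(!is.finite(object@axisScores))) msg <- c(msg, "axis scores must be finite")
  if (length(msg)) msg else TRUE
})
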