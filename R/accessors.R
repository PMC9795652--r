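#' Accessors for ClusterAssignment
#' @param x a [ClusterAssignment-class].
#' @name ClusterAssignment-accessors
NULL

#' @rdname ClusterAssignment-accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname ClusterAssignment-accessors
#' @export
setMethod("clusterK", "ClusterAssignment", function(x) x@k)

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d samples in %d clusters (%s)\n",
              length(object@labels), object@k,
              paste(sprintf("%s=%d", levels(object@labels),
                            tabulate(object@labels)), collapse = ", ")))
  if (length(object@silhouette))
    cat(sprintf("  mean silhouette at k=%d: %.3f\n", object@k,
                object@silhouette[[as.character(object@k)]]))
  if (length(object@manova))
    cat(sprintf("  PERMANOVA pseudo-F = %.3f, p = %.4g\n",
                object@manova$pseudoF, object@manova$p))
})

#' Accessors for OrdinationResult
#' @param x an [OrdinationResult-class].
#' @name OrdinationResult-accessors
NULL

#' @rdname OrdinationResult-accessors
#' @export
setMethod("ordinationPoints", "OrdinationResult", function(x) x@points)

#' @rdname OrdinationResult-accessors
#' @export
setMethod("eigenvalues", "OrdinationResult", function(x) x@eig)

#' @rdname OrdinationResult-accessors
#' @export
setMethod("fittedVectors", "OrdinationResult", function(x) x@vectors)

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult: %d samples, %d retained axes\n",
              nrow(object@points), ncol(object@points)))
  ve <- utils::head(object@varExplained, 3)
  cat("  variance explained:",
      paste(sprintf("PCo%d %.1f%%", seq_along(ve), 100 * ve), collapse = ", "), "\n")
  if (any(object@eig < 0))
    cat(sprintf("  %d negative eigenvalues reported (axes excluded)\n",
                sum(object@eig < 0)))
  if (nrow(object@vectors))
    cat(sprintf("  %d fitted covariate vectors\n", nrow(object@vectors)))
})

#' Accessors for CagPartition
#' @param x a [CagPartition-class].
#' @name CagPartition-accessors
NULL

#' @rdname CagPartition-accessors
#' @export
setMethod("cagMembership", "CagPartition", function(x) x@membership)

#' @rdname CagPartition-accessors
#' @export
setMethod("cagNames", "CagPartition", function(x) x@cagNames)

#' @rdname CagPartition-accessors
#' @export
setMethod("cagEdges", "CagPartition", function(x) x@edges)

#' @rdname CagPartition-accessors
#' @export
setMethod("discSizes", "CagPartition", function(x) x@discSizes)

setMethod("show", "CagPartition", function(object) {
  cat(sprintf("CagPartition: %d genera in %d CAGs (%s)\n",
              length(object@membership), length(object@cagNames),
              paste(object@cagNames, collapse = ", ")))
  cat(sprintf("  %d retained edges (tau > 0, q <= alpha)\n", nrow(object@edges)))
  if (length(object@discSizes))
    cat(sprintf("  disc sizes for %d clusters\n", ncol(object@discSizes)))
})

#' Accessors for ActivityTable
#' @param x an [ActivityTable-class].
#' @name ActivityTable-accessors
NULL

#' @rdname ActivityTable-accessors
#' @export
setMethod("activityRatios", "ActivityTable", function(x) x@ratios)

#' @rdname ActivityTable-accessors
#' @export
setMethod("rnaOnly", "ActivityTable", function(x) x@rnaOnly)

setMethod("show", "ActivityTable", function(object) {
  cat(sprintf("ActivityTable: %d samples x %d pathway|species features\n",
              nrow(object@ratios), ncol(object@ratios)))
  cat(sprintf("  %d RNA-only cells (DNA = 0, RNA > 0) side-tabled\n",
              nrow(object@rnaOnly)))
})

#' Accessors for SplsModel
#' @param x an [SplsModel-class].
#' @param block `"X"` or `"Y"`.
#' @name SplsModel-accessors
NULL

#' @rdname SplsModel-accessors
#' @export
setMethod("splsLoadings", "SplsModel", function(x, block = c("X", "Y")) {
  if (match.arg(block) == "X") x@Xloadings else x@Yloadings
})

#' @rdname SplsModel-accessors
#' @export
setMethod("splsScores", "SplsModel", function(x, block = c("X", "Y")) {
  if (match.arg(block) == "X") x@Xscores else x@Yscores
})

setMethod("show", "SplsModel", function(object) {
  cat(sprintf("SplsModel: %d components, %d X features (keepX: %s), %d Y features\n",
              ncol(object@Xloadings), nrow(object@Xloadings),
              paste(object@keepX, collapse = "/"), nrow(object@Yloadings)))
  cat("  explained covariance:", paste(signif(object@explainedCov, 4), collapse = ", "), "\n")
})

#' Accessors for DietAssignment
#' @param x a [DietAssignment-class].
#' @name DietAssignment-accessors
NULL

#' @rdname DietAssignment-accessors
#' @export
setMethod("dietGroups", "DietAssignment", function(x) x@groups)

#' @rdname DietAssignment-accessors
#' @export
setMethod("axisScores", "DietAssignment", function(x) x@axisScores)

setMethod("show", "DietAssignment", function(object) {
  cat(sprintf("DietAssignment: %d samples in %d dietary groups (%s)\n",
              length(object@groups), nlevels(object@groups),
              paste(sprintf("%s=%d", levels(object@groups),
                            tabulate(object@groups)), collapse = ", ")))
  cat(sprintf("  CA axis 1 inertia share: %.1f%%\n", 100 * object@inertia[1]))
})
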