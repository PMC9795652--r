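#' @rdname FeatureTable-accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("isRelative", function(x) standardGeneric("isRelative"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("abundanceLevel", function(x) standardGeneric("abundanceLevel"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' @rdname ClusterAssignment-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterAssignment-accessors
#' @export
setGeneric("clusterK", function(x) standardGeneric("clusterK"))

#' @rdname OrdinationResult-accessors
#' @export
setGeneric("ordinationPoints", function(x) standardGeneric("ordinationPoints"))

#' @rdname OrdinationResult-accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname OrdinationResult-accessors
#' @export
setGeneric("fittedVectors", function(x) standardGeneric("fittedVectors"))

#' @rdname CagPartition-accessors
#' @export
setGeneric("cagMembership", function(x) standardGeneric("cagMembership"))

#' @rdname CagPartition-accessors
#' @export
setGeneric("cagNames", function(x) standardGeneric("cagNames"))

#' @rdname CagPartition-accessors
#' @export
setGeneric("cagEdges", function(x) standardGeneric("cagEdges"))

#' @rdname CagPartition-accessors
#' @export
setGeneric("discSizes", function(x) standardGeneric("discSizes"))

#' @rdname ActivityTable-accessors
#' @export
setGeneric("activityRatios", function(x) standardGeneric("activityRatios"))

#' @rdname ActivityTable-accessors
#' @export
setGeneric("rnaOnly", function(x) standardGeneric("rnaOnly"))

#' @rdname SplsModel-accessors
#' @export
setGeneric("splsLoadings", function(x, block = c("X", "Y")) standardGeneric("splsLoadings"))

#' @rdname SplsModel-accessors
#' @export
setGeneric("splsScores", function(x, block = c("X", "Y")) standardGeneric("splsScores"))

#' @rdname DietAssignment-accessors
#' @export
setGeneric("dietGroups", function(x) standardGeneric("dietGroups"))

#' @rdname DietAssignment-accessors
#' @export
setGeneric("axisScores", function(x) standardGeneric("axisScores"))
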