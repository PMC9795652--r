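#' Construct a FeatureTable
#'
#' @param values numeric matrix, samples in rows and features in columns,
#'   with dimnames.  A data.frame of numeric columns is accepted and coerced.
#' @param level feature level, one of `"otu"`, `"genus"`, `"species"`,
#'   `"pathway"`, `"food"`, `"lipid"`.
#' @param taxonomy optional named character vector of lineage strings.
#' @param isRelative logical or `NA`; when `NA` (default) the table is
#'   declared relative if every sample row sums to 1 within `1e-9`.
#'
#' @return A [FeatureTable-class] object.
#' @examples
#' m <- matrix(c(5, 0, 3, 2, 1, 9), nrow = 2,
#'             dimnames = list(c("S1", "S2"), c("otuA", "otuB", "otuC")))
#' ft <- featureTable(m, "otu")
#' isRelative(ft)
#' @export
featureTable <- function(values, level, taxonomy = NULL, isRelative = NA) {
  if (is.data.frame(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.na(isRelative)) {
    rs <- rowSums(values)
    isRelative <- nrow(values) > 0L && all(abs(rs - 1) <= 1e-9)
  }
  if (is.null(taxonomy)) taxonomy <- setNames(character(0), character(0))
  new("FeatureTable", values = values, level = level,
      taxonomy = taxonomy, isRelative = isRelative)
}

#' Accessors for FeatureTable
#'
#' `sampleNames`/`featureNames` return the row/column identifiers,
#' `abundances` the raw matrix, `relAbundance` the row-normalized proportion
#' matrix (a no-op copy when the table already holds proportions summing
#' to 1).
#'
#' @param x a [FeatureTable-class].
#' @name FeatureTable-accessors
NULL

#' @rdname FeatureTable-accessors
#' @export
setMethod("sampleNames", "FeatureTable", function(x) rownames(x@values))

#' @rdname FeatureTable-accessors
#' @export
setMethod("featureNames", "FeatureTable", function(x) colnames(x@values))

#' @rdname FeatureTable-accessors
#' @export
setMethod("abundances", "FeatureTable", function(x) x@values)

#' @rdname FeatureTable-accessors
#' @export
setMethod("taxonomy", "FeatureTable", function(x) x@taxonomy)

#' @rdname FeatureTable-accessors
#' @export
setMethod("isRelative", "FeatureTable", function(x) x@isRelative)

#' @rdname FeatureTable-accessors
#' @export
setMethod("abundanceLevel", "FeatureTable", function(x) x@level)

#' @rdname FeatureTable-accessors
#' @export
setMethod("relAbundance", "FeatureTable", function(x) {
  rs <- rowSums(x@values)
  if (any(rs <= 0)) stop("cannot normalize all-zero sample rows: ",
                         paste(rownames(x@values)[rs <= 0], collapse = ", "))
  sweep(x@values, 1L, rs, "/")
})

#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))

#' Subset a FeatureTable by samples (i) and/or features (j)
#'
#' Subsetting never re-normalizes proportions; a relative table whose
#' features are subset keeps `isRelative = TRUE` with row sums possibly
#' below 1 (see [FeatureTable-class]).
#' @param x a [FeatureTable-class].
#' @param i,j sample and feature indices (any form `[` accepts).
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values[i, j, drop = FALSE]
  tax <- x@taxonomy[names(x@taxonomy) %in% colnames(v)]
  rel <- x@isRelative && all(rowSums(v) > 0)
  new("FeatureTable", values = v, level = x@level, taxonomy = tax,
      isRelative = rel)
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d samples x %d features [%s, %s]\n",
              nrow(object@values), ncol(object@values), object@level,
              if (object@isRelative) "relative" else "counts"))
  if (length(object@taxonomy))
    cat(sprintf("  taxonomy for %d features\n", length(object@taxonomy)))
})

setMethod("show", "PairedOmics", function(object) {
  cat(sprintf("PairedOmics: %d samples x %d pathway|species features (RNA + DNA)\n",
              nrow(object@rna@values), ncol(object@rna@values)))
})

#' Construct a PairedOmics object
#'
#' @param rna,dna [FeatureTable-class] objects at pathway level with
#'   identical "pathway|species" feature keys and identical samples.
#' @return A [PairedOmics-class] object.
#' @export
pairedOmics <- function(rna, dna) {
  if (!setequal(rownames(rna@values), rownames(dna@values)))
    stop("rna and dna sample sets differ: ",
         paste(union(setdiff(sampleNames(rna), sampleNames(dna)),
                     setdiff(sampleNames(dna), sampleNames(rna))), collapse = ", "))
  if (!setequal(colnames(rna@values), colnames(dna@values)))
    stop("rna and dna feature key sets differ")
  dna <- dna[sampleNames(rna), featureNames(rna)]
  new("PairedOmics", rna = rna, dna = dna)
}
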