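#' Read a feature table from TSV
#'
#' Reads a QIIME-classic style table: features in rows, samples in columns,
#' first column holding feature ids, optionally a final non-numeric
#' `taxonomy` column.  The matrix is transposed to the in-memory orientation
#' (samples in rows).  Counts versus proportions are detected from row sums
#' unless all values are integers; see [featureTable()].
#'
#' @param path path to a tab-separated file.
#' @param level feature level tag (see [FeatureTable-class]).
#' @return A [FeatureTable-class].
#' @export
readFeatureTable <- function(path, level) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("malformed feature table header in ", path,
         ": need a feature-id column plus at least one sample column")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated feature id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  taxcol <- NULL
  dat <- raw[, -1L, drop = FALSE]
  if (tolower(names(dat)[ncol(dat)]) %in% c("taxonomy", "lineage")) {
    taxcol <- setNames(as.character(dat[[ncol(dat)]]), ids)
    dat <- dat[, -ncol(dat), drop = FALSE]
  }
  bad <- !vapply(dat, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric sample column(s) in ", path, ": ",
         paste(names(dat)[bad], collapse = ", "))
  m <- as.matrix(dat)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at feature '%s', sample '%s' in %s",
                 ids[neg[1, 1]], colnames(m)[neg[1, 2]], path))
  rownames(m) <- ids
  featureTable(t(m), level = level, taxonomy = taxcol)
}

#' Write a feature table to TSV (features in rows, samples in columns)
#'
#' @param x a [FeatureTable-class].
#' @param path output path.
#' @export
writeFeatureTable <- function(x, path) {
  m <- t(abundances(x))
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  if (length(taxonomy(x)))
    df$taxonomy <- unname(taxonomy(x)[rownames(m)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from newick
#'
#' Parenthesis balance is checked up front so an unbalanced string is
#' reported with its character offset; parsing is then delegated to
#' [ape::read.tree()].  Missing branch lengths are set to 0 with a warning.
#'
#' @param path path to a newick file.
#' @return An [ape::phylo] tree.
#' @export
readTree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' in newick at offset ", i)
    }
  }
  if (depth > 0L)
    stop("unbalanced '(' in newick: ", depth,
         " unclosed at end of string (length ", nchar(txt), ")")
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (is.null(tree$edge.length)) {
    warning("newick has no branch lengths; setting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths in ", path)
  tree
}

#' Write a tree to newick
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' Missing values stay `NA`; nothing is imputed.  `weight_group` is kept as a
#' factor with levels NW/OB and `yfas_diagnosis` as logical.
#'
#' @param path path to a CSV with a `sample_id` column.
#' @return data.frame with rownames set to sample ids.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) stop("metadata must have a sample_id column")
  if (anyDuplicated(md$sample_id)) stop("duplicated sample ids in metadata")
  rownames(md) <- md$sample_id
  if ("weight_group" %in% names(md))
    md$weight_group <- factor(md$weight_group, levels = c("NW", "OB"))
  if ("yfas_diagnosis" %in% names(md))
    md$yfas_diagnosis <- as.logical(md$yfas_diagnosis)
  validateMetadata(md)
  md
}

validateMetadata <- function(md) {
  if (all(c("yfas_symptoms", "yfas_diagnosis") %in% names(md))) {
    bad <- !is.na(md$yfas_diagnosis) & md$yfas_diagnosis &
      !is.na(md$yfas_symptoms) & md$yfas_symptoms < 3
    if (any(bad))
      stop("YFAS diagnosis with fewer than 3 symptoms violates the instrument: ",
           paste(rownames(md)[bad], collapse = ", "))
    if (any(md$yfas_symptoms < 0, na.rm = TRUE))
      stop("negative YFAS symptom counts")
  }
  invisible(md)
}

#' Write a CAG network to GraphML
#'
#' Nodes are genera with CAG membership, CAG display name and (when
#' available) per-cluster disc sizes as attributes; edges carry Kendall
#' tau-b and q-values.
#'
#' @param partition a [CagPartition-class].
#' @param path output path.
#' @export
writeCagGraphML <- function(partition, path) {
  g <- cagGraph(partition)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Build the igraph object for a CAG network
#' @param partition a [CagPartition-class].
#' @return an [igraph::igraph] graph.
#' @export
cagGraph <- function(partition) {
  genera <- names(cagMembership(partition))
  ed <- cagEdges(partition)
  g <- igraph::graph_from_data_frame(
    ed[, c("genus1", "genus2")], directed = FALSE,
    vertices = data.frame(name = genera,
                          cag = unname(cagMembership(partition)),
                          cag_name = unname(cagNames(partition)[cagMembership(partition)])))
  if (nrow(ed)) {
    igraph::E(g)$tau <- ed$tau
    igraph::E(g)$q <- ed$q
  }
  ds <- discSizes(partition)
  if (length(ds))
    for (cl in colnames(ds))
      g <- igraph::set_vertex_attr(g, paste0("disc_", cl),
                                   value = ds[genera, cl])
  g
}
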