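#' UniFrac distances between samples
#'
#' Phylogenetic beta diversity over a rooted tree.  Unweighted UniFrac is
#' the fraction of observed branch length unique to one of the two
#' communities; weighted UniFrac weights each branch by the absolute
#' difference of its subtree proportion sums (normalized variant by
#' default).  Computation is delegated to [phyloseq::UniFrac()] behind this
#' surface.
#'
#' @param table a [FeatureTable-class] whose features are tree leaves.
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param weighted abundance-weighted variant.
#' @param normalized normalize the weighted variant to \[0, 1\].
#' @return square symmetric distance matrix.
#' @export
unifrac <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  m <- abundances(table)
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    stop("feature(s) missing from the tree: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  if (!ape::is.rooted(tree))  # root deterministically rather than at random
    tree <- ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(m, taxa_are_rows = FALSE),
                           phyloseq::phy_tree(tree))
  d <- phyloseq::UniFrac(ps, weighted = weighted,
                         normalized = normalized, parallel = FALSE)
  as.matrix(d)[rownames(m), rownames(m)]
}

#' Principal coordinates analysis
#'
#' Gower double-centering and eigendecomposition of a distance matrix;
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalue.  Negative eigenvalues (non-Euclidean input) are reported in
#' the eigenvalue vector but their axes are excluded from the coordinates;
#' no Cailliez/Lingoes correction is applied unless requested.  Axis signs
#' are fixed so each axis's largest-magnitude coordinate is positive.
#'
#' @param dist square symmetric distance matrix with zero diagonal.
#' @param correction `"none"` or `"cailliez"`.
#' @return an [OrdinationResult-class].
#' @export
pcoa <- function(dist, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (correction == "cailliez" && any(d > 0)) {
    # Cailliez constant: add c to off-diagonal distances to make them Euclidean
    center <- function(A) {
      A <- sweep(A, 1L, rowMeans(A)); sweep(A, 2L, colMeans(A))
    }
    n <- nrow(d)
    D1 <- center(-0.5 * d^2); D2 <- center(-0.5 * d)
    Z <- matrix(0, n, n)
    M <- rbind(cbind(Z, 2 * D1), cbind(-diag(n), -4 * D2))
    cc <- max(Re(eigen(M, only.values = TRUE)$values))
    if (cc > 0) d <- d + cc * (1 - diag(n))
  }
  B <- -0.5 * d^2
  B <- sweep(B, 1L, rowMeans(B))
  B <- sweep(B, 2L, colMeans(B))
  ee <- eigen(B, symmetric = TRUE)
  eig <- ee$values
  tol <- 1e-9 * max(abs(eig), 1)
  pos <- which(eig > tol)
  pts <- ee$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig[pos]), length(pos))
  # deterministic sign convention
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  dimnames(pts) <- list(rownames(d), paste0("PCo", seq_len(ncol(pts))))
  new("OrdinationResult", points = pts, eig = eig,
      varExplained = eig[pos] / sum(eig[pos]),
      vectors = data.frame())
}

#' Fit covariate vectors onto ordination axes
#'
#' Least-squares superimposition of each covariate onto the first two (by
#' default) ordination axes, with direction cosines, R-squared, and a
#' permutation p-value obtained by shuffling the covariate across samples
#' (seeded; delegated to [vegan::envfit()]).  Constant covariates are
#' flagged and skipped.  All fits are retained; `significant` marks the
#' display list at the given alpha.
#'
#' @param ord an [OrdinationResult-class].
#' @param covariates numeric data.frame/matrix (samples x covariates) or a
#'   food-level [FeatureTable-class].
#' @param nPerm permutations.
#' @param seed RNG seed.
#' @param axes which axes to fit on (default 1:2).
#' @param alpha significance level for the display filter.
#' @return the ordination with its `vectors` slot filled (covariate, axis
#'   direction cosines, r2, p, significant).
#' @export
envfitVectors <- function(ord, covariates, nPerm = 999L, seed = 1L,
                          axes = 1:2, alpha = 0.05) {
  if (is(covariates, "FeatureTable")) covariates <- abundances(covariates)
  covariates <- as.data.frame(covariates)
  pts <- ordinationPoints(ord)
  if (ncol(pts) < max(axes)) stop("ordination has fewer axes than requested")
  covariates <- covariates[rownames(pts), , drop = FALSE]
  keep <- vapply(covariates, function(x) stats::sd(x, na.rm = TRUE) > 0, logical(1))
  skipped <- names(covariates)[!keep]
  if (length(skipped))
    warning("constant covariate(s) skipped: ", paste(skipped, collapse = ", "))
  covariates <- covariates[, keep, drop = FALSE]
  if (!ncol(covariates)) stop("no non-constant covariates to fit")
  set.seed(seed)
  ef <- vegan::envfit(pts[, axes, drop = FALSE], covariates,
                      permutations = nPerm, na.rm = TRUE)
  arr <- ef$vectors$arrows
  res <- data.frame(covariate = rownames(arr),
                    dx = arr[, 1L], dy = arr[, 2L],
                    r2 = ef$vectors$r, p = ef$vectors$pvals,
                    row.names = NULL)
  res$significant <- res$p <= alpha
  methods::initialize(ord, vectors = res)
}
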