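#' Prevalence filter for OTU tables
#'
#' Keeps features present (abundance > 0) in at least `threshold` of the
#' samples; the boundary is inclusive (an OTU in exactly 20% of samples
#' survives the default filter).  Proportions are, by default, NOT
#' re-normalized afterwards, so retained values keep their meaning as
#' proportions of the original community.
#'
#' @param table a [FeatureTable-class].
#' @param threshold prevalence fraction in \[0, 1\].
#' @param renormalize re-normalize rows after filtering (default `FALSE`).
#' @return filtered [FeatureTable-class].
#' @export
prevalenceFilter <- function(table, threshold = 0.20, renormalize = FALSE) {
  m <- abundances(table)
  keep <- colMeans(m > 0) >= threshold
  if (!any(keep))
    stop("prevalence filter removed every feature; lower the threshold (",
         threshold, ")")
  out <- table[, which(keep)]
  if (renormalize && isRelative(table)) {
    v <- abundances(out)
    out <- featureTable(v / rowSums(v), level = abundanceLevel(table),
                        taxonomy = taxonomy(out), isRelative = TRUE)
  }
  out
}

#' Sample-by-sample Spearman correlation matrix
#'
#' Spearman correlation of feature profiles between every pair of samples
#' (average ranks on ties).  Rank correlations are invariant to per-sample
#' scaling, so counts and proportions give identical results.
#'
#' @param table a [FeatureTable-class] with at least 3 features.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(table) {
  m <- abundances(table)
  if (ncol(m) < 3L) stop("need at least 3 features for sample correlations")
  flat <- apply(m, 1L, function(x) length(unique(x)) == 1L)
  if (any(flat))
    stop("constant feature profile, correlation undefined for sample(s): ",
         paste(rownames(m)[flat], collapse = ", "))
  rho <- stats::cor(t(m), method = "spearman")
  diag(rho) <- 1
  rho
}

#' Ward clustering of samples on 1 - Spearman correlation
#'
#' Hierarchical Ward linkage on the correlation-to-dissimilarity map
#' `d = 1 - rho`.  With `k = "auto"` the cut maximizing the mean silhouette
#' width on `d` over `2..kMax` is chosen; the full tree is kept so any k can
#' be re-cut.  Cluster labels C1..Ck follow order of first appearance in the
#' sample ordering.
#'
#' @param corr sample correlation matrix (e.g. from [spearmanMatrix()]).
#' @param k integer number of clusters or `"auto"`.
#' @param kMax largest k tried under `"auto"`.
#' @return a [ClusterAssignment-class].
#' @export
wardClusterSamples <- function(corr, k = "auto", kMax = 8L) {
  n <- nrow(corr)
  d <- stats::as.dist(1 - corr)
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- numeric(0)
  if (identical(k, "auto")) {
    ks <- 2:min(kMax, n - 1L)
    sil <- vapply(ks, function(kk) {
      cl <- stats::cutree(hc, kk)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    names(sil) <- ks
    k <- ks[which.max(sil)]
  }
  k <- as.integer(k)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  cl <- stats::cutree(hc, k)
  # relabel C1..Ck by order of first appearance
  first <- order(match(unique(cl[hc$order]), cl[hc$order]))
  map <- setNames(paste0("C", seq_len(k)), unique(cl[hc$order]))
  labels <- factor(map[as.character(cl)], levels = paste0("C", seq_len(k)))
  names(labels) <- rownames(corr)
  new("ClusterAssignment", labels = labels, k = k,
      tree = list(hclust = hc), silhouette = sil,
      validity = data.frame(), manova = list())
}

#' Within-cluster Benjamini-Hochberg validation
#'
#' Tests every within-cluster sample pair for positive Spearman correlation
#' of feature profiles, adjusts p-values by BH jointly across all
#' within-cluster pairs, and flags a cluster valid when at least
#' `pairFraction` of its pairs have adjusted p <= alpha with rho > 0.
#' Singleton clusters are flagged and excluded from testing.
#'
#' @param table the [FeatureTable-class] the clustering was computed on.
#' @param assignment a [ClusterAssignment-class].
#' @param alpha BH significance level.
#' @param pairFraction required fraction of significant pairs.
#' @return the assignment with its `validity` slot filled (data.frame:
#'   cluster, n, n_pairs, frac_significant, valid).
#' @export
validateClustersBH <- function(table, assignment, alpha = 0.05,
                               pairFraction = 0.95) {
  m <- abundances(table)
  labels <- clusterLabels(assignment)
  pairs <- list()
  for (cl in levels(labels)) {
    ss <- names(labels)[labels == cl]
    if (length(ss) < 2L) next
    idx <- utils::combn(ss, 2L)
    for (j in seq_len(ncol(idx)))
      pairs[[length(pairs) + 1L]] <- c(cl, idx[1L, j], idx[2L, j])
  }
  if (!length(pairs)) stop("no cluster has 2 or more members")
  pm <- do.call(rbind, pairs)
  rho <- numeric(nrow(pm)); pval <- numeric(nrow(pm))
  for (i in seq_len(nrow(pm))) {
    ct <- stats::cor.test(m[pm[i, 2L], ], m[pm[i, 3L], ],
                          method = "spearman", exact = FALSE)
    rho[i] <- unname(ct$estimate); pval[i] <- ct$p.value
  }
  padj <- stats::p.adjust(pval, method = "BH")
  sig <- padj <= alpha & rho > 0
  res <- do.call(rbind, lapply(levels(labels), function(cl) {
    n <- sum(labels == cl)
    inCl <- pm[, 1L] == cl
    frac <- if (any(inCl)) mean(sig[inCl]) else NA_real_
    data.frame(cluster = cl, n = n, n_pairs = sum(inCl),
               frac_significant = frac,
               valid = !is.na(frac) && frac >= pairFraction)
  }))
  methods::initialize(assignment, validity = res)
}

#' Permutational MANOVA (Anderson pseudo-F)
#'
#' Partitions squared inter-point distances: `SS_T = sum_{i<j} d_ij^2 / n`,
#' `SS_W` analogously within groups, `F = (SS_A / (a - 1)) / (SS_W /
#' (n - a))`, and permutes group labels (seeded) to obtain
#' `p = (1 + #(F_perm >= F_obs)) / (1 + nPerm)`.  A degenerate grouping with
#' zero within-group distance gives an infinite pseudo-F; permutations
#' reproducing such a grouping count as ties.
#'
#' @param dist square symmetric distance matrix (or `dist`).
#' @param labels group labels (>= 2 groups with >= 2 members each).
#' @param nPerm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return list with `pseudoF`, `p`, `R2`, `nPerm`.
#' @export
permanova <- function(dist, labels, nPerm = 999L, seed = 1L) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L)
    stop("permutational MANOVA needs at least 2 groups")
  if (any(table(labels) < 2L))
    stop("every group needs at least 2 members")
  D2 <- d^2
  n <- nrow(D2)
  a <- nlevels(labels)
  ssT <- sum(D2) / (2 * n)
  ssW <- function(f) {
    s <- 0
    for (g in levels(f)) {
      idx <- f == g
      s <- s + sum(D2[idx, idx]) / (2 * sum(idx))
    }
    s
  }
  w <- ssW(labels)
  fStat <- function(w) if (w <= 0) Inf else ((ssT - w) / (a - 1)) / (w / (n - a))
  fObs <- fStat(w)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(nPerm)) {
    fp <- fStat(ssW(labels[sample.int(n)]))
    if (fp >= fObs) hits <- hits + 1L
  }
  list(pseudoF = fObs, p = (1 + hits) / (1 + nPerm),
       R2 = (ssT - w) / ssT, nPerm = as.integer(nPerm))
}

#' Alpha diversity: Shannon index and observed features
#'
#' Shannon entropy `H = -sum p_i log_base(p_i)` over the per-sample
#' proportion vector (base 2 by default, i.e. bits) and the count of
#' features with non-zero abundance.
#'
#' @param table a [FeatureTable-class] (counts or proportions).
#' @param base logarithm base.
#' @return data.frame with `shannon` and `observed`, one row per sample.
#' @export
alphaDiversity <- function(table, base = 2) {
  m <- abundances(table)
  rs <- rowSums(m)
  if (any(rs <= 0))
    stop("all-zero sample(s): ", paste(rownames(m)[rs <= 0], collapse = ", "))
  p <- m / rs
  h <- apply(p, 1L, function(x) {
    x <- x[x > 0]
    -sum(x * log(x, base = base))
  })
  data.frame(sample_id = rownames(m), shannon = h,
             observed = rowSums(m > 0), row.names = rownames(m))
}

#' Kruskal-Wallis omnibus with pairwise Wilcoxon post-hoc
#'
#' Tie-corrected Kruskal-Wallis across groups, followed (when
#' `pairwisePosthoc`) by two-sided Wilcoxon rank-sum tests for every pair,
#' BH-adjusted across pairs.  Wilcoxon is exact for small tie-free samples
#' and uses the normal approximation with continuity correction otherwise
#' (the [stats::wilcox.test()] policy).
#'
#' @param values numeric vector of per-sample measurements.
#' @param groups group labels aligned with `values`.
#' @param pairwisePosthoc run the pairwise layer.
#' @return list with `omnibus` (statistic, df, p), `groups` (n and median
#'   per group), and `pairwise` (data.frame with p and p_adj), class
#'   `"groupCompare"`.
#' @export
groupCompare <- function(values, groups, pairwisePosthoc = TRUE) {
  groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  if (any(table(groups) == 0L)) stop("empty group")
  kw <- stats::kruskal.test(values, groups)
  gs <- data.frame(group = levels(groups),
                   n = as.integer(table(groups)),
                   median = as.numeric(tapply(values, groups, stats::median)))
  pw <- NULL
  if (pairwisePosthoc) {
    cmb <- utils::combn(levels(groups), 2L)
    p <- numeric(ncol(cmb))
    for (j in seq_len(ncol(cmb))) {
      x <- values[groups == cmb[1L, j]]
      y <- values[groups == cmb[2L, j]]
      p[j] <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    }
    pw <- data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ], p = p,
                     p_adj = stats::p.adjust(p, method = "BH"))
  }
  structure(list(omnibus = list(statistic = unname(kw$statistic),
                                df = unname(kw$parameter), p = kw$p.value),
                 groups = gs, pairwise = pw),
            class = "groupCompare")
}

#' @export
print.groupCompare <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p))
  print(x$groups, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("pairwise Wilcoxon (BH-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
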