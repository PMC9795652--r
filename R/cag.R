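#' Genus filter for co-abundance analysis
#'
#' Keeps genera whose relative abundance strictly exceeds `relAbund`
#' (default 0.1%) in at least `minSamples` samples.
#'
#' @param table genus-level [FeatureTable-class] (relative abundances; a
#'   count table is normalized first).
#' @param relAbund abundance threshold (strict inequality).
#' @param minSamples minimum number of qualifying samples.
#' @return filtered [FeatureTable-class] of relative abundances.
#' @export
filterGenera <- function(table, relAbund = 0.001, minSamples = 2L) {
  rel <- if (isRelative(table)) abundances(table) else relAbundance(table)
  keep <- colSums(rel > relAbund) >= minSamples
  if (sum(keep) < 3L)
    stop("fewer than 3 genera survive the abundance filter (",
         sum(keep), " kept)")
  featureTable(rel[, keep, drop = FALSE], level = "genus",
               taxonomy = taxonomy(table)[names(taxonomy(table)) %in%
                                            colnames(rel)[keep]],
               isRelative = isRelative(table))
}

## Tie-corrected two-sided p-values for Kendall's tau-b, vectorized over all
## feature pairs (normal approximation; matches cor.test(exact = FALSE)).
.kendallPvals <- function(m, tau) {
  n <- nrow(m)
  n0 <- n * (n - 1) / 2
  tieStats <- apply(m, 2L, function(x) {
    t <- table(x)
    c(sum(t * (t - 1) / 2),               # pairs tied
      sum(t * (t - 1) * (2 * t + 5)),     # variance tie term
      sum(t * (t - 1)),                   # v1 term
      sum(t * (t - 1) * (t - 2)))         # v2 term
  })
  T1 <- tieStats[1L, ]; VT <- tieStats[2L, ]
  W1 <- tieStats[3L, ]; W2 <- tieStats[4L, ]
  D <- sqrt(outer(n0 - T1, n0 - T1))      # sqrt(D1 * D2)
  S <- tau * D
  v0 <- n * (n - 1) * (2 * n + 5)
  v <- (v0 - outer(VT, VT, "+")) / 18 +
    outer(W1, W1) / (2 * n * (n - 1)) +
    outer(W2, W2) / (9 * n * (n - 1) * (n - 2))
  z <- S / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

#' Storey q-values with BH fallback
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05..0.95 with
#' cubic-spline smoothing and returns `q_i = pi0 * m * p_(i) / i` made
#' monotone.  With fewer than 50 p-values the histogram is too sparse for
#' pi0 estimation and the BH procedure (pi0 = 1) is used, with a message.
#'
#' @param p vector of p-values.
#' @return list with `qvalue` (aligned with `p`) and `pi0`.
#' @export
storeyQvalues <- function(p) {
  ok <- !is.na(p)
  m <- sum(ok)
  pi0 <- 1
  if (m >= 50L) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0l <- vapply(lambda, function(l) sum(p[ok] > l) / (m * (1 - l)), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0l, df = 3)
    pi0 <- min(max(stats::predict(fit, x = 0.95)$y, 1e-8), 1)
  } else if (m > 0L) {
    message("fewer than 50 p-values; falling back to Benjamini-Hochberg (pi0 = 1)")
  }
  q <- rep(NA_real_, length(p))
  ord <- order(p[ok])
  ps <- p[ok][ord]
  qs <- pi0 * m * ps / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  qs <- pmin(qs, 1)
  qok <- numeric(m); qok[ord] <- qs
  q[ok] <- qok
  list(qvalue = q, pi0 = pi0)
}

#' Kendall co-abundance network with q-value FDR gating
#'
#' Tie-adjusted Kendall tau-b with two-sided p-values for every genus pair;
#' q-values by Storey's method ([storeyQvalues()]).  Retained edges satisfy
#' tau > 0 and q <= alpha.  Constant genera give undefined correlations and
#' are flagged.
#'
#' @param table filtered genus [FeatureTable-class] (>= 4 samples).
#' @param alpha FDR level for edge retention.
#' @return list with `edges` (retained edge data.frame: genus1, genus2,
#'   tau, p, q), `allPairs` (every pair), `pi0`, and `undefined` (genera
#'   with constant profiles).
#' @export
kendallNetwork <- function(table, alpha = 0.05) {
  m <- abundances(table)
  if (nrow(m) < 4L) stop("need at least 4 samples for Kendall correlations")
  const <- apply(m, 2L, function(x) length(unique(x)) == 1L)
  tau <- suppressWarnings(stats::cor(m, method = "kendall"))
  pv <- .kendallPvals(m, tau)
  ut <- upper.tri(tau)
  idx <- which(ut, arr.ind = TRUE)
  pairs <- data.frame(genus1 = colnames(m)[idx[, 1L]],
                      genus2 = colnames(m)[idx[, 2L]],
                      tau = tau[ut], p = pv[ut])
  undef <- const[pairs$genus1] | const[pairs$genus2]
  pairs$tau[undef] <- NA_real_; pairs$p[undef] <- NA_real_
  qres <- storeyQvalues(pairs$p)
  pairs$q <- qres$qvalue
  keep <- !is.na(pairs$tau) & pairs$tau > 0 & pairs$q <= alpha
  list(edges = pairs[keep, , drop = FALSE], allPairs = pairs,
       pi0 = qres$pi0, undefined = names(const)[const])
}

#' Assign genera to co-abundance groups (CAGs)
#'
#' Ward linkage on `1 - rho` between genus abundance profiles (Spearman),
#' cut at `k` (default 5) or at the silhouette-maximizing k under
#' `"auto"`.  Each CAG is named after its genus with the highest cohort-mean
#' relative abundance.
#'
#' @param table filtered genus [FeatureTable-class].
#' @param k number of CAGs, or `"auto"`.
#' @param edges optional retained edge data.frame from [kendallNetwork()]
#'   to store in the partition.
#' @param kMax largest k tried under `"auto"`.
#' @return a [CagPartition-class].
#' @export
assignCags <- function(table, k = 5L, edges = NULL, kMax = 8L) {
  m <- abundances(table)
  p <- ncol(m)
  rho <- stats::cor(m, method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "ward.D2")
  if (identical(k, "auto")) {
    ks <- 2:min(kMax, p - 1L)
    sil <- vapply(ks, function(kk)
      mean(cluster::silhouette(stats::cutree(hc, kk), d)[, "sil_width"]),
      numeric(1))
    k <- ks[which.max(sil)]
  }
  k <- as.integer(k)
  if (k > p) stop("k (", k, ") exceeds the number of genera (", p, ")")
  cl <- stats::cutree(hc, k)
  cohortMean <- colMeans(m)
  ids <- paste0("CAG", seq_len(k))
  membership <- setNames(ids[cl], colnames(m))
  nm <- vapply(seq_len(k), function(i) {
    g <- names(membership)[membership == ids[i]]
    g[which.max(cohortMean[g])]
  }, character(1))
  if (is.null(edges)) edges <- data.frame(genus1 = character(0),
                                          genus2 = character(0),
                                          tau = numeric(0), p = numeric(0),
                                          q = numeric(0))
  new("CagPartition", membership = membership,
      cagNames = setNames(nm, ids), edges = edges,
      discSizes = matrix(numeric(0), 0, 0))
}

#' Wiggum-plot disc statistics per cluster
#'
#' `disc(genus, cluster) = mean relative abundance in the cluster / mean
#' relative abundance in the whole cohort`; 1 means the cluster matches the
#' cohort average.  Genera absent cohort-wide are excluded.
#'
#' @param table genus [FeatureTable-class] (relative abundances).
#' @param assignment a [ClusterAssignment-class] (or named factor).
#' @param partition a [CagPartition-class].
#' @return the partition with its `discSizes` slot filled (genus x cluster).
#' @export
wiggumStats <- function(table, assignment, partition) {
  rel <- if (isRelative(table)) abundances(table) else relAbundance(table)
  labels <- if (is(assignment, "ClusterAssignment"))
    clusterLabels(assignment) else factor(assignment)
  common <- intersect(rownames(rel), names(labels))
  if (!length(common)) stop("no shared samples between table and assignment")
  rel <- rel[common, , drop = FALSE]
  labels <- droplevels(labels[common])
  genera <- intersect(names(cagMembership(partition)), colnames(rel))
  cohort <- colMeans(rel[, genera, drop = FALSE])
  present <- cohort > 0
  genera <- genera[present]
  disc <- vapply(levels(labels), function(cl) {
    colMeans(rel[labels == cl, genera, drop = FALSE]) / cohort[genera]
  }, numeric(length(genera)))
  disc <- matrix(disc, nrow = length(genera),
                 dimnames = list(genera, levels(labels)))
  methods::initialize(partition, discSizes = disc)
}
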