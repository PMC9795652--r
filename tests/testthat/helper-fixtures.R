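# Shared fixtures and independent oracles for the suite.

# Cache the default synthetic cohort (seed 42) so expensive stages build it
# only once per test run.
.cohortCache <- new.env(parent = emptyenv())
defaultCohort <- function() {
  if (is.null(.cohortCache$cohort))
    .cohortCache$cohort <- simulateCohort(synthConfig(rngSeed = 42L))
  .cohortCache$cohort
}

# Small deterministic count table: 4 samples x 3 features.
tinyCounts <- function() {
  m <- matrix(c(5, 0, 3,
                2, 1, 9,
                0, 4, 4,
                7, 2, 1), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("S", 1:4), paste0("otu", 1:3)))
  featureTable(m, "otu")
}

# Independent brute-force UniFrac oracle: walk every branch of a rooted ape
# tree, collect its descendant tips, and accumulate unique/shared branch
# length (unweighted) or abundance-weighted differences (weighted).
bfUnifrac <- function(tree, a, b, weighted = FALSE, normalized = TRUE) {
  n <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= n) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  pa <- a / sum(a); pb <- b / sum(b)
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[desc(tree$edge[e, 2])]
    L <- tree$edge.length[e]
    if (weighted) {
      num <- num + L * abs(sum(pa[tips]) - sum(pb[tips]))
      den <- den + L * (sum(pa[tips]) + sum(pb[tips]))
    } else {
      inA <- any(a[tips] > 0); inB <- any(b[tips] > 0)
      if (inA || inB) {
        den <- den + L
        if (xor(inA, inB)) num <- num + L
      }
    }
  }
  if (weighted && !normalized) return(num)
  num / den
}

# Full-enumeration Fisher oracle for 2x2 tables with fixed margins.
fisherEnum2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) stats::dhyper(a, r1, r2, c1), numeric(1))
  pObs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Adjusted Rand index between two labelings.
randARI <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  exp_a <- b * cc / choose(n, 2)
  max_a <- (b + cc) / 2
  (a - exp_a) / (max_a - exp_a)
}

# Noise-free PairedOmics fixture from an explicit ratio matrix: DNA = 1
# everywhere, RNA = ratio (NA ratio encoded as DNA = 0, RNA = 0).
pairedFromRatios <- function(ratios) {
  dna <- matrix(1, nrow(ratios), ncol(ratios), dimnames = dimnames(ratios))
  rna <- ratios
  dna[is.na(ratios)] <- 0
  rna[is.na(ratios)] <- 0
  pairedOmics(featureTable(rna, "pathway"), featureTable(dna, "pathway"))
}
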