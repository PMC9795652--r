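---
title: "Methods: community typing, co-abundance networks, and multi-omics coupling in microtype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community typing, co-abundance networks, and multi-omics coupling in microtype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

microtype implements the downstream arc of a multi-omics gut-microbiome
study: community "steady-state" typing, co-abundance network inference,
phylogenetic ordination with host-metadata association, dietary
patterning, DNA-normalized transcriptional activity, and sparse
partial-least-squares coupling of the metatranscriptome to the fecal
lipidome. This vignette records the models, the tunable parameters, the
numerical conventions, and the reasoning behind the design choices that
were genuinely open.

## Community typing

Samples are typed on OTU relative abundances filtered for prevalence
(present in at least 20% of participants, boundary inclusive;
`prevalenceThreshold`). Two conventions deserve note:

* **Proportions are not re-normalized after filtering.** Retained values
  keep their meaning as proportions of the original community; relative
  `FeatureTable`s therefore allow row sums below 1 after any feature
  subsetting, and the validity check enforces sums in (0, 1]. A
  `renormalizeAfterFilter` toggle restores unit sums for users who prefer
  the closed composition.
* **"Spearman distance" is `d = 1 − ρ`,** the standard
  correlation-to-dissimilarity map. It satisfies `d(x, x) = 0` and
  symmetry; it is not metric, which is acceptable for Ward linkage and is
  handled explicitly in the PCoA (below). Rank correlations are invariant
  to per-sample scaling, so counts and proportions give identical
  matrices.

Ward linkage (`ward.D2` on unsquared dissimilarities) produces the full
dendrogram; the cut `k` is chosen by maximizing the mean silhouette width
over `k = 2..kMax` (default 8) unless fixed. Cluster labels C1…Ck follow
dendrogram order of first appearance. Within-cluster coherence is
validated by testing every within-cluster sample pair for positive
Spearman correlation, adjusting p-values by Benjamini–Hochberg jointly
across all within-cluster pairs, and flagging a cluster valid when at
least 95% of its pairs reach adjusted p ≤ α with ρ > 0. The 95% pair
fraction (`validityPairFraction`) is this package's operationalization of
"each cluster shows significant within-group correlations"; sample-to-
centroid testing was considered and rejected because pair testing makes
the diagnostic independent of a centroid definition on ranks. Singleton
clusters are flagged and excluded.

Permutational MANOVA is implemented directly from the sums-of-squared-
distances partition: `SS_T = Σ_{i<j} d²_ij / n`, `SS_W` analogously within
groups, `F = (SS_A/(a−1)) / (SS_W/(n−a))`, with a seeded label permutation
and `p = (1 + #{F* ≥ F}) / (1 + N_perm)`. A degenerate grouping with zero
within-group distance yields an infinite F; permutations that reproduce
such a grouping count as ties, so the perfect-separation p-value
approaches `1/(N_perm + 1)` only when the group sizes make a chance
reproduction of the partition negligible (for two groups of 10,
probability ≈ 1e-5). vegan's `adonis2` is used as an equality cross-check
on non-degenerate input in the test suite; it is not used as the
implementation because its F statistic overflows in the zero-within-
distance case and its small-n complete-enumeration switch changes the
p-value denominator away from the stated formula.

Alpha diversity is Shannon entropy in bits (base 2 by `shannonLogBase`)
plus the observed-feature count; group contrasts use tie-corrected
Kruskal–Wallis with pairwise two-sided Wilcoxon rank-sum post-hoc tests,
BH-adjusted across pairs. Wilcoxon p-values follow the `stats::wilcox.test`
policy: exact for small tie-free samples, normal approximation with
continuity correction otherwise.

## UniFrac, PCoA, and vector fitting

UniFrac is computed by phyloseq behind the `unifrac()` surface; the test
suite verifies both the unweighted and the weighted variants (normalized
and raw) against an independent brute-force branch-enumeration oracle to
1e-12 on 100 random 8-leaf trees. Presence for the unweighted variant is
`count > 0` with no rarefaction (workflows that rarefy should subsample
the count table before calling `unifrac()`). Unrooted input trees are
rooted deterministically at the first
tip rather than at random, so reruns are identical.

PCoA uses Gower double-centering and a symmetric eigendecomposition;
coordinates are eigenvectors scaled by the square root of their
eigenvalues. Negative eigenvalues — expected for non-Euclidean inputs like
unweighted UniFrac or `1 − ρ` — are reported in full but their axes are
excluded from the coordinates; no Cailliez correction is applied by
default (it is available via `correction = "cailliez"`), since the
downstream uses (display axes 1–2, median regression on axes 1–3) only
consume the leading positive axes. Axis signs are fixed so each axis's
largest-magnitude coordinate is positive, making runs comparable.

Food-frequency vectors are superimposed with `vegan::envfit` on the first
two axes (the display space), seeded; all fits are retained and a
significance flag marks the display list at α. Constant covariates are
flagged and skipped.

## Co-abundance groups

Genera qualify at relative abundance strictly above 0.1% in at least two
samples. Network edges use tie-corrected Kendall τ_b with a vectorized
normal-approximation p-value (verified equal to `cor.test(exact = FALSE)`
with and without ties); edges are retained when τ > 0 and q ≤ 0.05.
q-values follow Storey's method with π₀ estimated on the λ grid
0.05…0.95 and cubic-spline smoothing; with fewer than 50 p-values the
histogram is too sparse for π₀ estimation and the procedure falls back to
Benjamini–Hochberg (π₀ = 1) with a message. The package keeps the
upstream convention of Kendall correlations for edges but Spearman-based
`1 − ρ` Ward clustering for the CAG partition — fidelity over elegance —
and names each CAG after its genus with the highest cohort-mean
abundance. Wiggum disc sizes are over-abundance ratios (cluster mean ÷
cohort mean), the more specific of the two published readings of disc
size; an absolute-abundance disc is one accessor away from the same
matrix.

## Dietary patterns

Correspondence analysis is computed from the SVD of the standardized
residuals `S = D_r^{-1/2}(P − rcᵀ)D_c^{-1/2}`; row principal coordinates
are `D_r^{-1/2} U D_σ`, per-axis inertia shares are σ²/Σσ², and total
inertia times the grand total equals the table's chi-square statistic
(asserted in the tests). Samples are rows and raw frequencies are used
(the two conventions the source leaves open); the axis sign is fixed so
the food with the largest column mass has a non-negative coordinate.
A rank-1 (independence) table has no non-trivial axes and returns zero
scores. Dietary groups are 1-D Ward/Euclidean clusters of the axis-1
scores, labeled D1…Dk by increasing group mean.

The Healthy Food Diversity index composes the number, distribution and
health value of consumed foods as `HFD = hv̄ × BI` with Berry index
`BI = 1 − Σ sᵢ²` and share-weighted mean health value hv̄ — the cited
construction, since the source names the index without printing a
formula; the health-value vector is a user-suppliable annotation column.
Nutrient summaries use Atwater factors 4/4/9 kcal/g and normalize fiber
to grams per 1000 kcal.

## Transcriptional activity

RNA:DNA ratios quantify expression independent of gene copy number. The
zero policy is explicit because the upstream tools do not state one:
DNA = 0 with RNA = 0 is undefined and excluded from aggregation; DNA = 0
with RNA > 0 is also undefined but surfaced in a side table, because
transcripts without detectable gene copies are a real signal worth
inspecting in HUMAnN2-style tables. An optional smoothing pseudocount is
off by default. Cluster aggregation uses means, not medians, to match the
"average ratio" convention of the outputs it emulates.

Log2 over-abundance is `log2((mean_cluster + ε)/(mean_cohort + ε))` with
ε set to half the smallest nonzero ratio in the table. A species is
"active" in a (cluster, category) cell when its log2 value strictly
exceeds 1 in at least ⌈m/3⌉ of the category's m pathways; the pathway →
category map ships as a plain-text table (`defaultPathwayCategories()`)
and is overridable. Note that the cohort reference includes the cluster
itself: a multiplier M planted in a cluster of weight w is recovered as
`log2(M/(1 + w(M−1)))`, not `log2 M`. The package's spike-in validation
therefore plants its known multiplier in a small cluster (3% of a
400-sample cohort), where the reference contamination shifts the
expectation by under 0.1 on the log2 scale.

## Sparse PLS

`splsFit` is a NIPALS implementation: alternating singular directions of
the X'Y cross-covariance, soft-thresholding the X loading to the keepX
largest entries, unit-norm loadings, and regression-mode deflation of
both blocks on the X score. Blocks are centered and unit-scaled by
default; initialization is the leading singular vector of X'Y, so the fit
is deterministic; convergence tolerance is 1e-9 with a 500-iteration cap
per component, and non-convergence is an error, not a warning. Each
component's X loading is flipped so its largest-magnitude entry is
positive. Defaults are ncomp = 2 with keepX = all features (sparsity is
tuned only on request, since the emulated analysis prints neither).
mixOmics' sPLS is used in the tests as an independent reference (loading
agreement to |cos| > 0.999), never as the implementation.

The association heatmap scores are the plain loading product
`Σ_h u_h v_hᵀ` (a covariance-weighted variant is available via
`covWeighted`); rows and columns are ordered by complete linkage on
`1 − r` (not `1 − |r|`, matching the clustered-image-map convention; the
absolute variant is a flag). The X block is the RNA-level pathway table
filtered at 50% prevalence (inclusive); all lipid variables enter Y.

## Host associations

Median (τ = 0.5) regression `y = β₀ + β₁·axis + β₂·age` is solved by
iteratively reweighted least squares from the OLS start (the objective is
convex; tolerance 1e-10, 200 iterations). Reported alongside the raw β₁
are `RC_range = β₁ × (max − min)` and `RC_sd = β₁ × sd` of the axis
scores — both invariant to axis rescaling, which makes them the right
reporting scale for ordination axes whose units are arbitrary. p-values
for β₁ use the rank-score test (restricted-fit residual signs scored
against the L2-projected axis; null calibration measured at 5.25% over
400 null replicates during development, and re-measured by the acceptance
script) with a seeded pairs-bootstrap fallback below 20 complete cases.
BH correction is applied across the full variable × axis grid. Complete
cases only; nothing is imputed.

Fisher's exact test delegates to the network algorithm of
`stats::fisher.test`, switching to a seeded Monte Carlo estimate (with
reported standard error) above roughly 1e7 candidate tables. Cramér's V
uses the uncorrected chi-square. HOMA-IR is `glucose × insulin / 405`
with insulin resistance strictly above 2.5; the Matsuda index is
`10000/√(G0·I0·Gmean·Imean)`, deriving OGTT means from AUCs divided by
the test duration (default 120 min) when means are absent. YFAS
stratification applies the three printed rules to OB participants only,
and a diagnosis with fewer than three symptoms is a validation error
because it violates the instrument.

## The synthetic cohort: what it emulates, and what it does not

`simulateCohort()` generates the full labeled cohort at the study's
scale: 100 participants in four community states at proportions
0.31/0.33/0.22/0.14, normal-weight probabilities 0.48/0.28/0.36/0.36 per
state, 40 genera in five co-abundance blocks, three dietary archetypes, a
15-lipid panel, and paired RNA/DNA pathway tables over 10 species.

* **Abundances.** Genus log-abundance is a fixed baseline plus the
  cluster × block multiplier, a per-(block, sample) latent factor
  (loading 0.3) driving positive within-block Kendall correlation, and
  Gaussian noise (sd 0.25). The default multipliers encode the published
  qualitative layout: C2 and C3 lose the Bifidobacterium block, C3
  over-represents Prevotella and Ruminococcus (×3), C4 trades Bacteroides
  for a tripled Bifidobacterium block. Genus mass is split over 3–10 OTUs
  by a cluster-specific Dirichlet draw around a fixed base split
  (`otuSplitConcentration = 1.5`): community states differ in strain-level
  OTU composition, which separates them in sample-rank space while
  leaving every genus-level quantity (CAG structure, Wiggum discs)
  untouched. This strain-level divergence is what makes all four states
  separable by Spearman/Ward at the default sequencing depth of 5000
  reads/sample (kept deliberately below study scale so the suite runs in
  minutes; depth is a config knob). The multiplier magnitudes and the
  split concentration were calibrated once so that the planted k = 4 is
  the silhouette-optimal cut — with a cohort-wide fixed split, scalar
  block multipliers move rank correlations far too little for the two
  Bifidobacterium-depleted states ever to separate.
* **Alpha diversity.** C1 (all five blocks) is the most diverse and C2
  loses diversity with its lost block — the contrast the tests assert.
  C3's over-representation trades evenness for its doubled blocks, so C3
  lands low rather than high; the generator reproduces the
  highest-in-C1/lowest-in-C4 ends of the published ordering, not every
  intermediate rank.
* **Behavior.** TFEQ-UE and BITE symptom scores are linear in the second
  unweighted-UniFrac PCoA axis with slopes stated in score points per
  axis standard deviation (defaults −1.5 and −1.2; the raw per-unit slope
  is an artifact of eigenvalue scaling and is recorded in the ground
  truth for recovery checks), plus an age term and symmetric noise.
  β = 0 gives an exactly null association.
* **Expression.** DNA is species abundance times a fixed incidence
  matrix; RNA is DNA times a per-(species, pathway, cluster) multiplier
  times log-normal noise (sd 0.25). The default layout plants the
  published qualitative patterns: K00076 transcribed by *E. coli* only in
  C1; K01442 by *A. hadrus* in C2; weak K07007 activity by
  *F. prausnitzii* in C4 (which also keeps the smallest nonzero ratio —
  and hence the log2 pseudocount — realistically small); and secondary
  bile acid biosynthesis by *F. prausnitzii* as the dominant C3/C4
  signal, so that its coupling with 5β-sitostanol is the strongest
  association the sPLS stage finds, as reported for the emulated study.
  Several other couplings are genuinely planted (cholesterol and primary
  bile acids with the C2-specific transcription, SCFAs inversely with the
  C3/C4 axis), so the clustered heatmap surfaces a family of real
  associations, and the exact rank of any single pair varies with the
  seed.
* **Not emulated.** Read-level noise (chimeras, contamination),
  compositional artifacts beyond the multinomial draw, longitudinal
  structure, covariate confounding between diet and community state
  (dietary archetypes are assigned independently of clusters), and
  missing-data patterns. Passing tests therefore demonstrate that the
  statistical machinery recovers planted structure of realistic shape and
  size — not that it is robust to every failure mode of real sequencing
  data.

## Problem sizes and determinism

The test suite and acceptance script scale simulations to run in minutes:
the default cohort (n = 100, ~250 OTUs), 300 null replicates of a
200-genus Kendall network for the realized-FDR check, 500 null datasets
(n = 20, 199 permutations) for PERMANOVA calibration, 100 random 8-leaf
trees for the UniFrac oracle, 200 null replicates for median-regression
calibration, and a 400-sample spike-in cohort for expression recovery.
Every stochastic stage takes an explicit seed; rerunning any stage or the
whole pipeline with the same seed is bit-identical, and file round-trips
preserve numeric values to the 15 significant digits written.

## Known limitations

* Storey's π₀ spline estimate is unstable for small test families; the
  BH fallback is deliberate and logged, not silent.
* The rank-score p-value uses an L2 projection of the tested covariate on
  the restricted design (the classical simplification); for heavy-tailed
  noise at small n the seeded bootstrap fallback is the safer route.
* Median regression by IRLS converges to the LAD solution for practical
  purposes but does not return the exact linear-programming vertex;
  coefficients agree with the planted truth well inside the reporting
  precision.
* UniFrac inherits phyloseq's conventions (no variance adjustment or
  generalized UniFrac); unweighted UniFrac is sensitive to rare-feature
  presence and hence to sequencing depth — users comparing cohorts of
  very different depth should rarefy upstream.
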