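# microtype

Downstream multi-omics analysis of stool microbiome cohorts, built for
studies that relate gut community structure to host phenotype (weight
status, eating behavior, diet, fecal lipids, microbial gene expression).
The package takes the *derived* tables such studies produce — an OTU count
table with a rooted phylogeny, sample metadata, food-frequency data,
HUMAnN2-style paired RNA/DNA pathway tables, and a fecal lipid panel — and
runs the full downstream arc:

1. **Community steady-state typing.** OTUs are filtered for ≥ 20%
   prevalence, samples are correlated by Spearman's ρ over OTU proportions,
   and hierarchical Ward linkage on `d = 1 − ρ` cuts the cohort into
   community clusters (C1…Ck; k chosen by silhouette or fixed). Clusters
   are validated by Benjamini–Hochberg–corrected within-cluster correlation
   tests and by permutational MANOVA (Anderson's pseudo-F with seeded label
   permutation, `p = (1 + #{F* ≥ F}) / (1 + N_perm)`).
2. **Beta-diversity ordination.** Unweighted and weighted UniFrac →
   principal coordinates analysis (Gower double-centering; negative
   eigenvalues reported, their axes excluded), with food-frequency vectors
   superimposed by permutation-tested least-squares fits.
3. **Co-abundance groups (CAGs).** Genera at > 0.1% relative abundance in
   ≥ 2 samples; tie-corrected Kendall τ_b for every pair with Storey
   q-values (BH fallback under 50 tests); edges kept when τ > 0 and
   q ≤ 0.05; Ward/Spearman clustering into CAGs named for their dominant
   genus; Wiggum disc statistics (cluster mean ÷ cohort mean abundance) and
   GraphML export.
4. **Dietary patterns.** Correspondence analysis of the FFQ, 1-D Ward
   clustering of axis-1 scores into dietary groups, the Healthy Food
   Diversity index `HFD = hv̄ × (1 − Σ sᵢ²)`, and Atwater (4/4/9) nutrient
   summaries with fiber per 1000 kcal.
5. **Transcriptional activity.** RNA:DNA ratios per "pathway|species"
   feature (explicit zero policy: DNA = 0 cells are undefined; RNA-only
   cells are side-tabled), per-cluster log2 over-abundance, an
   "active species" rule (log2 > 1 in ≥ ⌈m/3⌉ of a category's pathways),
   and KO-panel cluster/cohort ratio tables.
6. **Multi-omics coupling.** Sparse partial least squares (NIPALS with
   soft-thresholded X loadings, regression-mode deflation) linking the
   metatranscriptome block (features present in ≥ 50% of samples) to the
   full lipid panel, with a complete-linkage `1 − r` clustered association
   heatmap table.
7. **Host associations.** Age-adjusted median (quantile) regression of
   behavioral scores on the leading ordination axes, reporting the raw
   coefficient β together with `RC_range = β × range(axis)` and
   `RC_sd = β × sd(axis)`, rank-score p-values and BH correction; Fisher's
   exact tests, Cramér's V, HOMA-IR (`glucose × insulin / 405`, insulin
   resistance at > 2.5), the Matsuda index, and YFAS behavioral
   stratification (O_LA / O_HA / O_DHA).

A seeded synthetic-cohort generator (`simulateCohort()`) plants the exact
statistical structure these stages assume — four community states at
realistic proportions, five genus co-abundance blocks, dietary archetypes,
cluster-patterned lipid panels, expression multipliers — so the entire
pipeline is testable end-to-end without any data download.

## Worked example

```r
library(microtype)

cohort <- simulateCohort(synthConfig(rngSeed = 42))
res <- runPipeline(cohort, analysisConfig(rngSeed = 42, nPermutations = 199),
                   outDir = "results/run42")
res$typing
#> ClusterAssignment: 100 samples in 4 clusters (C1=22, C2=33, C3=14, C4=31)
#>   mean silhouette at k=4: 0.773
#>   PERMANOVA pseudo-F = 1001.895, p = 0.005

subset(res$associations, axis == "PCo2" & variable %in% c("tfeq_ue", "bite_symptom"))
#>         variable axis   n      beta  rc_range     rc_sd            p        p_adj significant
#> xx1 bite_symptom PCo2 100 -52.96451 -7.148885 -1.983102 5.777242e-04 0.0043329317        TRUE
#> xx4      tfeq_ue PCo2 100 -35.21392 -4.753000 -1.318483 1.092337e-05 0.0001638505        TRUE
```

The typing stage selects k = 4 by silhouette and recovers the four planted
community states exactly (adjusted Rand index 1.0 against the generator's
ground truth). The association table shows the planted behavioral
couplings: uncontrolled-eating and binge-eating scores increase as samples
shift toward negative values of the second UniFrac-PCoA axis (negative β,
significant after BH correction across the variable × axis grid), while
the same scores show no association with axes 1 and 3.

`res` also carries the CAG partition (five groups named Bacteroides,
Bifidobacterium, Dorea, Prevotella, Ruminococcus), per-cluster Wiggum disc
sizes, dietary groups D1–D3 with HFD summaries, the RNA:DNA activity
tables, and the sPLS model whose strongest positive association pairs
5β-sitostanol with secondary bile acid biosynthesis transcribed by
*F. prausnitzii*.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/microtype.R simulate --out cohort_dir --seed 42
Rscript inst/scripts/microtype.R all --in cohort_dir --out results --seed 42
```

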