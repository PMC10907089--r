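# locus2gene

Genome-wide association studies (GWAS) report risk *variants*, not risk
*genes*: a typical locus spans dozens of genes, and the association signal
rarely points at the causal one. `locus2gene` implements a complete
locus-to-gene nomination pipeline for this problem, of the kind used to
prioritize candidate genes at the 78 Parkinson's-disease GWAS loci: it
combines genomic distance, variant-consequence severity, QTL links and
cell-type expression into a per-gene probability that the gene drives its
locus's association, explains every score with exact Shapley values, and
follows up nominated genes with pathway over-representation and
pathway-specific polygenic risk scores (PRS).

It is aimed at statistical geneticists who want a tested, reusable, fully
synthetic-benchmarkable version of this analysis: every stage can be run
against generated data with planted ground truth, so recovery of the truth
is measurable.

## The method

1. **Locus construction.** Independent risk variants within 250 kb are
   merged into one locus by single-linkage chaining (90 lead variants
   yield 78 loci under the study design this emulates). All protein-coding
   genes within 1 Mb of a locus's lead variants are candidates; fine-mapped
   credible SNPs attach to their locus.
2. **Neighbourhood scores.** Each feature is rescaled within each locus
   relative to the best gene: for "higher is better" features
   `score = value / max(value in locus)`; for distances,
   `t = log10(d_max + 1) − log10(d + 1)` then `t / max(t)`, so the closest
   gene scores 1. This encodes the locus structure the learner needs.
3. **Two-step boosted classifier.** An XGBoost model with
   `scale_pos_weight = n_negative / n_positive` is trained on a handful of
   positively labelled genes against their within-locus neighbours
   (negatives), with 5-fold locus-grouped cross-validation maximizing mean
   average precision (MAP). Step 1 selects the features the ensemble
   actually uses (nonzero split importance); step 2 re-tunes and refits on
   that subset. Genes are scored with probabilities in [0, 1].
4. **Explanation.** Exact tree-Shapley attribution (native
   double-precision implementation of the polynomial-time path-dependent
   algorithm) decomposes every score into additive per-feature
   contributions: `E[f(x)] + Σ φ_j = f(x)` on the log-odds scale.
5. **Nomination.** The top-scoring gene per locus is nominated, tiered at
   probability > 0.75 (high) and < 0.30 (low), with runner-up flags when a
   second gene also exceeds 0.75.
6. **Pathway follow-up.** Nominated genes are tested for over-representation
   in gene sets (hypergeometric upper tail against a protein-coding
   universe, Benjamini-Hochberg FDR). Nominated pathways are then tested
   with pathway-specific PRS: SNPs with MAF ≥ 0.01 and GWAS p ≤ 0.05 are
   LD-clumped (r² = 0.1, 250 kb), summed over pathway gene bodies with
   GWAS weights, standardized, and associated with case status by logistic
   regression with 10,000 label permutations for an empirical p-value;
   cohorts are pooled by fixed-effect inverse-variance meta-analysis with
   Cochran's Q heterogeneity and a leave-one-out outlier report.

A synthetic-data module (`sim_config()`, `simulate_loci()`,
`simulate_features()`, `simulate_cohort()`, `simulate_gene_sets()`)
generates study-shaped data — 78 loci from 90 leads, 284 features across
four modalities with missingness, 7 positive labels, case-control cohorts
with a planted pathway liability effect — with full ground truth, so every
downstream stage is testable.

## Worked example

```r
library(locus2gene)

cfg <- sim_config(n_loci = 12, n_leads = 14, genes_per_locus = c(2, 8),
                  n_positive_labels = 5, n_individuals = 1000,
                  n_discovery = 8000, seed = 7)
run <- l2g_pipeline(cfg, n_cohorts = 2, n_permutations = 999)
run
#> <l2g_run>
#>   14 lead variants -> 12 loci; 49 locus-gene pairs
#>   model: 32/284 features selected, CV MAP 0.900
#>   planted gene ranked first in 83.3% of 12 loci
#>   nominations: 2 high / 10 mid / 0 low confidence
#>   top enriched set: DECOY_SET_030 (q = 0.983)
#>   pathway PRS meta: OR 1.136 (1.039-1.243), p = 0.0053
```

Reading the output: 14 simulated lead variants merged into 12 loci holding
49 candidate genes; two-step training selected 32 of 284 features and
reached a cross-validated MAP of 0.90 on the labelled loci; the planted
causal gene was ranked first in 10 of 12 loci; two nominations exceeded the
0.75 high-confidence threshold. At this small scale the enrichment stage
has too few nominated genes for the planted pathway to reach significance
(the top set is a decoy at q = 0.98 — i.e. nothing is significant), while
the pathway PRS still recovers a positive association (pooled odds ratio
1.14 per SD of the score, p = 0.005, two cohorts). Individual stages are
available as plain functions returning tibbles
(`merge_variants()`, `assign_genes()`, `neighbourhood_transform()`,
`train_two_step()`, `score_genes()`, `attribute()`, `nominate()`, `ora()`,
`score_pathway()`, `associate()`, `permutation_p()`, `meta_analyze()`), with
`tidy()`/`glance()` methods and `plot_*()`/`autoplot()` graphics.

```r
glance(run$model)
#>   n_pos n_neg pos_weight n_features_in n_features_selected n_folds cv_map
#> 1     5    17        3.4           284                  32       5    0.9
```

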