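# transmed

Cis and trans eQTL mapping with permutation FDR control and causal
mediation calling, for population-scale genotype–expression cohorts.

## The problem

A variant that is an expression quantitative trait locus (eQTL) for a nearby
gene (in *cis*, here within 1 Mb of the transcription start site) and also
for a distant gene (in *trans*, beyond 5 Mb or on another chromosome) hints
at a regulatory chain: the variant perturbs the cis gene, whose product then
modulates the trans gene. `transmed` implements the full analysis a
systems-genetics study needs to find and test such chains:

- **Association scans.** Spearman rank correlation between additive dosages
  (SNPs and copy-number variants) and probe-level expression, with the
  two-sided p-value from the t approximation
  `t = rho * sqrt((n-2)/(1-rho^2))` on `n-2` degrees of freedom. Cis scans
  test a ±1 Mb window around the TSS; trans scans everything beyond ±5 Mb or
  on other chromosomes. Probe QC flags (common SNP in probe, multi-mapping)
  are honored.
- **Permutation FDR.** A gene-based cis null (one shared sample-label
  permutation per round, minimum p per gene) with rank-threshold selection,
  and a genome-wide trans null that pools per-probe-per-round minima and
  sweeps a single p threshold — both selecting the loosest threshold whose
  estimated FDR stays at or below the target (default 5%).
- **Conditional regression.** Iterative residualization to call multiple
  independent cis-eQTLs per gene, variance explained by the best or all
  independent eQTLs, heritability explained `min(r2/h2, 1)`, and allelic
  concordance of independent eQTLs on trans genes.
- **Sharing and replication.** Storey's π1 on replication p-value
  collections, sharing-versus-sample-size curves, per-variant trans-load
  profiles, and replication counting in a second cohort.
- **Enrichment.** Matched-variant resampling (MAF ±1%, distance to closest
  gene ±2 kb) to test overlap of a target variant set with significant
  eQTLs.
- **CNV artifact filters.** Trans associations of copy-number variants are
  discarded when the associated gene shares the CNV's chromosome, when a
  chromosome harbors SNPs correlated with the CNV (r² > 0.1, a mismapping
  signature), or when the CNV's dosage is sex-imbalanced.
- **Causal calling.** Each (variant G, cis gene C, trans gene T) triplet is
  classified as SCT (G→C→T), STC (G→T→C) or INDEP (G→C and G→T) by
  consensus of (a) maximum-likelihood Gaussian Bayesian networks compared by
  AIC = 2k − 2ln L (k = 5 for all models) with a 10× relative-likelihood
  rule, and (b) a causal inference test (CIT) with four component
  regressions per direction and Bonferroni-corrected calling.
- **Synthetic cohorts.** A seeded generator plants cis effects with exact
  variance budgets, LD blocks, mediation chains of all three types,
  sex-imbalanced CNVs and heritability ground truth, so every stage has
  recovery experiments against known truth.

## Worked example

Simulate the bundled mediation scenario (800 samples; 10 SCT, 10 STC and 10
INDEP triplets with path variance-explained 0.2/0.2), map cis-eQTLs at 5%
permutation FDR, and classify three triplets:

```r
library(transmed)

co  <- simulate_cohort(make_scenario("mediation"))
sc  <- cis_scan(co$geno, co$expr, co$annot)
nl  <- cis_permutation_null(co$geno, co$expr, co$annot, n_perm = 200, seed = 2)
sel <- cis_fdr_select(sc, nl)
sel
#> fdr_threshold (cis): 30 discoveries at target FDR 0.05 (achieved 0.0498)
#> permutation rank used: 5
```

All 30 genes carrying a planted genetic effect are recovered at an achieved
FDR just under the 5% target. Building one triplet of each planted type and
calling causality:

```r
tr   <- co$config$triplets[c(1, 11, 21), ]   # one SCT, one STC, one INDEP
trip <- lapply(seq_len(nrow(tr)), function(j) causal_triplet(
  co$geno$dosage[tr$variant_id[j], ],
  co$expr$values[paste0("p_", tr$cis_gene[j]), ],
  co$expr$values[paste0("p_", tr$trans_gene[j]), ],
  standardize = TRUE))
classify_triplets(trip, B = 500, seed = 3)
#>   bn_call cit_call consensus trans_var_explained
#> 1     SCT      SCT       SCT              0.9993
#> 2     STC      STC       STC              0.3310
#> 3   INDEP    INDEP     INDEP              0.0475
```

Both methods agree with the planted truth in all three cases. The last
column is the fraction of the variant's trans association removed by
conditioning on the cis gene: ~1 under full mediation, ~0 under
independence.

Single associations follow the same arithmetic as the scans:

```r
neglog10_p_from_rho(0.443, n = 869)
#> [1] 42.34544
```

i.e. a Spearman correlation of 0.443 at 869 samples corresponds to
p ≈ 10^-42.3.

The full pipeline (cis → conditional → trans → trans-of-cis → causal) runs
from one configuration and writes TSVs plus a reproducibility manifest:

```r
cfg <- pipeline_config(scenario = "mediation", n_perm_cis = 200,
                       n_perm_trans = 100, seed = 11)
run_pipeline(cfg, "out_dir")
```

A thin command-line wrapper lives at `inst/scripts/transmed-eqtl.R`.

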