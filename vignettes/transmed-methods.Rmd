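---
title: "Methods: cis/trans eQTL mapping and causal mediation calling in transmed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis/trans eQTL mapping and causal mediation calling in transmed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transmed)
```

This vignette is the package's account of the statistical machinery: the
models and their assumptions, the parameters that matter, the numerical
choices, and what the synthetic-data experiments do and do not demonstrate.

## Association model

All association testing is single-variant and additive: a variant's dosage
(expected alternate-allele count in [0, 2] for SNPs; a copy-number value for
CNVs) is correlated with a probe's expression by Spearman rank correlation.
Rank-based testing makes every scan invariant to monotone transforms of
either variable and robust to expression outliers, which is why the CNV
dosage scale (integer copies vs. continuous intensity) does not need to be
resolved: any monotone encoding gives the same statistic.

`spearman_test()` computes rho as the Pearson correlation of mid-ranks
(average ranks on ties — SNP dosages are always heavily tied) and converts
it with the two-sided t approximation, `t = rho * sqrt((n-2)/(1-rho^2))` on
`n - 2` degrees of freedom. `neglog10_p_from_rho()` evaluates the same tail
in log space, so correlations with |t| up to ~60 map to finite −log10 p
instead of underflowing. Two properties of this approximation matter:

- At the cohort sizes the package targets (hundreds of samples) it is
  essentially exact on the p scale a scan uses.
- At toy sizes it is only a tail approximation: exhaustive enumeration of
  all 5040 orderings at n = 7 shows agreement with the exact permutation p
  within 0.03 absolute everywhere and within 10% relative for moderate
  correlations (exact p above roughly 0.25), but relative deviations grow
  to tens of percent in the deep tail. The test suite pins both facts.
  Permutation-based FDR control downstream does not rely on the
  approximation being exact, only on it being a monotone transform of |rho|
  at fixed n, which it is.

Perfect correlations (|rho| = 1) have no finite t; their p is reported as
the smallest positive normal double rather than 0 so that logs stay finite.

## Scan geometry

Coordinates are 1-based and windows are closed: a cis scan tests variants
with `|position − TSS| <= half_window` (default 1 Mb, a 2 Mb window) on the
probe's chromosome; a trans scan tests variants on other chromosomes or
with `|position − TSS| > exclusion` (default 5 Mb). The 1–5 Mb annulus is
deliberately tested by neither scan — it is ambiguous territory where LD
with cis variants is still plausible — and a test asserts the two scans
never share a variant–probe pair. Probes flagged as containing a common SNP
are excluded from cis scans (the polymorphism perturbs hybridization and
fakes cis signal); multi-mapped probes are excluded from trans scans (a
mismapped probe generates spurious "trans" hits at its true location).

## Permutation FDR control

Two null schemes, matching the two scan geometries:

**Cis (gene-based).** Each permutation round draws one sample-label
permutation, applies it to the whole expression matrix (preserving
inter-probe correlation), re-runs the cis scan and keeps the minimum p per
probe. Because ranks are label-invariant, permuting a probe reduces to
permuting its precomputed standardized rank vector, and all rounds for one
probe collapse into a single matrix product — this is what makes 1000-round
nulls cheap. For a candidate rank r, the per-gene threshold is the r-th
smallest permuted minimum; expected false discoveries are `G * r /
(n_perm + 1)` over G tested genes (the +1 is the standard permutation
convention avoiding a degenerate zero threshold); the procedure returns the
largest r whose estimated FDR stays at or below the target. Per-gene
thresholds adapt to each gene's window size and LD structure.

**Trans (genome-wide).** A set of probes (default 288, one per gene) is
permuted `n_perm` times; each probe-round contributes its genome-wide
minimum p, and all `n_probes * n_perm` minima are pooled as if one probe
had been permuted that many times — justified because every probe is tested
against approximately the same variant panel and rank statistics are
comparable across probes. The threshold sweeps the pooled values; expected
false discoveries at τ are the pooled tail fraction times the number of
probes tested. For the trans analysis restricted to cis-eQTL variants the
same machinery runs with all probes permuted and the variant panel
restricted (`variant_subset`).

The published genome-wide cutoffs of this kind of analysis are functions of
the dataset; what is reproducible is the *procedure's calibration*, which
the acceptance suite measures: on 20 seeded null cohorts (500 probes, 2000
variants, n = 400, 200 rounds) the mean false discovery proportion at a 5%
target stays below 10%.

## Conditional regression and heritability

`conditional_scan()` regresses the rank-inverse-normal expression jointly on
all previously accepted dosages each round (not sequentially on residuals of
residuals — joint refitting avoids order-dependent drift), re-scans the
residuals with Spearman, and accepts the best variant while it beats the
gene's primary permutation threshold, reused verbatim across rounds. A
candidate whose dosage is almost an affine combination of the accepted set
(R² > 0.999) stops the loop with a warning instead of inflating the design.

Variance explained is the plain coefficient of determination of the joint
linear fit; heritability explained is `min(r2 / h2, 1)` with the cap making
the ratio a proper fraction when the (externally supplied) heritability
estimate is smaller than the realized r². The degenerate corners are fixed
by convention: `h2 = 0` gives 0 when `r2 = 0` and 1 otherwise.

`allelic_concordance()` orients the main and secondary cis variants so each
raises cis expression, then compares the main variant's trans direction
with the secondary's direction on trans expression residualized on the main
dosage. An identical secondary is concordant by construction (after
residualization it has no residual effect to orient, so the general path
cannot apply).

## Sharing, replication, enrichment

`storey_pi1()` estimates the alternative fraction of a p-value collection:
`pi0(lambda) = #{p > lambda} / (m (1 - lambda))` on the grid 0.05–0.95,
smoothed by a cubic smoothing spline with 3 degrees of freedom and read off
at lambda = 0.95 (the convention of the standard q-value implementation),
clamped to [0, 1]. Two properties matter for interpretation: the estimator
needs a reasonable m (it refuses m < 50; its boundary estimate has sampling
sd near 0.1 at m = 500), and under a planted alternative whose p-values are
not all tiny it is mildly conservative — a 30% Beta(0.1, 1) mixture has an
expected estimate near 0.27, which is what the recovery tests check against
a ±0.05 band around the planted 0.30.

`replication_test()` re-tests discovery pairs in a second cohort and counts
p < alpha with matching rho sign; pairs missing from the replication data
are reported separately, never silently dropped. `sharing_curve()` repeats
this on seeded subsamples of increasing size and summarizes π1 with 5%/95%
quantiles across draws — the subsampling interval is a design choice, as is
treating "sharing" as replication of an association list in any second
dataset. `pi1_trans_profile()` is the per-variant version: π1 over the
variant's full trans p-value vector, estimating its trans load without
calling individual targets.

`enrichment_test()` draws, per permutation, one matched variant per target
(MAF within ±1%, distance to closest gene within ±2 kb, uniformly among
eligible pool variants, fresh draws each round) and compares the observed
overlap with a significant set against the matched-null overlaps;
`empirical_p = (1 + #{null >= obs}) / (n_perm + 1)`. Overlap means the
variant itself is significant; LD-aware colocalization is out of scope.

## CNV trans filters

Copy-number dosages come from hybridization intensities, and a mismapped
CNV probe behaves like a variant at the wrong locus: its "trans" hits
cluster on its true chromosome. The filter therefore removes CNV trans
records when (a) the associated probe is on the CNV's own chromosome, (b)
any SNP on the probe's chromosome correlates with the CNV dosage (Pearson
r² > 0.1 on dosages), or (c) the CNV dosage differs between the sexes
(Wilcoxon rank-sum p below 0.05 / #CNVs by default — the threshold is a
package choice, Bonferroni over the CNV panel), since a sex-imbalanced CNV
correlates with every sex-differential probe. Removals carry reason codes
so the filter is auditable.

## Causal models

For a triplet (G, C, T) with standard-normalized expression, three fixed
Gaussian networks anchored on the genotype are fitted by maximum
likelihood, each factorized over its DAG: SCT = G→C→T, STC = G→T→C,
INDEP = G→C plus G→T. Child terms are ML linear regressions (variance
RSS/n); the root term for G is included in all three models so likelihoods
are over the same variables, and cancels in comparisons. Models are
compared by AIC = 2k − 2lnL with k fixed at 5 for every model; since k is
constant, AIC ranking equals likelihood ranking and the exact parameter
accounting is immaterial to any call. A model is called only when the
second best is at most a tenth as likely
(`exp((AIC_best − AIC_second)/2) <= 0.1`). Genotype is treated as a
continuous Gaussian node — dosages are continuous, and the root term
cancels anyway.

The causal inference test supplies an independent, regression-based check
per mediation direction (mediator M, outcome O): p1 tests the marginal G–O
association; p2 tests G in M ~ G + O; p3 tests M in O ~ M + G; p4 is an
equivalence-type test that G ⊥ O | M, implemented by referring the observed
F of G in O ~ G + M to a noncentral F whose noncentrality is estimated from
B seeded datasets in which M is permuted within rounded-dosage strata of G
(preserving the G–O and G–M marginals while destroying mediation). Small p4
means the conditional association is significantly weaker than a direct
effect of the observed marginal strength would produce. The omnibus p is
the maximum of the four; calling uses Bonferroni-corrected thresholds
(alpha over the number of triplets tested): SCT if only the C-mediator
direction is significant, STC if only the T-mediator direction, INDEP if
neither, no call if both. The consensus is the BN call when both methods
agree, otherwise none. Because p4 uses a parametric reference distribution
with an estimated noncentrality rather than an empirical permutation
p-value, it can fall below 1/B, which Bonferroni calling requires.

`trans_assoc_variance_explained()` reports the fraction of the variant's
trans effect removed by conditioning on the cis gene as
`1 − (slope of G in T ~ G + C / slope of G in T ~ G)²`, clamped to [0, 1].
Naive residualization of T on C was rejected: the cis gene is itself a
proxy for the variant, so residualizing on it absorbs part of a purely
direct G→T effect and reports spurious mediation (~0.33 for an independent
triplet with 20%/20% effects); the conditional-slope form is exactly 1
under full mediation, ~0 under independence, and monotone in mediation
strength.

## Preprocessing

`log2_quantile_normalize()` log2-transforms raw intensities,
quantile-normalizes each individual's technical replicates against each
other, averages them, then quantile-normalizes the per-individual columns
(the quantile engine is limma's, with tied values receiving the mean of the
quantiles they span). One subtlety: replicate averaging can create exact
ties — after within-individual normalization both replicates are
permutations of the same quantile vector, so rows with swapped ranks
average identically — and the tie convention then makes sorted columns
agree only up to tie-averaging rather than exactly. On tie-free input the
post-normalization columns are exactly equal as multisets, and the
operation is idempotent.

`pca_outlier_filter()` excludes samples whose scores on the first `n_pcs`
(default 2) principal components deviate from the mean by more than
`sd_mult` standard deviations. The literal one-standard-deviation rule is
the default, but note that under approximately Gaussian scores it removes
~32% of samples per component — far more than the few percent such filters
usually target — so `sd_mult` is exposed as a parameter and 3 is a
reasonable practical value. Whether published versions of this rule meant
literal 1 sd or something stricter is ambiguous; the parameter, not a
guess, carries that ambiguity. Zero-variance components flag no outliers.

`standard_normalize()` is the rank-based inverse normal transform
`qnorm((rank − 0.5)/n)` with average ranks on ties — the field's usual
meaning of "standard normalized" expression; it makes linear-model
residualization well behaved and downstream Gaussian node models defensible
regardless of the raw expression distribution.

## Synthetic cohorts: what they emulate and what they do not

`simulate_genotypes()` draws SNP dosages binomial(2, f) with per-variant
frequencies from `maf_range`; LD blocks use a haplotype-copying scheme
(each variant copies a shared block anchor allele with probability
`target_r2^(1/4)`, otherwise draws independently at the block frequency),
which yields the target pairwise dosage r² exactly in expectation, with no
decay inside a block and independence across blocks. CNVs are integer copy
numbers 2 + binomial(2, f); sex-imbalanced CNVs use different carrier
frequencies per sex. Variants are laid out deterministically on synthetic
chromosomes so cis/trans geometry is controllable.

`simulate_expression()` builds each cis gene as
`sum(sqrt(ve_i) * standardized dosage) + polygenic + noise` with component
variances `ve_i`, `h2 − sum(ve)` and `1 − h2`: variance-explained and
heritability targets are hit exactly in expectation because every component
is scaled against realized dosage variance. Mediation triplets overwrite
the involved genes: SCT builds T from standardized C, STC the reverse,
INDEP gives both genes independent regressions on the variant. Noise is
Gaussian — harmless for rank-based or inverse-normal-transformed inference,
and it makes the variance budgeting exact. Sex effects are additive mean
shifts on designated probes.

Scenario presets fix the study conditions used throughout the tests:
`null` (500 probes, 2000 variants, n = 400, no effects), `cis_only` (100
genes with one 10% cis variant, h² = 0.3, plus 100 nulls, n = 800),
`multi_cis` (50 genes with two independent 10% variants, n = 800),
`mediation` (10 SCT + 10 STC + 10 INDEP triplets with 0.2/0.2 path
variances, n = 800), and `sex_cnv_confound` (sex-imbalanced CNVs plus
sex-differential probes on other chromosomes, n = 400). Effect sizes and
sample sizes mirror the regime of a large array-based cohort: a 10–20%
cis effect at n = 800 is comfortably detectable, a single trans effect of
a few percent is not — which is the regime that motivates the trans-of-cis
strategy.

What the generator does **not** emulate: population structure and
relatedness, imputation uncertainty, LD decay within blocks or any
realistic recombination map, probe-level hybridization artifacts beyond
the QC flags, non-Gaussian expression noise, and batch effects. Passing
recovery tests therefore demonstrates the *procedures* are correct and
calibrated under their stated assumptions, not that real-data thresholds
or discovery counts would be reproduced.

## Numerical choices and degenerate inputs

- Ties: average ranks everywhere (Spearman, inverse-normal transform);
  quantile normalization averages spanned quantiles.
- Best-per-probe ties on p are broken by record order (stable, then
  order-independence of scans is asserted separately).
- Constant vectors error in `spearman_test`, `standard_normalize` and the
  BN/CIT fits; monomorphic simulated variants error at generation.
- Collinearity guards: conditional acceptance stops at dosage R² > 0.999;
  `variance_explained` errors on singular designs.
- `|rho| = 1` maps to the smallest positive normal double; `neglog10`
  arithmetic stays in log space.
- FDR selection uses `r/(n_perm + 1)`; thresholds returned are always
  elements of the null (or 0 when nothing passes).
- Empirical p-values use the `(1 + #{null >= obs}) / (n_perm + 1)`
  convention, bounded below by `1/(n_perm + 1)`.
- Every stochastic function takes an explicit integer seed and is
  byte-reproducible given it.

## Problem sizes in the test suite

The suite runs the calibration and recovery experiments at deliberately
chosen sizes: 20 seeded null cohorts with 200 permutation rounds for FDR
calibration; 30 triplets with B = 500 CIT replicates for causal recovery;
100 seeded replicates for two-variant conditional recovery; m = 10⁴
p-values for π1 recovery; full enumeration of 5040 orderings for the n = 7
Spearman oracle. These sizes give the Monte Carlo checks comfortable margins
while keeping the whole suite under a couple of minutes on one core.

## Known limitations

- Only the three fixed anchored networks are compared; no structure
  learning, hidden confounders, or >3-node models.
- The CIT component p4 follows the stratified-permutation scheme described
  above; it is validated by calibration and recovery experiments, not by
  formula identity with other implementations.
- Heritability is an input (an external estimate per probe); the package
  does not estimate it.
- Matched-variant enrichment treats overlap as variant identity; LD-aware
  colocalization is out of scope.
- No covariate-adjusted association models, phased haplotypes,
  multi-allelic records beyond a dosage, or binary genotype formats.
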