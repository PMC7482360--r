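---
title: "Methods: conditional analysis, fine-mapping and polygenic scores for blood-trait GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional analysis, fine-mapping and polygenic scores for blood-trait GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemegwas)
```

# Scope and model

Large genome-wide association studies of blood-cell traits (counts and
indices of red cells, white-cell subtypes and platelets) rest on a small
set of bespoke statistical procedures layered on top of ordinary
regression: rank-based phenotype normalization, an exact stepwise
conditional analysis that resolves association signals into conditionally
independent sentinel variants, Bayesian fine-mapping of those sentinels
into credible sets, inverse-variance meta-analysis across cohorts, a
battery of coexpression-network tests motivated by the omnigenic model
(a small core of disease genes trans-regulated by a large periphery),
polygenic scores built from the discovered variants, and saturation curves
describing how discoveries grow with cohort size. `hemegwas` implements
each of these as a tested, composable function, and pairs them with a
seeded synthetic-cohort generator so the entire pipeline can be exercised,
and its operating characteristics measured, without access to any cohort
data.

All user-facing functions take data frames (tibbles) first and return
tibbles, so analyses chain with the pipe; genotype dosages live in a light
`geno_matrix` container (a samples-by-variants numeric matrix plus variant
metadata and sample covariates).

# Phenotype preparation

Raw blood counts are filtered with the standard clinical extreme-value
exclusions (WBC > 200×10⁹/L, hemoglobin > 20 g/dL, hematocrit > 60%,
platelets > 1000×10⁹/L); white-cell subtype counts are derived as total
WBC times the subtype proportion. Traits are regressed on age, age², sex
and principal components by OLS (WBC-related traits log10-transformed
first), and the residuals are mapped to normal quantiles by a rank-based
inverse-normal transform.

Two conventions here are genuinely open and were fixed once:

* **Rank offset.** `inverse_normal_transform()` uses the Blom offset,
  `z = Φ⁻¹((r − 3/8)/(n + 1/4))`. Any offset in common use changes the
  output by O(1/n); Blom is the standard epidemiological choice.
* **Ties** receive average ranks, so tied measurements map to equal
  z-scores and the transform is symmetric.

The transform is idempotent (ranks are preserved), order-preserving, and
its output has mean ≈ 0 and variance ≈ 1 (the Blom variance is slightly
below 1 at finite n; no post-standardization is applied). Clinical and
medication exclusions are modeled as a pass-through boolean flag — the
package does not encode ICD logic.

# Association and meta-analysis

`single_variant_scan()` fits per-variant OLS of the adjusted phenotype on
allele dosage under the additive model. The study this design follows used
linear mixed models to absorb relatedness; the synthetic cohorts here are
unrelated by construction, for which the mixed model reduces to OLS — a
documented divergence, not an approximation error at the scale tested.

Cohorts are combined by inverse-variance weighted fixed effects
(`meta_fixed_effects()`), with alleles harmonized to the
`chrom:pos_allele1_allele2` convention (alleles ordered lexicographically,
indels shorter-first; equal-length indels fall back to lexicographic
order — a convention the identifier scheme does not pin down). QC removes
variants with INFO ≤ 0.4 or minor allele count ≤ 5 (≤ 20 for very large
cohorts). Two significance constants recur: 8.31×10⁻⁹ for the conditional
analysis and 5×10⁻⁹ for the meta-analysis stage; both are arguments, not
hard-wired.

# Exact stepwise conditional analysis

Genome-wide significant variants of one trait are partitioned into blocks
such that adjacent blocks are at least 5 Mb apart (maximizing the number
of blocks) and no block exceeds 2,500 variants; oversized blocks are split
at their largest internal gaps, with ties broken toward the most balanced
cut so progress is guaranteed. Within each block, `stepwise_select()` runs
the add/remove stepwise regression: seed with the best univariable
variant; repeatedly add the candidate with the smallest coefficient
t-test p-value in the augmented model while that p-value is ≤ 8.31×10⁻⁹,
skipping candidates in LD r² > 0.9 with any model member; after each
addition, drop members whose drop-one p-value is at or above the
threshold, worst first. The high-LD skip applies to additions only, as the
algorithm is stated. Addition p-values are computed by
Frisch–Waugh–Lovell residualization (numerically identical to the naive
nested-model t-test, which the test suite verifies against a plain `lm()`
implementation). Selected variants from all blocks of a chromosome are
then refit jointly and the algorithm resumes at the removal stage
(`chromosome_joint_refine()`), which eliminates duplicated signals that
block boundaries kept apart. Ties in the minimum p-value resolve to the
lower genomic coordinate, making output deterministic. A hard iteration
cap guards the (provably terminating) loop.

Sentinels across traits are clumped into loci greedily by best p-value
with an r² > 0.8 membership rule (`ld_clump()`); between-tag r² ≤ 0.8
holds by construction. LD is always computed from the analysis samples
themselves.

# Fine-mapping

Regions are ±250 kb windows around sentinels, merged when overlapping,
with the maximum causal count K equal to the number of sentinels merged
in. Posteriors are computed by **exhaustive enumeration** of all causal
configurations of size 1..K — replacing the stochastic shotgun search of
conventional fine-mapping tools with an exact computation that is entirely
adequate at these region sizes (a guard refuses more than 2×10⁶
configurations). The configuration Bayes factor uses the standard
summary-statistic Gaussian model: with LD matrix `R` and effect-prior SD
`s = 0.08`, the z-scores of configuration γ are `N(0, R_γγ + n s² R_γγ R_γγ)`
under the causal model versus `N(0, R_γγ)` under the null. For a single
variant this reduces exactly to the Wakefield approximate Bayes factor,
which the tests require to 10⁻¹⁰ relative error; multi-variant Bayes
factors are checked against a Gauss–Hermite quadrature oracle. The
configuration prior is uniform over k ∈ {1..K} and uniform within k — the
only prior information used is K and s.

The 95% credible set is the smallest PIP-ordered prefix of variants whose
*configuration coverage* (summed posterior of configurations intersecting
the prefix) reaches 0.95; for K = 1 this is exactly the summed PIP. Sets
are per-region, not per-signal (the per-signal reading is a possible
alternative the interface does not currently expose). Boundary ties are
resolved deterministically in variant order so the set remains minimal —
with uniform PIPs over 100 variants the set has exactly 95 members.
Configurations whose LD submatrix is singular (perfectly correlated
variants) are skipped with a log message rather than failing the region.

# Coexpression-network battery

The omnigenic-model tests all reduce to comparisons against permutation or
matched nulls:

* `overlap_enrichment()` — observed overlap of a query gene set with an
  annotated set versus uniform same-size draws from the universe; fold
  enrichment is observed over null mean and the p-value uses the add-one
  estimator `(1 + #{null ≥ obs})/(n_perm + 1)`, floored at
  `1/(n_perm+1)` (10,000 permutations by default, matching the convention
  of reporting `p < 10⁻⁴` at the floor).
* `degree_test()` — per-gene link counts at a hard correlation cutoff,
  core versus non-core, one-sided Wilcoxon. Edges use |correlation| >
  cutoff: the underlying procedure is stated for positive cutoffs only,
  and the absolute value extends it symmetrically to negative
  coexpression.
* `core_coexpression_test()` — median absolute core–core correlation
  versus equal-sized random gene draws.
* `matched_effect_comparison()` — per annotation class, MAF-matched
  controls for core-gene variants, fold change of median absolute effect
  sizes, Wilcoxon p; classes with fewer than 10 variants in either group
  are skipped and logged.
* `trans_eqtl_enrichment()` — per-gene trans-eQTL counts, core versus
  non-core genes matched on rank-inverse-normalized median expression and
  mean |Z| (absorbing detection-power differences), Wilcoxon p and a mean
  count ratio.
* `neighbor_enrichment()` — enrichment of a query set among first- or
  second-degree network neighbors of core genes (1,000 permutations by
  default).

Matching is greedy nearest-neighbor without replacement on rank-scaled
covariates; it is deterministic (treated items processed in covariate
order, distance ties to the lowest index). A dedicated matching package
would be interchangeable here; the greedy matcher keeps the dependency
surface small and its balance is verified by a rank-test post-check in the
suite.

# Polygenic scores

`select_variants()` implements the four selection strategies compared in
blood-trait PGS work: (a) all variants after greedy LD pruning at r² 0.8,
(b) pruned variants passing one of the GWAS p-value thresholds
{0.05, 5×10⁻⁴, 5×10⁻⁶, 5×10⁻⁸} — all four are meant to be evaluated and
compared, the package does not auto-pick one unless the user scores a
validation cohort — (c) sentinels plus fine-mapped variants with PIP >
0.5, (d) sentinels only, with joint-model betas when available. Weights
are oriented to trait-increasing alleles so all stored weights are
non-negative; scores are weighted allele-dosage sums standardized to unit
SD. Missing dosage entries are mean-imputed from the sample allele
frequency (the default of standard scoring tools). Evaluation is Pearson
R and R²; disease associations are logistic models reporting the odds
ratio per SD of the score with Wald confidence intervals, refusing
diseases with fewer than 40 cases and fits showing separation. Carrier
penetrance uses the 2×2 cross-product odds ratio with a Woolf interval
and the Haldane–Anscombe 0.5 correction for zero cells (the suite checks
it agrees with the covariate-free logistic fit to 10⁻⁶). The
PGS-deviation check flags carriers beyond k = 2 population SDs and runs a
logistic group test when there are more than 10 carriers, otherwise only
the threshold flags and a binomial tail test.

# Discovery saturation

`fit_saturation_models()` fits `y ~ x`, `y ~ √x`, `y ~ √x + x` and
`y ~ log x` to (cohort size, discovery count or heritability) points and
selects by AICc, with the correction term computed on the regression
coefficient count (the error variance is profiled). The selection
criterion itself is a labeled package choice — "best fitting" admits many
readings — and AICc has the useful property that with only four cohorts
the saturated three-coefficient form is ineligible (its small-sample
correction is undefined), so it cannot win trivially by interpolation;
with five or more points it competes normally. `project_discovery()`
evaluates the chosen curve at a new cohort size and also reports the naive
linear projection through the first three points for comparison.

# The synthetic-cohort generator

The generator defines the study conditions under which the pipeline's
operating characteristics are measured.

* **Genotypes.** Variants are organized in haplotype blocks. Each block
  has a pool of 20 founder haplotypes drawn from an AR(1) Gaussian copula
  (lag-1 latent correlation 0.95) thresholded at per-variant allele
  frequencies drawn uniformly from the configured MAF range; sample
  haplotypes are mosaics of the founders with a 10% per-step switch rate.
  This produces realistically decaying within-block r² (adjacent-variant
  r² around 0.3–0.6, near zero across blocks) with very little machinery.
  The 20-founder pool quantizes realized frequencies (binomial noise
  around the target; occasional monomorphic draws at low MAF) — analyses
  that need a fine frequency spectrum raise `n_founders`. Dosage mode adds
  Gaussian noise to the hard calls and records INFO as the ratio of
  Hardy–Weinberg expected to observed dosage variance, capped at 1, so
  the QC filter acts on something real.
* **Phenotypes.** Sum of sparse causal effects on centered dosages, a
  dense polygenic background rescaled to exactly its configured variance
  fraction, covariate effects (age ~ U(40, 70), sex ~ Bernoulli(0.5),
  PCs ~ N(0, 1) — ranges chosen as typical of adult biobank cohorts), and
  Gaussian noise filling the variance budget to 1; the budget being
  exceeded is an error, not a warning. True effects are stored for
  recovery tests. Trait heritabilities are free parameters of the
  generator, not calibrated claims about any real trait.
* **Networks.** A background of near-zero correlations, sparse edges with
  correlations in [0.25, 0.5] at an edge probability giving non-core
  genes `base_degree` expected partners (core genes
  `core_degree_multiplier` times more), and all core–core pairs drawn
  around `core_mutual_correlation`. The assembled matrix is projected to
  the nearest positive semi-definite correlation matrix when needed.
  Setting the multiplier to 1 and the core correlation to 0 recovers an
  exchangeable null.
* **Trans-eQTLs.** Records are allocated to target genes multinomially
  with core genes weighted by the enrichment fold; |Z| and per-gene
  expression are identically distributed for core and non-core genes, so
  the matched comparison is confounder-free by construction.
* **Disease.** Labels follow a logistic model in the standardized score
  with the intercept calibrated numerically to the target prevalence.

Every generator is seeded and bit-reproducible, and restores the caller's
RNG state.

**What passing tests do and do not show.** The generator reproduces the
statistical *structure* the methods assume — blockwise LD, sparse +
polygenic trait architecture, hub-like core genes — but not coalescent
genealogies, imputation artifacts beyond simple dosage noise, relatedness
or population structure (the mixed-model layer is out of scope), or the
X chromosome. Operating characteristics measured here (recovery rates,
credible-set coverage, null calibration) therefore validate the
implementation under its own assumptions; they are not forecasts of
performance on any particular real cohort.

# Problem sizes used in the checks

The packaged checks run the conditional analysis on blocks of 200
variants at n = 5,000 with three strong causal variants (effects specified
on the z scale, expected marginal |z| = 8) and on 500 null blocks;
fine-mapping coverage on 200 single-causal regions of 50 variants;
network tests on 250-gene networks with 20 core genes (degree multiplier
5, core correlation 0.3, trans-eQTL enrichment 2); PGS recovery on a
20,000-sample split-half cohort with 50 causal variants explaining 25% of
variance; and saturation fits on four cohort sizes spanning 35k–400k.
These sizes were chosen so every property is measured with comfortable
Monte-Carlo margin while the whole battery remains quick on one CPU.

# Known limitations

* OLS stands in for the mixed model; conclusions about relatedness
  handling are out of scope.
* Summary-statistic conditional analysis (GCTA-COJO style) is not
  implemented; the conditional analysis here requires individual-level
  (synthetic or user-supplied) genotypes.
* Credible sets are per-region; per-signal sets for K > 1 are not
  exposed.
* Heterogeneity statistics (Cochran's Q, I²) are deliberately absent from
  the meta-analysis module.
* The permutation universe for real-data network tests must be supplied
  by the user; synthetic mode uses the simulated gene universe.
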