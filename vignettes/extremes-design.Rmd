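---
title: "The PRS-extremes design: models, parameters, and validation"
author: "extremescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PRS-extremes design: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design

`extremescan` implements a phenotype-agnostic association design. An
external ("base") GWAS supplies per-variant effect estimates; a
clumping-and-thresholding polygenic risk score (PRS) is computed for every
individual in a target cohort; the top and bottom tails of the score
distribution become surrogate cases and controls; and a covariate-adjusted
logistic GWAS contrasts them. Downstream, the hits are organised into
genomic risk loci, compared against the base study, and the extreme groups
are characterised by gene-set enrichment, LD score regression, and a
phenome-wide scan.

The statistical logic is deliberately circular in one respect and that
circularity is the point: because group membership is defined by a genetic
score, any variant correlated with the score — through being included in
it, through LD with included variants, or through genuine shared
architecture — is truly associated with membership. The genomic inflation
factor of the extremes GWAS is therefore expected to be far above 1, and
the package treats a large lambda as a property of the design rather than
as confounding to be corrected. Conversely, for variants *independent* of
the score the test must be exactly calibrated; this separation is what the
validation suite checks.

## Models and statistics

**PRS.** Greedy clumping visits candidates (p below `clump_p`) in ascending
p order; each surviving variant becomes an index SNP and removes candidates
within `clump_kb` kilobases at squared dosage correlation `clump_r2` or
above. Index SNPs below `p_threshold` are retained. The score is
`sum_j beta_j d_ij` over harmonized effect-allele dosages; missing dosages
are mean-imputed at twice the cohort effect-allele frequency (the
drop-and-renormalise alternative is documented but off by default); min-max
rescaling to [0, 1] exists only for display and never feeds statistics.
Defaults: `p_threshold = 0.05` (the design's stated inclusion rule),
`clump_kb = 250`, `clump_r2 = 0.1`, `clump_p = 1` (standard scoring-tool
defaults; configurable and logged).

**Extreme groups.** `k = ceiling(q N)` per tail from raw scores. The
ceiling convention reproduces 18,892 from q = 0.05 of N = 377,834 (a floor
would give 18,891). Boundary ties are broken by stable sample-id order with
a warning.

**Extremes GWAS.** Variants pass QC when MAF, Hardy-Weinberg exact-test p
and missing-call fraction clear the thresholds; two presets mirror the two
stages of the design (score construction: MAF ≥ 0.1%, HWE p > 1e-15,
missingness < 1%; GWAS: MAF ≥ 5%, HWE p ≥ 1e-6, missingness ≤ 1%). The HWE
test is the conditional exact test given allele counts, computed by
closed-form enumeration over heterozygote counts; the package's test suite
cross-checks it against an independent probability-recurrence oracle. HWE
is evaluated on the combined two-group sample by default — which sample set
the original design used is unstated, so this is an explicit, overridable
choice. Association is maximum-likelihood logistic regression (IRLS,
relative tolerance 1e-8, 100 iterations) with a two-sided Wald test on the
dosage term, the common GWAS-tool default in preference to LRT or score
tests. Non-convergence or |beta| > 20 is reported as `separated` with no
p-value, mirroring how those tools emit NA under separation. Lambda is the
median chi-square over ok-status variants divided by `qchisq(0.5, 1)`.

**Loci.** Three tiers: independent significant SNPs (greedy clump of
genome-wide significant SNPs at r² 0.6, chromosome-wide window), lead SNPs
(second clump at r² 0.1), and merged genomic loci. Each group's LD-block
envelope is the positional min/max of its members plus candidate SNPs
(p ≤ 0.05, r² ≥ 0.6 with any member); candidates are searched within 1 Mb
of the members — a documented cap that bounds the computation and, at the
in-sample r² threshold of 0.6, does not change results in practice.
Envelopes within 250 kb on one chromosome merge; loci are numbered in
genome order and labelled by the nearest gene of the top SNP (ties: smaller
gene start, then lexicographic id). These tie rules are fixed and
documented, not claimed identical to any external annotation service. The
LD panel defaults to the analysis cohort itself, removing an external-panel
download from the critical path; an external panel can be supplied.

**Base comparison.** For each base-study variant, the lowest-p extremes
variant within a 500 kb flank decides replicated / not replicated; a
reported variant whose own record failed QC is `not_tested` with the QC
reason, so "we could not test it" is never conflated with "it is null".
Novel loci at p ≤ 1e-15 form the strict novel list.

**Enrichment.** Significant SNPs map to genes within ±10 kb of gene
boundaries (inclusive). Overlap p-values are one-sided hypergeometric; BH
FDR is applied across *all* catalog sets with at least one background gene,
while the ≥ 2-gene-overlap rule filters only the reported table — the
multiple-testing universe is ambiguous in the original description, and
counting every tested set is the conservative reading. The background
defaults to all genes in the annotation and is configurable.

**LDSC.** LD scores sum adjusted squared correlations
`r2 - (1 - r2)/(n - 2)` within a 1 Mb physical window (a kb window rather
than centimorgans because synthetic data carry no genetic map). The
heritability regression is two-pass weighted least squares with a free
intercept — an unweighted pass sets heteroskedasticity weights
`1/(l_j (1 + slope l_j)^2)` for the final pass; a two-step update rather
than full iteration matches common practice. Standard errors come from a
delete-one-block jackknife (200 contiguous blocks, reduced to 20 below
2,000 variants). Negative heritability estimates are reported unclamped
and flagged. Genetic correlation regresses the z-score product on LD
scores with the intercept free to absorb sample overlap; `rg` of a trait
with itself is exactly 1 by construction, which the tests assert to 1e-6.

**Phenome scan.** Traits are typed (exactly two values: binary; numeric
with more than 20 distinct values: continuous; numeric with at most 20:
ordered; otherwise unordered — the 20-value cutoff is this package's rule,
standing in for a full field-recoding decision tree, which is out of
scope). The trait is the outcome and group membership the exposure; models
are linear, logistic, proportional-odds, or per-level one-vs-rest logistic
with a within-trait Bonferroni factor. Traits with more than 20% missing
answers are excluded; categorical levels under 200 answers are dropped and
traits left degenerate are excluded with reason `category_size`. The
family-wise threshold is alpha over the number of tests actually performed,
with that number reported. P-values that underflow are clamped at 1e-150
in the signed -log10 plotting column only.

## The synthetic-data generator

Genotypes: within each block, two haplotypes per sample threshold a latent
Gaussian AR(1) process (correlation `rho^|i-j|`) at `qnorm(f)`, so the
effect-allele frequency is exact in expectation and the true dosage-scale
LD is available in closed form from the bivariate-normal orthant — that
closed form is used as an oracle for the LD-score tests. Blocks are
independent. Phenotype: liability is the standardized causal score scaled
to the requested heritability plus independent Gaussian noise, thresholded
at `qnorm(1 - prevalence)`; effects are rescaled to the realized cohort so
the generating heritability is exact in-sample. Covariates mirror a biobank
analysis (sex, year of birth, deprivation index, batch, ten principal
components); the PCs are computed from the realized genotypes so adjusting
for them is meaningful. Base summary statistics are simulated analytically:
the marginal effect of each variant is the LD-weighted sum of causal
effects with correlations taken from the panel *within blocks* (blocks are
independent by construction, and cross-block sample correlation is
O(1/sqrt(n)) noise), and the reported estimate adds Gaussian noise with
`SE = 1/sqrt(n 2f(1-f))`. This keeps the cost O(variants x block width)
instead of simulating an external cohort, at the price of independent
estimation noise across variants — which leaves the LDSC expectation
`E[chi2] = 1 + N h2 l/M` intact, as the recovery tests confirm.

What the generator does *not* emulate: realistic demography, recombination
maps, imputation uncertainty, confounded covariates, assortative mating, or
selection. Passing tests show the machinery is correct and calibrated under
the stated model, not that real-data results are unbiased.

One global seed expands into per-stage child seeds through a documented
polynomial string hash (`childSeed`), so stages are independently
reproducible and reordering stages does not silently reuse streams.

## Validation experiments and their problem sizes

The acceptance suite runs five synthetic experiments, sized for a single
core:

- *Null calibration*: a 40-block scoring chromosome and an independent
  10,000-variant tested chromosome, 8,000 samples, zero heritability, 2,000
  samples per tail. Scoring and testing use disjoint chromosomes because
  score-included variants are mechanically associated with membership even
  under the null; the calibration claim (uniform p, lambda within 0.05 of
  1) concerns variants independent of the score. The polygenic experiment
  is the intended complement: heritability 0.5, 500 causal variants among
  2,500, lambda computed over score-included variants only, expected well
  above 1.5.
- *Design power*: over 50 seeds, a causal variant that is sub-significant
  in a small (n = 5,000) base study is tested under the extremes design and
  under a random case-control design of the same total size; the extremes
  median chi-square is far larger, which is the design's rationale. The
  small base cohort matters: under a huge base study, "sub-significant"
  would imply a negligible effect and both designs would be powerless.
- *LDSC recovery*: 5,000 variants over 200 blocks with heterogeneous rho
  (0 to 0.9), panel of 800, GWAS N of 20,000, heritability 0.3, 20
  replicates. Heterogeneous LD is essential — with identical blocks the LD
  scores barely vary and the regression is unidentified.
- *Phenome-scan recovery*: a binary trait with log-odds 1.0 between groups
  of roughly 2,000.
- *Rare-variant contrast*: deterministic expected genotype counts under
  Hardy-Weinberg at frequencies 4.9e-3 versus 2.2e-3 in two groups of
  18,892; the logistic odds ratio agrees with the 2x2 allele-table odds
  ratio within 5%.

## Numerical choices and degenerate inputs

Monomorphic variants: undefined correlation is treated as r² = 0 in
clumping, excluded with a warning from LD scores, and emitted with missing
statistics and a flag from the base-statistics generator. A degenerate
score distribution (max = min) rescales everyone to 0.5 with a warning;
group assignment still works through the stable id-order tie rule.
Zero p-values on input are clamped to the smallest positive double and
flagged. Harmonization never strand-flips: mismatched alleles are dropped,
and A/T and C/G pairs are dropped by default. Variants are matched on
position and alleles, never on rsid. Coordinates are 1-based inclusive
everywhere except BED interchange, converted at the boundary.

## Limitations

Logistic association is fitted per variant with dense IRLS; at biobank
scale a production run would want a compiled inner loop or a score-test
prefilter. The proportional-odds and one-vs-rest models cover the common
trait shapes but not PHESANT's full recoding tree. LDSC here is the
single-component model — no partitioned heritability, no reference LD-score
downloads. The pipeline's file mode reads VCF/TSV/BED/GMT but assumes a
single genome build; there is no liftover.
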