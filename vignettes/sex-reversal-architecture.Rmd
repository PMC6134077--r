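---
title: "Dissecting the genetic architecture of ZW sex reversal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the genetic architecture of ZW sex reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwgwas)
```

## The problem

In ZW fish such as the Chinese tongue sole, females are the heterogametic
sex (ZW) and males homogametic (ZZ). Some genetic females develop into
phenotypic males ("pseudomales"), which matters economically because
females grow much faster. The reversal trait in this system is governed
by two linked Z-chromosome loci: a hemizygous allele T at a first SNP and
at least one A allele at a second SNP in the third intron of *Dmrt1*
jointly determine reversal, and pseudomales transmit essentially only
Z-bearing sperm, so the unfavorable T-A haplotype is inherited intact by
every genetic-female offspring of a pseudomale.

zwgwas implements the full analysis chain for this architecture: a
forward simulator of ZW family populations, genotype QC and LD
imputation, a realized relationship matrix, a whitened linear mixed-model
genome scan with a genome-wide threshold and a peak support interval,
two-locus penetrance classification, an offspring sex-ratio test under
the no-W-sperm transmission model, and a *Dmrt1* haplotype panel.

## The scan model

Reversal is recorded per individual as `y = 1` (reversed) or `0`. The
scan fits, for each marker genotype $m$ coded 0/1/2,

$$ y = \mu + b\,m + g + e, \qquad
   g \sim N(0, \mathbf{K}\sigma_g^2), \quad
   e \sim N(0, \mathbf{I}\sigma_e^2), $$

against the null model without the marker term. $\mathbf{K}$ is the
realized relationship matrix $\mathbf{Z}\mathbf{Z}'/n_m$ built from
column-standardized genotype codes ([`build_grm()`]); the standard
deviation uses the divide-by-$n$ convention, a global rescaling that the
variance components absorb.

Two deliberate approximations:

* **Liability scale.** A logistic link applied to an individual 0/1
  outcome is undefined at the individual level, so the model is fitted
  as a *linear* mixed model on the 0/1 indicator. This is exactly what
  the whitened regression below computes, and for a binary trait it is
  the usual liability-scale approximation. A penalized-quasi-likelihood
  logistic variant is out of scope.
* **EMMAX-style variance components.** $\sigma_g^2$ and $\sigma_e^2$ are
  estimated once by REML under the null ([`estimate_vc()`]:
  eigendecompose $\mathbf{K}$, profile the restricted likelihood over
  $\lambda = \sigma_g^2/\sigma_e^2$ on a 121-point log grid spanning
  $[10^{-6}, 10^{6}]$, refine by golden-section search) and reused for
  every marker. When $\mathbf{K}$ carries no structure only the total
  variance is identifiable; the profile is flat and a boundary solution
  is returned with a warning.

With $\hat\sigma_g^2, \hat\sigma_e^2$ fixed,
$\mathbf{V} = \mathbf{K}\hat\sigma_g^2 + \mathbf{I}\hat\sigma_e^2$ is
factored once by Cholesky ($\mathbf{V} = \mathbf{L}\mathbf{L}'$, with
one jitter retry of $10^{-8}\,\overline{\mathrm{diag}(\mathbf{V})}$ if
the factorization fails) and every column is whitened:
$y^* = \mathbf{L}^{-1} y$, $\mathbf{M}^* = \mathbf{L}^{-1}\mathbf{M}$.
Each marker test is then ordinary least squares of $y^*$ on the whitened
intercept and $m^*$, with the Gaussian likelihood-ratio statistic
$T = n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ referred to $\chi^2_1$. Tests
verify that $T$ matches a direct generalized-least-squares fit with the
same fixed $\mathbf{V}$ to within $10^{-6}$.

Numerical edge cases are resolved as follows: markers monomorphic in the
cohort (collinear with the intercept, detected at relative determinant
$\le 10^{-12}$) get $T = 0$, $P = 1$ and flag `collinear`; a marker that
separates the phenotype perfectly drives $\mathrm{RSS}_1$ to zero
(relative tolerance $10^{-12}$) and is reported with the smallest
representable positive P-value and flag `underflow` rather than 0; ties
for the peak break by smallest P, then leftmost genomic position.

## Genome-wide threshold and support interval

The genome-wide critical value ([`piepho_threshold()`]) uses the quick
upcrossing approximation for a $\chi^2_1$ scan process: with
$z_i = \mathrm{sign}(b_i)\sqrt{T_i}$ the signed-root profile and $V$ the
summed total variation of $z$ across adjacent markers within
chromosomes,

$$ \alpha(u) \approx C\,P(\chi^2_1 > u) + V\,e^{-u/2}/\sqrt{2\pi}, $$

where $C$ is the number of chromosomes. The equation is solved for $u$
by root finding and clamped into the pointwise-to-Bonferroni bracket
$[\chi^2_{1,1-\alpha},\ \chi^2_{1,1-\alpha/m}]$. Markers with
non-finite statistics are excluded from $V$. The bound is conservative
by construction; a permutation oracle
([`permutation_threshold()`]) is used in the tests to confirm that the
genome-wide false-positive rate stays at or below nominal (the suite
checks $\le 0.10$ at nominal $0.05$ over 200 null scans of a
120-individual, 240-marker population).

The support interval of a significant peak ([`peak_ci()`]) is the
contiguous marker run around the peak where $T \ge T_{peak} - d$ with
$d = \chi^2_{1,\mathrm{level}}$ (3.841 at 95%), extended to the
midpoints between the last inside and first outside markers and clipped
to the chromosome's marker span (or to supplied chromosome lengths).
When the peak statistic is infinite (perfect separation) only perfectly
separating markers fall inside the drop, which is the natural limit of
the rule.

## The simulator as study-condition generator

[`simulate_population()`] generates full-sib ZW families on a marker map
scaled from the reference panel of 33,410 SNPs over chromosomes 1-20, W
and Z ([`default_marker_table()`]). Defaults encode the emulated study
design and were chosen once:

* 9 families, 51 offspring each, so that the expected Z^T W cohort is
  about 171 fish;
* `marker_scale = 0.1` (about 3,300 markers), keeping a full scan around
  a second;
* founder frequency 0.75 for T at the first causal locus and 0.55 for A
  at the second: the study design does not state founder frequencies,
  and these values reproduce both the cohort yield and the observed
  reversal fraction (94/171 ≈ 0.55) in expectation;
* neutral founder frequencies uniform in [0.05, 0.5]; penetrance noise
  and missingness 0 by default.

Meiosis places one uniformly located crossover per paired chromosome.
The Z of a ZW dam has no pairing partner and is transmitted intact, as
is the W; a pseudomale sire transmits its single Z intact and no W, so
pseudomale-sired families are ZW:ZZ ≈ 1:1 and the T-A haplotype never
recombines on that path. Z- and W-linked genotypes of ZW fish are
hemizygous and coded 0/2 on the diploid scale; an optional
`het_locus2_rate` introduces AG heterozygotes at the second locus,
mimicking the rare *Dmrt1* duplication, and such fish carry A and
reverse. ZZ fish have no W and are coded `NA` at W markers.

What the simulator does *not* emulate: genotyping error, linkage maps
(crossover count is fixed at one), environment-dependent reversal
(the emulated design held temperature constant), WW viability beyond
exclusion, and multi-generation pedigrees. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
polygenic-plus-major-locus architecture, not robustness to real-data
artifacts.

## QC and imputation

[`filter_markers()`] applies the strict thresholds MAF < 0.05 and call
rate < 0.80 — a marker exactly at either boundary is retained — and is
idempotent. [`impute_missing()`] predicts each missing call from the 10
nearest observed markers on the same chromosome (both flanks pooled,
distance in bp): each neighbor votes for the genotype class of the
target most frequent among complete-case individuals sharing the
focal individual's genotype at the neighbor, weighted by $r^2$; ties go
to the marker's modal genotype, and calls with no usable neighbor fall
back to the modal genotype with a message. The estimator is validated
by the property that it strictly beats the modal-genotype baseline on
LD-structured simulations, and by exact recovery under perfect LD.

## Two-locus rule, ratio test, haplotypes

[`classify_reversal()`] is the deterministic penetrance rule
(pseudomale iff T and ≥1 A); [`build_two_locus_table()`] tabulates a
cohort and counts disagreements with the rule. On the 259-fish
validation table the rule predicts 44 pseudomales and 215 females with
zero misclassification.

[`offspring_ratio_test()`] tests observed (ZW, ZZ) offspring counts of
pseudomale sires against 2:1 — the expectation if W sperm existed and
WW died — using a chi-square goodness-of-fit test with 1 df. The
chi-square default reproduces the reference P = 0.037 for counts
(24, 22) exactly to the printed precision; an exact binomial option
(one-sided toward the deficit, P ≈ 0.031) is also offered. Which test
produced the published value is not stated; chi-square is the default
precisely because it reproduces it.

[`dmrt1_panel()`] hard-codes the 11 polymorphic sites (9 SNPs, 2
indels) between exon 2 and intron 3 of *Dmrt1*; indel alleles are
literal strings with "/" marking absence, compared by exact match.
Positions run opposite to the gene's orientation and are stored sorted
by coordinate. [`match_haplotype()`] is strict: any covered site
breaking the pattern makes the call `recombinant`, an allele matching
neither haplotype makes it `unknown`. Which haplotype is ancestral is
not inferred.

## Problem sizes used in validation

The shipped tests exercise: a 171-fish, ~3,100-marker cohort scan
(locus recovery at P below $10^{-28}$), 200 null scans of a
120 × 240 design for threshold calibration, 100 replicate 100-fish
cohorts for interval coverage, 25 REML recovery replicates at n = 120,
and GLS-oracle comparisons at n = 50. These sizes were chosen to make
the full suite run in about a minute while leaving each property
clearly resolvable; all of them scale up by changing `sim_config()`
arguments.

## Known limitations

* The liability-scale linear model can be miscalibrated for very rare
  phenotypes or tiny cohorts; the scan's χ² reference is asymptotic.
* The upcrossing threshold is an upper bound and is conservative when
  markers are in strong LD.
* The imputation estimator is a documented in-package choice: the
  neighbor count and LD principle follow the emulated pipeline, but the
  exact published estimator is not reproducible from its description.
* `estimate_vc()` returns boundary solutions (λ → 0 or λ → ∞) silently
  apart from the stored flag when the likelihood is maximized at the
  grid edge — e.g. under full penetrance, where heritability
  approaches 1.
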