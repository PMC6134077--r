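# zwgwas

Genetic architecture of female-to-male sex reversal in ZW fish.

In species with ZW sex determination — the motivating case is the
Chinese tongue sole (*Cynoglossus semilaevis*) — genetic females (ZW)
sometimes develop as phenotypic males ("pseudomales"). Reversal in this
system is controlled by two linked Z-linked loci: a ZW female reverses
iff her single Z carries the unfavorable T allele at one SNP **and** her
genotype at a second SNP, in the third intron of *Dmrt1*, carries at
least one A allele. Because the Z of a ZW fish has no pairing partner
and pseudomales transmit only Z sperm, the T-A haplotype is passed
intact to every genetic-female offspring of a pseudomale.

zwgwas is an R package for analysts working on such systems. It
provides:

* **`simulate_population()` / `sim_config()`** — a forward simulator of
  ZW full-sib families: hemizygous Z/W coding (0/2 on the diploid
  scale), one-crossover meiosis, dams transmitting Z or W, pseudomale
  sires transmitting only the intact T-A Z, and the deterministic
  two-locus reversal rule (with optional penetrance noise and a
  *Dmrt1*-duplication heterozygote option).
* **`filter_markers()` / `impute_missing()`** — marker QC (MAF < 0.05
  and call rate < 0.80 discarded, strict boundaries) and LD-based
  imputation from the 10 nearest informative neighbors.
* **`build_grm()`** — the realized relationship matrix
  `K = ZZ'/n_m` from column-standardized genotypes.
* **`run_gwas()`** — a binary-trait linear mixed-model scan in the
  EMMAX style: REML variance components under the null
  (`estimate_vc()`), Cholesky whitening of
  `V = K sigma_g^2 + I sigma_e^2` (`whiten()`), per-marker
  `T = n log(RSS0/RSS1)` tests against chi-square(1)
  (`scan_markers()`), an upcrossing-approximation genome-wide threshold
  (`piepho_threshold()`), and a drop-based support interval around the
  peak (`peak_ci()`). Returns a classed object with `print()`,
  `summary()`, `coef()` and a Manhattan `plot()` method.
* **`classify_reversal()` / `build_two_locus_table()` /
  `offspring_ratio_test()`** — the two-locus penetrance rule, cohort
  tabulation with misclassification counting, and the ZW:ZZ offspring
  ratio test against 2:1 under the no-W-sperm transmission model.
* **`dmrt1_panel()` / `match_haplotype()` / `count_haplotypes()`** —
  the 11-site *Dmrt1* polymorphism panel (9 SNPs + 2 indels) and strict
  haplotype matching.
* **`run_pipeline()`** — chains simulate → QC → GRM → scan →
  interaction with one seed and a JSON run manifest.

See `vignette("sex-reversal-architecture")` for the model, its
assumptions, and all numerical choices.

## Worked example

Simulate a mapping cohort of 171 Z^T W genetic females (every fish
carries the conditioning T allele, so the scan targets the second
locus), then scan:

```r
library(zwgwas)
sim <- simulate_ztw_cohort(171, sim_config(seed = 11))
fit <- run_gwas(sim$geno, sim$pheno)
fit
#> Mixed-model genome scan (171 individuals, 3118 markers)
#> genome-wide threshold (alpha = 0.05): 18.610
#> peak: Cyn_Z_8564889 (chrom Z, 8,564,889 bp)  T = Inf  P = 2.23e-308
#> 95% support interval: chrom Z, 8,562,904-8,657,112 bp
```

The peak is the simulated causal *Dmrt1* SNP at 8,564,889 bp on Z. Its
statistic is infinite because the locus is fully penetrant in the
cohort — the marker separates reversed from normal fish perfectly — so
the P-value is reported as the smallest representable positive number
with an `underflow` flag (far beyond the genome-wide threshold of
18.6). The support interval (~8.56–8.66 Mb) brackets the causal
position. `plot(fit)` draws the Manhattan plot with the dashed
genome-wide threshold.

The transmission test: pseudomale-sired offspring counts of 24 ZW and
22 ZZ are tested against the 2:1 ratio expected if pseudomales made W
sperm (WW zygotes die):

```r
offspring_ratio_test(24, 22)
#> offspring ZW:ZZ ratio test (chisq) vs 2:1
#> observed ZW = 24, ZZ = 22
#> X-squared = 4.3478, df = 1, P = 0.03706
```

P < 0.05 rejects 2:1 — the observed ratio is ~1:1, consistent with
pseudomales producing no W sperm. The penetrance rule itself:

```r
classify_reversal(c("T", "T", "A"), c("AA", "GG", "AG"))
#> [1] "pseudomale" "female"     "female"
```

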