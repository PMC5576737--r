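---
title: "Methods: conditional and conjunction FDR for cross-trait GWAS analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional and conjunction FDR for cross-trait GWAS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiocfdr)
```

## The model

Given two GWAS of related traits, summarized as per-SNP p-values
$p_1$ and $p_2$ over a shared SNP set, the conditional false discovery rate
for SNP $i$ with trait 1 as the principal phenotype is

$$\mathrm{cFDR}(p_1^{(i)} \mid p_2^{(i)}) =
  \Pr\!\big(H_0^{(i)} \mid P_1 \le p_1^{(i)},\, P_2 \le p_2^{(i)}\big),$$

the probability that SNP $i$ is null for trait 1 given that both of its
p-values are at least as extreme as observed. `empirical_cfdr()` estimates
it by the empirical ratio

$$\widehat{\mathrm{cFDR}}^{(i)} = p_1^{(i)} \times
  \frac{\#\{m : p_2^{(m)} \le p_2^{(i)}\}}
       {\#\{m : p_1^{(m)} \le p_1^{(i)},\ p_2^{(m)} \le p_2^{(i)}\}},$$

capped at 1. The numerator-over-denominator fraction is the reciprocal of
the empirical conditional CDF $\hat F(p_1 \mid P_2 \le p_2)$, so the
estimate is the principal p-value deflated by how strongly small trait-1
p-values concentrate among SNPs that are also extreme for trait 2. All
counts are inclusive ($\le$): every SNP counts itself, the denominator is
at least 1, and tied p-values are handled symmetrically, which makes the
result invariant under row permutations. When all conditional p-values are
equal the estimate collapses to the Benjamini–Hochberg-style quantity
$p \cdot N / \mathrm{rank}(p)$ (ranks with inclusive ties); this reduction
is asserted exactly in the tests.

The conjunction cFDR is the elementwise maximum of the two directional
estimates, `ccfdr = max(cfdr_1_given_2, cfdr_2_given_1)`, estimating the
probability that a SNP is null for *either* trait. Significance uses the
strict rule `value < alpha` with `alpha = 0.05` by default, in both the
directional and conjunction calls, matching the conventional
$-\log_{10}$ threshold of 1.3 on Manhattan plots.

Assumptions worth stating: the two studies are independent (no sample
overlap), p-values are valid under their own nulls (genomic control, if
needed, is assumed already applied upstream), and the SNP set has been
thinned to approximate linkage equilibrium so the empirical CDFs are not
dominated by a few long LD blocks. The estimator is a point estimate of a
posterior probability, not a sampling-variance-adjusted quantity; calls
near the threshold should be read accordingly.

### Computation

A naive evaluation of the denominator is $O(N^2)$. `empirical_cfdr()` uses
a Fenwick-tree sweep over SNPs sorted by the principal p-value, inserting
groups of tied values before querying them, which reproduces the
double-loop counts *exactly* (asserted on hundreds of random instances,
ties included) in $O(N \log N)$. An optional `monotone = TRUE` replaces
each estimate by the maximum over all SNPs it dominates in both p-values
(a two-dimensional cumulative maximum, computed by a prefix-max variant of
the same sweep). That enforces that the cFDR never decreases as the
principal p-value grows within any conditioning stratum. It is off by
default: the plain ratio is the standard estimator, and the smoothing is a
strictly more conservative post-processing.

## LD pruning

`ld_prune()` implements a windowed greedy scan over dosage genotypes:
within each chromosome a window of `window = 20` SNPs (counted in SNPs, not
kb) is scanned; every within-window pair with squared Pearson correlation
$r^2 >$ `r2_max = 0.2` is broken by removing the member with the smaller
minor allele frequency; pair evaluation then restarts over the window's
remaining members; once the window is clean it advances by `step = 5` kept
SNPs; and whole passes repeat until one removes nothing, so the terminal
state is clean regardless of window/step interactions. Two points were
genuinely open and are fixed here as package policy: (i) pair evaluation
restarts after each removal (rather than continuing mid-scan), which makes
the outcome independent of transient pair ordering after a removal; and
(ii) "LD" is read as $r^2$, the conventional scale for pruning thresholds.
Exact MAF ties are broken by removing the SNP at the larger genomic
position, for determinism. The tests compare the implementation against an
independently written literal transcription of this scan on block-LD
fixtures, and verify directly that no kept pair co-occurring in a window
exceeds the threshold.

When no genotype panel is available the pipeline accepts a pre-pruned SNP
list, or skips pruning; pruning real data against a reference panel is the
user's choice of panel and is out of scope here.

## Harmonization

`harmonize_merge()` keys on rsid (both source studies in the motivating
analysis are rsid-indexed meta-analyses); chrom/pos are carried for
plotting and region labels, and shared rsids whose coordinates disagree are
dropped rather than arbitrated. Identical allele pairs merge as `direct`;
pairs matching after base complementation merge as `strand_flipped`;
palindromic (A/T, C/G) SNPs are dropped by default because strand cannot be
resolved without allele frequencies and effect directions are not needed
for cFDR — dropping is the conservative choice, switchable with
`drop_ambiguous = FALSE`. Zero p-values are floored (default `1e-300`,
`apply_p_floor()`) so that $-\log_{10}$ and the cFDR ratio stay finite;
published loci carry p-values as small as $10^{-250}$, so the floor must
sit well below the data. Positions are 1-based and the bundled MHC
coordinates assume GRCh37.

## Conditional Q-Q diagnostics

`conditional_qq_data()` stratifies the principal p-values by conditional
thresholds $p_2 \le 1, 0.1, 0.01, 0.001$ (the customary ladder). Within a
stratum of size $n$, rank $r$ is plotted at empirical quantile $r/(n+1)$ —
the $n+1$ denominator keeps the top rank off $-\log_{10}(0)$; the package
does not attempt to match any particular plotting convention beyond this.
Enrichment appears as leftward/upward deflection of tighter strata.
`qq_shift()` quantifies it: the median, over a grid of matched quantiles,
of the difference in nominal $-\log_{10} p$ between a stratum and a
reference, with each curve linearly interpolated at the grid. The grid is
uniform on the *quantile* scale over the overlap of the two strata's
quantile ranges. A grid uniform in $-\log_{10} q$ would concentrate the
median in the extreme tail, where small strata carry almost no
information; the quantile-scale grid makes the statistic reflect the bulk
of the distribution, keeps the identities exact (a stratum against itself
gives 0; scaling all p-values by 0.1 gives exactly 1), and allows a
Kolmogorov–Smirnov band to bound its null behaviour, which the tests use.

## The synthetic-data generator

`simulation_config()` / `simulate_summary_pair()` define the validation
conditions. Each SNP draws one of four classes — null/null, trait-1 only,
trait-2 only, shared — with probabilities `class_probs`; the default
`(0.90, 0.025, 0.025, 0.05)` represents a realistic two-trait setting in
which most SNPs are null and shared effects are as common as single-trait
ones. Non-null z-scores follow the scale mixture $z \sim N(0, 1+\tau^2)$
with $\tau = 4$ by default — symmetric and sign-free, matching the
two-sided p-values and the empirical-Bayes setting of the cFDR literature;
a location-shift alternative was considered and rejected because the
estimator never uses effect direction. p-values are computed exactly as
$2\Phi(-|z|)$, never resampled, so truth labels and statistics are coupled
only through the class assignment. Genotypes (for pruning) are two latent
AR(1) haplotypes per individual, correlation `rho = 0.8` within blocks of
`block_size = 10` SNPs, thresholded at each SNP's MAF quantile and summed —
simple, reproducible block LD. The root seed feeds four deterministic
sub-streams (classes/layout, z1, z2, genotypes), so, e.g., skipping
genotype generation leaves the summary statistics bit-identical.

What the generator does *not* emulate: the effect-size and MAF joint
distribution of real meta-analyses, imputation uncertainty, sample overlap,
population stratification, or long-range LD beyond the block structure.
Passing tests therefore demonstrate correctness of the machinery and
sensible operating characteristics under an idealized two-trait model, not
calibrated FDR on any particular real dataset. Synthetic allele pairs are
drawn from the non-palindromic set only, so simulated pairs survive the
ambiguity filter intact.

## Operating characteristics computed by the tests

The suite (fixed seeds throughout) runs: 20 replicates of an all-null model
at $N = 20{,}000$ SNPs, where the fraction of directional cFDR $< 0.05$
calls stays below $0.05$ plus three binomial standard errors (empirically
it is orders of magnitude smaller — under the global null the estimator is
strongly conservative); and 50 replicates with a 5% shared class at
$\tau = 4$, where the mean realized conjunction FDR stays at or below 0.10
and conjunction power exceeds per-trait Bonferroni at the same nominal
level. These sizes were chosen as the smallest at which the binomial bounds
are meaningful for a 5% rate. Q-Q enrichment is checked on a 10%-shared,
$\tau = 3$ model (shift strictly increasing along the threshold ladder) and
on the all-null model (shift within a KS-band-derived bound of 0). Pruning
fixtures use up to 500 SNPs.

## Known limitations

- The estimator shares the cFDR literature's caveat: it controls a
  posterior-probability-style quantity per SNP, not family-wise error, and
  LD pruning is a prerequisite, not a cure, for correlated tests.
- The conjunction maximum is conservative when the two directional
  estimates are strongly dependent.
- MHC class I/III/II boundaries are conventional GRCh37 coordinates exposed
  in `region_config()`; region labels are annotations, not tests.
- Gene/role annotation is a pass-through from a user-supplied map; no
  external annotation service is queried.
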