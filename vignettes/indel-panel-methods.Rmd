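---
title: "Methods: forensic and population-genetic analysis of biallelic InDel panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forensic and population-genetic analysis of biallelic InDel panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popindel)
```

popindel analyses diploid genotype panels of biallelic insertion/deletion
markers — the marker class of commercial 30-locus forensic kits — from raw
genotype tables through forensic efficiency parameters, equilibrium and
linkage screens, population differentiation, genetic distances and trees,
PCA, and model-based ancestry inference. This vignette is the package's
account of the models it fits, the estimators it chose where several are
in circulation, the numerical decisions that make outputs reproducible to
the byte, and what its synthetic-data tests do and do not establish.

## Data model

A `genotype_dataset` stores the dosage of the Insertion allele (`II` = 2,
`ID`/`DI` = 1, `DD` = 0) with `NA` for missing genotypes. Because the loci
are strictly biallelic, the Insertion allele is the counted allele
everywhere; the deletion frequency is always derived as `1 - p_ins`,
never stored, so the two can never disagree. Missing data are handled by
locus-wise complete-case analysis — a sample missing one locus still
contributes everywhere else — because all per-locus statistics condition
on the typed genotypes at that locus only. How missing genotypes arise is
not modelled.

## Forensic efficiency parameters

For genotype counts `(n_II, n_ID, n_DD)` at one locus, with
`h = n_ID / n` (observed heterozygosity), `p` the insertion frequency and
`q = 1 - p`:

| quantity | formula |
|---|---|
| He  | `2pq` |
| PIC | `1 - p^2 - q^2 - 2 p^2 q^2` |
| MP  | sum of squared **observed** genotype frequencies |
| DP  | `1 - MP` |
| PE  | `h^2 (1 - 2 h (1-h)^2)` |
| TPI | `1 / (2 (1-h))` |

Two conventions needed deciding, and both are settled by which variant
reproduces published survey tables from their own printed inputs:

* **He without the small-sample correction.** The `2n/(2n-1)` unbiased
  estimator cannot produce the value 0.5000 that surveys print for a
  locus at `p = 0.5` with n in the hundreds (it gives 0.50049 at
  n = 513); the uncorrected `2pq` can. The corrected variant is available
  via `expected_heterozygosity(p, unbiased = TRUE, n = n)` but is off by
  default.
* **MP from observed genotype frequencies**, not Hardy-Weinberg expected
  ones — the spreadsheet convention of forensic practice. The two differ
  in the third decimal on real-sized samples.

`PE(0.5283) = 0.2135` and `PE(0.3548) = 0.0887` to four decimals, the
extremes a 30-locus survey reports; human-readable output rounds half-up
to 4 decimals (the spreadsheet convention) while machine output keeps
full precision. Combined powers are evaluated in log space
(`CDP = -expm1(sum(log(MP)))`), so a CDP of `1 - 9e-13` is representable
instead of collapsing to 1.

## Hardy-Weinberg and linkage screens

The exact test conditions on the observed allele counts and enumerates
every genotype configuration with a heterozygote count of matching
parity, weighting each by `n! / (n_II! n_ID! n_DD!) * 2^n_ID`. The
two-sided p-value sums configurations no more probable than the observed
one (probability-ordering rule, the standard biallelic convention). Ties
are compared with a `1 + 1e-12` relative guard so floating-point jitter
cannot drop the observed configuration itself. A 1-df chi-square test
(no continuity correction) is provided as a large-sample cross-check;
it is undefined at monomorphic loci, where the exact test returns 1.

Pairwise LD is measured as `r^2` on haplotype frequencies estimated by EM
under within-locus Hardy-Weinberg — only the double heterozygote is
phase-ambiguous, and the EM splits it between coupling and repulsion in
proportion to current haplotype products. Initialisation is at linkage
equilibrium, tolerance `1e-8` on the largest frequency change, at most
1,000 iterations; the log-likelihood is asserted non-decreasing at every
iteration. The screen applies the conventional `r^2 < 0.1` independence
rule rather than permutation p-values, matching how such surveys report
LD. Monomorphic loci are skipped with a warning and listed in the result.

## Population differentiation

The package estimates Fst with the Weir-Cockerham (1984) variance
components `a` (between populations), `b` (between individuals within
populations) and `c` (within individuals), computed from sample sizes,
allele frequencies and observed heterozygote frequencies; the multi-locus
estimate is the ratio of summed components. This θ was preferred to an
AMOVA Φ formulation because for codominant biallelic genotypes the two
coincide at the levels fitted here and θ has an unambiguous published
closed form against which the implementation can be checked. Negative
estimates are reported as computed — clamping would bias the calibration
tests — and only the heat-map-ready long export floors them at zero.

Significance comes in two forms: a permutation test on θ (individuals
permuted between the two populations, sizes fixed;
`p = (1 + #{θ* >= θ_obs}) / (n_perm + 1)`, default `n_perm = 10000`,
seed mandatory) and, per locus, Fisher's exact test on the 2x2
insertion/deletion allele-count table, which is fast, deterministic and
matches the per-locus reporting style of population surveys.
"Significant at k loci" always means Bonferroni within the comparison
across the panel's loci (0.05/30 reported as 0.0017).

## Distances and trees

Nei's D_A for biallelic loci is
`1 - mean_l [sqrt(p_A p_B) + sqrt(q_A q_B)]`; Nei's standard distance is
offered as the alternative metric. Neighbor joining is implemented in the
package rather than delegated, for two reasons: ties in the Q-criterion
are broken by the lowest (row, column) index pair of the working matrix
(merged nodes appended last), making output Newick strings
bit-reproducible; and branch lengths are propagated at full double
precision, so on an additive input matrix the tree's path-length matrix
reproduces the input to 1e-10. `ape`'s independent NJ is used as a
cross-check in the tests, and `ape` handles all Newick parsing and
serialisation. Negative branch lengths — legitimate NJ output — are kept
in machine output and only warned about when read back. Which tree-build
method a given survey's figure used is often unstated; the package
standardises on distance + NJ for both tree variants and exposes the
metric as the only switch.

## PCA and admixture

Individual-level PCA standardises each genotype entry as
`(g - 2p) / sqrt(2p(1-p))` with `p` the pooled frequency (the
frequency-variance scaling of genotype-PCA practice), drops monomorphic
loci, and mean-imputes missing entries (zero after centring).
Population-level PCA centres the population-by-locus frequency matrix
without scaling — frequencies are already commensurate. Coordinates are
deterministic up to per-axis sign; eigenvalue spectra are
sign-independent.

Ancestry inference fits the unsupervised ADMIXTURE likelihood
`sum_il [g_il log(Q F)_il + (2 - g_il) log(1 - (Q F))_il]` by EM, rather
than re-implementing the Bayesian MCMC of STRUCTURE: the likelihood is
identical, the maximiser is deterministic given a seed, and model size is
chosen by cross-validation instead of posterior approximation.
Initialisation draws Q from symmetric Dirichlet(1) and F from
Uniform(0.05, 0.95) per restart (default 10 restarts, tolerance `1e-6`
on the log-likelihood gain, cap 2,000 iterations); ancestral frequencies
are clipped to `[1e-6, 1 - 1e-6]`; the log-likelihood is asserted
monotone at every iteration and the best restart wins. Missing genotypes
contribute nothing to the sums.

Two behaviours of this MLE are worth knowing:

* **Boundary shrinkage at small panels.** With few, strongly diverged
  loci the likelihood genuinely prefers ancestral frequencies slightly
  more extreme than the sources' truth, compensated by ancestry
  proportions slightly inside the simplex — an unadmixed individual may
  be estimated at q ≈ 0.95, not 1.0. This is a property of the
  unpenalised maximum, not an optimisation failure (the interior solution
  can beat the generating parameters by ~100 log-likelihood units on a
  200-sample, 30-locus panel), and it bounds how sharp recovery tests on
  30 loci can be.
* **Cross-validation scoring.** `choose_k()` masks random genotype
  entries, refits, and scores held-out entries by binomial deviance at
  the fitted dose `mu = (Q F)`. For scoring, `mu` is floored at
  `1/(2n + 2)` — a fit on n diploids cannot support a more extreme
  predicted frequency. Without the floor, a handful of boundary `F`
  estimates contribute `-2 log(1e-6) ≈ 28` per held-out allele and can
  drag the criterion toward K = 1 even on clearly 3-source data; with
  it, the criterion selects the simulated K reliably. (ADMIXTURE's own
  CV avoids the same pathology by scoring squared prediction error.)

Label switching between runs is resolved by `align_q_labels()`,
exhaustive over column permutations up to K = 8, ties to the
lexicographically smallest permutation.

## Synthetic panels: what they emulate and what they don't

`generate_reference_panel()` builds a scale model of a multi-population
survey under the Balding-Nichols model, in which a population's frequency
at a locus of ancestral frequency `p` is Beta-distributed with variance
`F p (1-p)` — divergence is parameterised directly by the Fst the
downstream estimator must recover, which is why it was chosen over a
coalescent simulator. The defaults are fixed once to mirror the study
design the package targets:

* 30 loci, ancestral frequencies Uniform(0.2, 0.8) — keeping loci
  informative, as in panels whose He spans ~0.36-0.50;
* four regional poles at F = 0.025/0.025/0.055/0.035 from a shared
  ancestor, with 9 + 5 + 6 + 1 drift populations at within-region
  F = 0.008 — chosen so realised pairwise Fst spans ~0.001-0.09 and
  D_A spans roughly three orders of magnitude, like the published
  24-population comparison;
* three admixed populations drawing ancestry from the first two poles
  with Dirichlet(50 x weights) individual ancestries; the first two share
  identical weights and form the panel's near-identical pair (their
  D_A ~ 1e-3 is pure sampling noise), and the first is the focal
  population with 513 diploids (reference populations default to 100,
  configurable since published reference sizes vary).

Genotypes are Hardy-Weinberg draws (`Binomial(2, p)`), loci independent.
The generator deliberately omits mutation, selection, linkage, and any
real demographic history: a passing test shows the estimators recover the
parameters of *this* model at survey scale (e.g. multi-locus θ within
0.005 of the simulated F = 0.05 averaged over 100 replicates), not that
any particular human dataset satisfies the model. Recovery under drift
with LD, or under non-equilibrium genotype proportions, is untested by
design.

All generators and every stochastic stage take a mandatory seed;
`run_pipeline()` derives a named substream per stage from one root seed,
so stages can be rerun independently and a rerun with the same config and
seed is byte-identical, manifest included.

## Problem sizes used in the test suite

The suite exercises the estimators at the scale the methods are meant
for while staying quick to run: survey-sized single panels (513 diploids,
30 loci) wherever a claim is about per-locus arithmetic; 100 replicate
panels of 2 x 250 diploids for θ calibration; 1,000-2,000 replicates for
the size of the exact HWE and permutation tests (permutation size 100 at
n = 50 per group); 5 replicate 3-source panels of 60 diploids each for
cross-validated K selection; and a reduced 9-population panel for the
end-to-end byte-reproducibility check of the pipeline.

## Known limitations

* The exact HWE enumeration is O(min(n_ins, n_del)) per locus — fine for
  panels, slow for millions of variants.
* The admixture EM is plain R matrix algebra; hundreds of samples and
  tens of loci fit in seconds, biobank scale is out of scope.
* No bootstrap support on trees, no hierarchical AMOVA, no
  linkage-aware admixture, no kinship likelihood ratios beyond TPI —
  all deliberate non-goals.
* `count_significant_loci()` implements the per-comparison Bonferroni
  convention of survey reporting; it is not a replacement for FDR
  control in discovery settings.
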