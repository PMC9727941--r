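---
title: "Unbiased kinship estimation: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unbiased kinship estimation: model, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ukin)
```

## The estimation problem

The kinship coefficient $\phi_{ii'}$ of two individuals is the probability
that two alleles drawn at random, one from each individual at the same
autosomal locus, are identical by descent. With IBD-sharing probabilities
$(k_0, k_1, k_2)$ it is $\phi = k_1/4 + k_2/2$: 0.5 for MZ twins, 0.25 for
parent–offspring and full sibs, 0.125 for half sibs, 0.0625 for first
cousins. Under random mating in a homogeneous population the genotype
dosages $X_{ij} \in \{0,1,2\}$ of a pair are correlated with
$\rho_{ii'} = 2\phi_{ii'}$ at every SNP, so estimating kinship is
equivalent to estimating a genotype correlation.

The standard moment estimator (the sample-correlation GRM, `scgrm()`)
averages standardized cross-products over $m$ SNPs:
$$\hat\rho_{ii'} = \frac{1}{m}\sum_{j=1}^m
  \frac{(X_{ij}-\bar X_j)(X_{i'j}-\bar X_j)}{\sigma_j^2},
  \qquad \hat\phi_{ii'} = \tfrac12 \hat\rho_{ii'} .$$
Because the centering means $\bar X_j$ are estimated from the same $n$
samples, the estimator is biased:
$$E\,\hat\rho_{ii'} = \rho_{ii'}
  - \frac1n\sum_{a\ne i}\rho_{ia}
  - \frac1n\sum_{a\ne i'}\rho_{ai'}
  - \frac1n + \frac{n-1}{n}\bar\rho ,$$
(`expected_scgrm_pair()`), and the pair estimates sum, in expectation, to
$\frac{n-1}{2}(\bar\rho - 1) \le 0$ for every SNP
(`expected_pair_sum()`). That negative sum is why large fractions of
estimated kinship coefficients are negative regardless of the true
structure. In the extreme case of a single group of $n$ individuals with
average true correlation $\bar\rho$, the expected average kinship estimate
is $(\bar\rho-1)/(2n)$ (`expected_family_average_kinship()`): for 500 full
siblings this is $-5\times10^{-4}$ although every true kinship is 0.25.

The corrected estimator (`ukin()`) adds back the row-sum mass the centering
removed:
$$\tilde\rho_{ii'} = \hat\rho_{ii'}
  + \tfrac12\sum_{k\ne i}\hat\rho_{ik}
  + \tfrac12\sum_{l\ne i'}\hat\rho_{li'} + 1 ,$$
which has expectation exactly $\rho_{ii'}$ (it equals, SNP by SNP, an
unbiased per-SNP statistic averaged over markers; the test suite verifies
the two constructions agree to machine precision). It is an affine map of
the scGRM matrix, so it costs one matrix pass beyond the scGRM itself.

Two exact algebraic consequences are worth knowing because they hold for
*every* data set, not just in expectation:

* with sample variances and centering over all $n$ samples, the scGRM pair
  estimates sum to exactly $-(n-1)/2$ on the correlation scale, so the
  all-pairs mean corrected correlation is exactly 0;
* centered scores sum to zero per SNP, so for two *identical* genotype rows
  (MZ twins) the per-SNP corrected statistic collapses to the constant 1 —
  MZ pairs are estimated at exactly $\phi = 0.5$ with zero variance under
  all-sample centering. A summary table printing 0.000 bias and 0.000 SD
  for the MZ group is an algebraic identity, not rounding or truncation.

## Comparators

`rgrm()` weights SNPs proportionally to their variance (summed
cross-products over summed variances); it collapses to scGRM when all
variances are equal, and shares the centering bias. `king_robust()` is the
frequency-free moment estimator built from heterozygote and
opposite-homozygote counts,
$\hat\phi = (N_{\mathrm{het,het}} - 2N_{\mathrm{opp}})/(N^{(i)}_{\mathrm{het}}+N^{(j)}_{\mathrm{het}})$,
computed over the SNPs non-missing in both members. Degree calls
(`classify_relationship()`) use half-open powers-of-two intervals with the
upper endpoint assigned to the more distant class, so a value exactly at
$2^{-3/2}$ is called first-degree, deterministically.

## Tunable parameters that matter

* **Variance source** (`estimator_config(variance_mode=)`): `"sample"`
  (unbiased per-SNP sample variance, divisor count−1), `"hwe"`
  ($2\hat p(1-\hat p)$), or `"known"` (externally supplied, e.g. the
  simulator's true $2p(1-p)$ or a reference panel). The choice is
  consequential: with self-estimated sample variance the forced-sum
  identities pin the all-pairs means to constants regardless of true
  relatedness, so demonstrating the family-average bias and its correction
  (the sib-family experiment) requires known variances with within-family
  centering. The default is `"sample"`, the practical choice for real
  data; the simulator-driven experiment runners default to `"known"`.
* **Centering set** (`centering_set`): samples whose means center the
  dosages. Default: all samples in the analysis.
* **Missing data** (`missing_policy`): per-SNP mean imputation (default)
  leaves centered scores at zero, contributing nothing to cross-products;
  `"error"` refuses missing data. How the original analyses handled
  missingness is not documented; mean imputation is this package's choice.
* **Monomorphic SNPs** are dropped whenever the working variance estimate
  is zero (sample/hwe modes), identically across the GRM-type estimators
  so comparisons share one SNP set. In `"known"` mode all SNPs with
  positive declared variance are kept — including ones observed
  monomorphic — because the unbiasedness statement is an unconditional
  expectation over genotype draws.
* **QC** (`qc_filter()`): individuals with more than 10% missing genotypes
  are removed first, then SNPs with missing rate above 5% or MAF below 5%,
  mirroring the order such cohort pipelines describe.
* **Diagonal entries**: the estimators are defined for pairs; the package
  applies the formulas with $i = i'$ so a complete GRM exists for REML.
  KING's formula gives exactly 0.5 on the diagonal. This convention is a
  construction choice, recorded in the object, not an inbreeding estimate.
* **No truncation**: negative estimates are reported as computed — they
  are the phenomenon under study.

## The synthetic-data generator

`simulate_mixed_cohort()` reproduces the evaluation cohort design: 500
pairs each at true kinship 0.125 (half sibs), 0.25 (full sibs) and 0.5 (MZ
twins) plus 1000 singletons — 4000 individuals at 50,000 independent SNPs
with MAF drawn uniformly from $[0.05, 0.5]$. Genotypes are produced by
gene dropping: founder haplotypes are Bernoulli($p_j$) draws, and each
offspring inherits one uniformly chosen haplotype per parent per SNP
(Mendelian transmission under linkage equilibrium). Kinship-0.125 pairs
are realized as half sibs rather than avuncular pairs; both have IBD
$(0.5, 0.5, 0)$, so estimator behaviour is identical.
`drop_pedigree()` exposes the same machinery for arbitrary non-inbred
pedigrees and emits ground truth: kinship by the standard recursion, and
IBD coefficients by the non-inbred product formula
$k_2 = \phi_{f_af_b}\phi_{m_am_b} + \phi_{f_am_b}\phi_{m_af_b}$,
$k_1 = 4\phi - 2k_2$ (pairs involving a founder have $k_2 = 0$; MZ pairs
are $(0,0,1)$). All randomness flows from a single seed through R's
stream, so every experiment is replayable.

What the generator deliberately does **not** emulate: linkage
disequilibrium, inbreeding loops, population structure or admixture, sex
chromosomes, genotyping error. Passing tests therefore demonstrate
correctness of the estimators under the model assumptions (LE, HWE,
homogeneity), not robustness to real-data violations of them. One visible
consequence: the reference summary table for the mixed cohort was produced
with a correlated-binary genotype generator whose pairwise *joint*
distribution differs from Mendelian gene dropping even though means,
variances and correlations agree. Second moments of the estimators are
close but not identical — this package's UKin SD in the kinship-0.25
group runs about 10% above the reference value, while the scGRM unrelated
SD matches the delta-method value $0.5/\sqrt m$ within 1–2%.

The generator's scGRM bias realized in the mixed cohort is of order
$-10^{-4}$ on the kinship scale, an order of magnitude smaller than the
reference table's $-0.9\times10^{-3}$; the experiment runner therefore
reports the closed-form prediction alongside the realized bias
(`predicted_scgrm_bias_1e3`) so the discrepancy is visible rather than
hidden. Which variance convention (sample vs observed-frequency) produced
the reference values is not documented; this package exposes all three.

## Heritability estimation

`reml_h2()` fits $y \sim N(\mu\mathbf 1,\;
\sigma_g^2 G + \sigma_e^2 I)$ with $G = 2K$ by restricted maximum
likelihood. The implementation absorbs the intercept first — the REML
criterion is the likelihood of contrasts orthogonal to $\mathbf 1$ — then
eigendecomposes the projected GRM once and profiles a one-dimensional
restricted likelihood over $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2) \in
[0,1]$ on a 101-point grid refined by golden-section search. For a single
component this is deterministic, needs no starting values, and cannot
converge to a local optimum the grid misses. Standard errors come from the
numeric observed information of the profile restricted likelihood;
boundary optima are flagged and their SE carries the same caveat rather
than being omitted. Negative eigenvalues of the projected GRM beyond
tolerance are clipped to zero with a warning. A GRM proportional to the
identity makes the two components unidentifiable and is refused. Fixed
effects: intercept only, matching the simulated phenotypes.

**A structural result.** The corrected-estimator matrix equals the scGRM
matrix plus $\tfrac12(S\mathbf 1' + \mathbf 1 S') + \mathbf 1\mathbf 1'$
(uniformly, including the diagonal). Perturbations of the form
$u\mathbf 1' + \mathbf 1 u' + c\,\mathbf 1\mathbf 1'$ vanish in every
contrast covariance $K'VK$ with $K'\mathbf 1 = 0$, so *exact* single-GRM
REML with an intercept returns identical $h^2$ for the scGRM and the
corrected matrix. Working in the contrast space makes this hold
numerically (a full-space implementation breaks it spuriously through
eigenvalue clipping of the corrected GRM, which is indefinite). The test
suite asserts the equality. The practical reading: on LE synthetic
cohorts, heritability comparisons between the two estimators show
$|\mathrm{bias}_{\mathrm{UKin}}| \le |\mathrm{bias}_{\mathrm{scGRM}}|$ as
near-exact equality; reported real-data differences between them must
arise outside this idealized model — LD, QC interactions, or
implementation details of other REML pipelines — and are not reproducible
from the centering-bias mechanism alone.

`coverage_experiment()` wraps the replicate loop: simulate a sib-family
cohort and a phenotype, estimate kinship (or use truth), fit, and record
estimate, SE, and CI coverage. Two phenotype models are provided.
`"causal"` draws Gaussian effects on standardized dosages of a random 1%
of SNPs and rescales the genetic score so its sample variance is exactly
$h^2$; with small synthetic panels the handful of causal SNPs makes the
*realized* genetic relatedness fluctuate substantially around the pedigree
expectation, which depresses and disperses $h^2$ estimates for every
estimator alike. `"mvn"` draws $y \sim N(0, h^2 G + (1-h^2)I)$ from the
true-kinship GRM — the exactly correctly specified model — and is the
appropriate benchmark for CI calibration and for isolating estimator
quality; it mirrors the large-panel regime where realized and expected
relatedness coincide.

## Problem sizes used by the checks

The packaged checks run the sib-family experiment at 50–60 families of
500 siblings with 10,000 SNPs (the design's family size and SNP panel,
with the family count reduced from 200; the family-average distribution is
what matters and its Monte-Carlo SE enters the assertions explicitly), the
mixed cohort at the full 4000 × 50,000 design, Monte-Carlo expectation
checks at 1000 replicates of a 40-individual, 500-SNP miniature of the
mixed cohort, and CI coverage at 200 replicates. These sizes were chosen
so each assertion's Monte-Carlo error is well below the effect it checks.

## Known limitations

* No LD weighting: the minimum-variance two-step GRM and quadratic-program
  LD weights are out of scope; all SNPs are weighted equally (scGRM/UKin)
  or by variance (rGRM).
* Homogeneous-population assumption: one frequency vector serves all
  samples; admixture-aware extensions are not attempted.
* The PLINK readers cover biallelic autosomal SNPs only (no multi-allelic
  sites, dosage uncertainty, or strand flipping; alleles are taken as
  labelled).
* `reml_h2` fits a single variance component with an intercept; covariate
  matrices, multiple GRMs and liability-scale transformations are out of
  scope.
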