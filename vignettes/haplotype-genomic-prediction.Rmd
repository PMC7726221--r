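---
title: "Haplotype-block genomic prediction: models, numerics and design choices"
author: "hapblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-block genomic prediction: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapblup)
```

# The model

`hapblup` fits the multi-allelic mixed model

$$
\mathbf{y} = \mathbf{Xb}
 + \mathbf{W}_\alpha \boldsymbol\alpha_o
 + \mathbf{W}_\delta \boldsymbol\delta_o
 + \mathbf{W}_{\alpha h} \boldsymbol\alpha_{ho}
 + \mathbf{e}
$$

with one record per individual (the incidence matrix of observations on
individuals is the identity). The three random terms are SNP additive
values, SNP dominance values, and haplotype additive values; any subset of
them defines one of the six prediction models (1: A+D+H, 2: A+H, 3: D+H,
4: H, 5: A+D, 6: A). The coding columns come from the genetic partition of
genotypic values:

* **SNP additive**: $x - 2p$ for $x$ copies of the counted allele at
  sample frequency $p$ — column mean zero by construction.
* **SNP dominance**: $\{-2q^2,\, 2pq,\, -2p^2\}$ for genotypes with
  $\{2, 1, 0\}$ copies — mean zero and orthogonal to the additive column
  under exact Hardy–Weinberg proportions (both identities are asserted in
  the test suite on exact-proportion toy populations).
* **Haplotype additive**: each block is a locus; each distinct phased
  allele string over the block's SNPs is an allele $l$ with frequency
  $p_l$; an individual carrying $c_l$ copies is coded $c_l - 2p_l$. Within
  a block the columns sum to zero for every individual, so a block with
  $A$ alleles contributes at most $A-1$ to the rank.

Any centering-equivalent coding gives identical relationship matrices
after trace normalization: $G = WW'/k$ with $k = \mathrm{tr}(WW')/n$
forces mean diagonal exactly 1 and absorbs any scalar rescaling of $W$.
Duplicating SNP columns leaves $G$ — and therefore GREML estimates and
GBLUP predictions — unchanged; this repeated-SNP invariance is what makes
differencing haplotype-model and SNP-model heritabilities meaningful, and
it is verified to ~1e-14 in the acceptance checks.

SNP frequencies are full-sample frequencies computed after MAF filtering
and before any cross-validation masking: relationship matrices describe
all genotyped individuals, as is standard GBLUP validation practice. (The
alternative, within-training-fold centering, changes third decimals at
the sample sizes used here; we fixed the simpler convention.)

# Haplotype blocks

Three blocking families are provided.

* **Fixed distance**: half-open windows $[kw, (k+1)w)$ on absolute
  chromosome coordinates. We deliberately anchor windows at coordinate
  zero rather than at the first SNP: windows then mean the same thing on
  every chromosome and data set, and the rule matches the worked
  enumeration used to test the implementation (SNPs at 1, 3, 6, 12 and
  20 kb with a 10-kb window yield exactly one block, $\{1,3,6\}$).
  Windows holding fewer than two SNPs yield no block. Note that the block
  *count* is not monotone in the window size — two adjacent singleton
  windows can merge into one two-SNP window — but the set of SNPs left
  unblocked can only shrink as windows coarsen; the suite tests the
  latter, correct property.
* **Fixed SNP count**: consecutive groups of exactly $s$ SNPs; when a
  chromosome's count is not divisible by $s$ the final block is the last
  $s$ SNPs and may overlap its predecessor, so every block has exactly
  $s$ SNPs and each chromosome yields $\lceil m_c/s \rceil$ blocks. The
  trailing-overlap rule is inferred from summary statistics that report
  minimum = maximum SNPs per block for every $s$.
* **Annotation intervals** (genes, coding genes, noncoding genes,
  ChIP-seq sites): each interval is extended by a 2-kb flank on both ends,
  overlapping extended intervals of the same class are merged, merged
  intervals are cut into chunks of at most 150 kb, and chunks with fewer
  than two SNPs are dropped. Classes are merged and analyzed separately; a
  SNP may appear in blocks of different classes since each class defines
  its own analysis.

Rare haplotype alleles are never filtered — frequency filtering is
SNP-level only — so the allele catalog is exactly what phasing produced.

# GREML and GBLUP numerics

The restricted likelihood is computed in the **error-contrast space**:
with $K$ an orthonormal basis of the null space of $X'$,

$$
\ell(\sigma^2) = -\tfrac12\left[\log\det K'VK + y'K (K'VK)^{-1} K'y\right].
$$

This is not a stylistic choice. Centered codings make $\mathbf{1}$ a null
vector of every GRM, and $\mathbf{1}$ lies in the column space of $X$
(the intercept); in the textbook $V$-form the projection
$P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}$ is then a difference of two
terms that both diverge as $\sigma_e^2 \to 0$, and the cancellation error
can fabricate likelihood gains of thousands of units. The contrast space
removes the offending direction exactly. A state is additionally rejected
when the Cholesky diagonal of $K'VK$ signals a condition number beyond
1e12, which backs the line search away from degenerate boundaries.

The optimizer takes EM-REML steps for the first two iterations, then
average-information updates with step-halving and an EM fallback; negative
updates are truncated at $10^{-8}$ times the phenotypic variance, and a
component pinned at that bound with negative gradient is dropped from the
update system (boundary fixation) until its gradient turns positive.
Accepted iterations never decrease the likelihood; convergence requires a
relative likelihood change below 1e-8 and relative parameter changes below
1e-6.

For a single genetic component the model is rotated through the
eigendecomposition of its GRM and the likelihood profiled over the
variance ratio with Brent search. Because Brent localizes an optimum only
to about $\sqrt{\varepsilon}$, the optimum is polished with a root find on
the analytic profile gradient, which restores ~1e-12 reproducibility —
needed so that numerically identical GRMs (e.g. before and after SNP
duplication) give bitwise-comparable fits. The decomposition can be cached
and reused across cross-validation folds and simulation replicates with
identical results to direct solves (tested at 1e-8); this mirrors the
decomposition-reuse strategy of fast GBLUP validation pipelines. Both
paths report the likelihood with the same constant, so likelihoods are
comparable across models and algorithms (nested models are tested for
non-decreasing maximized likelihood).

GBLUP solves $\hat b = (X'V^{-1}X)^{-1}X'V^{-1}y$ on training records and
$\hat u_i = \sigma_i^2 G_i[\cdot,\text{train}]\,V^{-1}(y - X\hat b)$,
producing predictions for masked individuals; a near-singular $V$ gets a
ridge of $10^{-8}\times$ its mean diagonal with a warning. Per-locus
heritabilities back-solve effects
$\hat\alpha = (\hat\sigma^2/k)\,W'V^{-1}(y - X\hat b)$; the heritability
of SNP $j$ is $\mathrm{var}(W_{\cdot j})\hat\alpha_j^2 / \hat\sigma_P^2$
and of a block the sample variance of the block's fitted genetic-value
vector over $\hat\sigma_P^2$. These profiles are a ranking instrument —
the tested contract is that a simulated causal locus tops the profile,
not the absolute values, because back-solved effects are shrunken.

# Phenotype preparation

Box–Cox fitting maximizes the profile log-likelihood
$-\tfrac{n}{2}\log\hat\sigma^2(z_\lambda) + (\lambda-1)\sum\log y$ over
$\lambda \in [-3, 3]$ with Brent search (tolerance 1e-6); a grid-search
oracle and the MASS implementation agree in the tests. Outlier removal is
a single pass: mean and SD are computed once on all non-missing values
and points beyond `outlierSd` (default 10) standard deviations are
removed with their distances reported. The default of 10 SD removes
outliers of the magnitude reported for lipid phenotypes (13–18 SD)
without touching plausible tails. Outliers are removed *before* any
Box–Cox transform, since reported outlier distances are on the raw scale.
Per-trait use of original versus transformed values is a flag, mirroring
traits (height, BMI) that are analyzed untransformed.

# Cross-validation

Phenotyped individuals are randomly split into ten folds: nine of size
$\lceil n/10 \rceil$ and a generally smaller tenth (with a most-even
fallback when that rule is infeasible). Within each fold the validation
phenotypes are omitted from variance-component and fixed-effect
estimation, relationship matrices keep all individuals, and accuracy is
the Pearson correlation between validation phenotypes and predicted total
genetic values, reported per fold with mean and SD. Fixed effects and
variance components are re-estimated per training fold by default; a
switch reuses full-data components (both options exist because published
pipelines differ, and the reuse strategy is markedly faster). A
permutation of validation phenotypes must, and does, destroy accuracy,
and replacing validation phenotypes with arbitrary values leaves that
fold's predictions unchanged to 1e-10 — the leak test.

# Epistasis heritability (heritability-based method)

$\hat h_E^2 = \hat h_g^2 - \hat h_s^2$, where the haplotype model's total
heritability is differenced against its *matching* SNP baseline: models 2
and 4 against model 6, models 1 and 3 against model 5. The relative form
divides by the baseline's additive heritability. Negative values are
reported with a haplotype-loss flag, never clamped: loss is real model
behavior (the haplotype model estimating SNP additive signal less
accurately than the SNP model). The method carries a known upward bias —
visible in our simulations as a positive offset (~0.04 at the simulated
null) — so monotone response to the true interaction variance, not
unbiasedness, is the tested property. A variance-based alternative is not
implemented; the API leaves the estimator pluggable.

# The synthetic-data generator

The generator emulates what the analysis needs from cohort genotype data
and no more:

* **Genotypes**: founder haplotypes from a first-order Markov chain along
  each chromosome, so adjacent SNPs have allelic correlation close to
  `ldDecay` (one knob, no coalescent); per-SNP frequencies drawn from a
  uniform MAF spectrum; diploids formed by pairing independent haplotypes,
  or by one generation of random mating over a founder pool when GRM
  off-diagonal structure is wanted. The conditional allele probability is
  clamped to $[0,1]$, so the target correlation is attainable only where
  neighboring frequencies are similar — LD calibration tests therefore use
  a narrow spectrum. Realized MAF is a binomially noisy copy of the drawn
  spectrum; distribution tests use enough individuals that this noise is
  negligible against the spectrum's width.
* **Phenotypes**: fixed effects (a two-level sex-like factor, a centered
  age-like covariate) plus additive, dominance and within-haplotype
  epistasis components and Gaussian residual. Each component is rescaled
  so its realized sample variance matches its requested fraction of the
  (unit) phenotypic variance exactly. Epistasis acts **per haplotype
  copy**: for each sampled within-block SNP pair, each chromosome
  contributes the product of its centered allele codes times an
  interaction effect, summed over the two copies. This makes the
  epistasis value an additive function of the individual's two haplotype
  alleles — exactly the structure the haplotype-additive hypothesis
  ($a_h \approx a + \varepsilon_h$) posits, and the structure a
  genotype-dosage product would *not* have (dosage products mix alleles
  across homologs, a haplotype-dominance term no model here includes).
  Optional skew applies the inverse Box–Cox transform; $\lambda = 1$ is
  an affine shift, recovering the unskewed trait.
* **Annotations**: interval counts, a size distribution, class fractions
  over coding/noncoding/ChIP-seq, placed uniformly on length-weighted
  chromosomes; intervals of a class may overlap.

What it does **not** emulate: demographic history, recombination maps,
genotyping or phasing error, ascertainment of SNP panels. Passing tests
therefore demonstrate correctness of the estimators under the stated
generative model, not robustness to real-data artifacts such as imputation
error — which the profile comparisons on real cohorts specifically
implicate in haplotype loss.

## Study conditions used in the automated checks

Where the checks simulate data, the conditions are fixed once:

* *Parameter recovery*: $n = 1000$ individuals, $m = 2000$ SNPs (two
  10-Mb chromosomes at 100 SNPs/Mb), true additive/dominance fractions
  0.4/0.1, LD 0.5, 20 replicates; the A+D model's GREML means must sit
  within two empirical standard errors of truth.
* *Epistasis response*: same panel sizes, MAF spectrum on $[0.35, 0.5]$,
  LD 0.9, 3-SNP blocks, additive fraction 0.3, interaction fractions
  $\{0, 0.05, 0.10, 0.15\}$, 20 replicates. The near-symmetric spectrum is
  what isolates the interaction: odd central moments of allele indicators
  vanish as $p \to 1/2$, so per-haplotype products are uncorrelated with
  additive codes and the SNP baseline cannot absorb the interaction
  variance; tight LD with small blocks keeps the allele catalog small
  (≈6 alleles/block), which bounds the haplotype model's overfitting bias
  at the null. Means over replicates must be strictly increasing in the
  simulated fraction, and the zero-fraction mean below 0.05.
* *Null calibration, oracles, invariances*: sizes as stated in the test
  names (n = 30 grid oracle, n = 50/200 ridge equivalence, n = 100/500
  duplication invariance, n = 300–1000 cross-validation checks).

# Known limitations

* Dense matrices throughout: intended scale is $n$ up to a few thousand
  individuals; biobank-scale fitting would need out-of-core or sparse
  machinery.
* Haplotype dominance is deliberately absent (no model includes it), so
  cross-homolog interaction variance is not estimable.
* The per-locus heritability definition is a back-solve substitute for a
  pipeline-internal formula that is not published; its ranking behavior
  is the tested contract.
* The HBM epistasis estimator's upward bias is documented, not corrected;
  estimates near the null should be read against the ~0.04 offset seen in
  the calibration simulations.
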