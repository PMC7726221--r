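# hapblup — haplotype-block genomic prediction with multi-allelic GBLUP/GREML

Genomic prediction usually fits each SNP as a biallelic locus, ignoring
where SNPs sit and how they travel together. `hapblup` implements the
complementary haplotype view: consecutive SNPs are grouped into **blocks**
using structural rules (fixed chromosome distance, fixed SNP count) or
functional annotation (gene boundaries, ChIP-seq sites), each block is
treated as one **multi-allelic locus** whose distinct phased allele strings
are its alleles, and prediction models combine SNP additive, SNP dominance
and haplotype additive values. The package is aimed at quantitative
geneticists who want to measure whether — and *why* — haplotypes improve
prediction accuracy for a trait.

## The model

Phenotypes follow the mixed model

```
y = Xb + Wα αo + Wδ δo + Wαh αho + e
  = Xb + a + d + ah + e
```

with `Wα` the centered allele-count (additive) codes `x − 2p`, `Wδ` the
genetic-partition dominance codes `{−2q², 2pq, −2p²}`, and `Wαh` one
centered column per block allele (`cₗ − 2pₗ`). The reparameterized
covariances use trace-normalized genomic relationship matrices,

```
Var(a)  = σα²  · Ag,   Ag  = Wα Wα' / kα,    kα  = tr(Wα Wα')/n
Var(d)  = σδ²  · Dg,   Dg  = Wδ Wδ' / kδ
Var(ah) = σαh² · Agh,  Agh = Wαh Wαh' / kαh
```

so every relationship matrix has mean diagonal exactly 1. Variance
components are estimated by GREML (average-information updates with EM
safeguarding; a single-component fast path works in the eigenbasis of the
GRM), genetic values by GBLUP, and prediction accuracy by ten-fold
cross-validation over six model variants (1: A+D+H, 2: A+H, 3: D+H, 4: H,
5: A+D, 6: A).

**Haplotype epistasis heritability** is the excess of a haplotype model's
total heritability over its SNP-baseline model (the heritability-based
method): models 2/4 are differenced against model 6, models 1/3 against
model 5. Under the hypothesis `ah ≈ a + εh`, this excess measures
within-block additive×additive interaction variance; a negative value
diagnoses haplotype loss.

A synthetic-data module generates phased multi-chromosome panels (Markov
founder haplotypes with tunable local LD and MAF spectrum, optional random
mating), annotation intervals, and phenotypes with known additive /
dominance / within-haplotype-epistasis variance fractions, so every stage
is testable without access-restricted cohort data.

## Worked example

```r
library(hapblup)

panel  <- simulateGenotypes(simConfig(
  nIndividuals = 500, chromosomes = c(chr1 = 5e6, chr2 = 5e6),
  snpDensity = 100, mafRange = c(0.35, 0.5), ldDecay = 0.9, seed = 11))
blocks <- enumerateHaplotypes(blocksFixedCount(snpMap(panel), 3L), panel)
sim    <- simulatePhenotypes(panel, blocks,
                             fractions = c(add = 0.3, dom = 0, epi = 0.15),
                             seed = 12)
X      <- buildDesign(sim$pheno, "y", classVars = "sex", covars = "age")
grms   <- buildGrms(buildModelMatrices(panel, blocks,
                                       components = c("add", "hap")))@grms

fitHap <- gremlFit(sim$pheno$y, X, grms["hap"], model = 4L)
fitSnp <- gremlFit(sim$pheno$y, X, grms["add"], model = 6L)
epistasisEstimate(fitHap, fitSnp)
```

prints (among other fields)

```
 $ h_g2 : num 0.473      # haplotype-model total heritability
 $ h_s2 : num 0.349      # SNP-baseline total heritability
 $ h_E2 : num 0.124      # their difference: epistasis heritability
 $ h_Er2: num 0.354      # relative to the SNP additive heritability
```

The trait was simulated with 30% additive and 15% within-haplotype
epistasis variance: the SNP model sees only the additive part (0.349),
the haplotype model also absorbs the within-block interactions (0.473),
and the difference (0.124) recovers most of the simulated 0.15. The same
data cross-validated:

```r
plan <- makeFolds(seq_len(500), k = 10, seed = 13)
cvHap <- crossValidate(sim$pheno$y, X, grms, model = 4, plan = plan)
cvSnp <- crossValidate(sim$pheno$y, X, grms, model = 6, plan = plan)
accuracyGain(cvHap$mean, cvSnp$mean)
#> accuracy: hap 0.375 ± 0.110 | snp 0.344 ± 0.107 | gain 9.25%
```

— the haplotype model predicts better exactly because the epistatic
variance exists and is block-local. `runPipeline()` chains all stages
(preparation, blocking, CV grid, epistasis, heritability profiles) from a
single config list or YAML file and writes every report as TSV.

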