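test_that("simConfig validates its invariants", {
  expect_error(simConfig(1, c(chr1 = 1e6)), "nIndividuals")
  expect_error(simConfig(10, c(chr1 = 1e6), ldDecay = 1), "ldDecay")
  expect_error(simConfig(10, c(chr1 = -5)), "lengths")
  expect_error(simConfig(10, c(chr1 = 1e6), mafRange = c(0, 0.5)), "mafRange")
})

test_that("genotype simulation is deterministic and rejects empty chromosomes", {
  cfg <- simConfig(20, c(chr1 = 5e5, chr2 = 2e5), snpDensity = 100, seed = 11)
  p1 <- simulateGenotypes(cfg)
  p2 <- simulateGenotypes(cfg)
  expect_identical(haplotypeMatrix(p1), haplotypeMatrix(p2))
  expect_identical(snpMap(p1), snpMap(p2))
  expect_true(all(diff(snpMap(p1)$pos[snpMap(p1)$chrom == "chr1"]) > 0))
  # a chromosome too short for even one SNP rejects the config
  expect_error(
    simulateGenotypes(simConfig(10, c(chr1 = 1e6, tiny = 100),
                                snpDensity = 10, seed = 1)),
    "zero SNPs")
})

test_that("ldDecay = 0 gives independent adjacent SNPs", {
  panel <- simulateGenotypes(simConfig(200, c(chr1 = 1e7), snpDensity = 1000,
                                       ldDecay = 0, seed = 21))
  expect_gte(nSnps(panel), 9000)
  dose <- genotypeDosage(panel)
  m <- ncol(dose)
  adjCor <- vapply(seq_len(m - 1L),
                   function(j) cor(dose[, j], dose[, j + 1L]), numeric(1))
  expect_lt(abs(mean(adjCor)), 0.03)
})

test_that("ldDecay = 0.9 is recovered by an empirical correlation oracle", {
  # narrow MAF spectrum: the target adjacent correlation is attainable only
  # when neighboring allele frequencies are close
  panel <- simulateGenotypes(simConfig(500, c(chr1 = 2e6), snpDensity = 500,
                                       mafRange = c(0.28, 0.32),
                                       ldDecay = 0.9, seed = 31))
  H <- haplotypeMatrix(panel)  # empirical, independent of generator internals
  m <- ncol(H)
  adjCor <- vapply(seq_len(m - 1L),
                   function(j) cor(H[, j], H[, j + 1L]), numeric(1))
  expect_lt(abs(mean(adjCor) - 0.9), 0.05)
})

test_that("realized MAF distribution matches the spectrum (KS test)", {
  panel <- simulateGenotypes(simConfig(2000, c(chr1 = 2.5e7),
                                       snpDensity = 200,
                                       mafRange = c(0.05, 0.45),
                                       ldDecay = 0, seed = 41))
  expect_gte(nSnps(panel), 5000)
  ks <- suppressWarnings(
    stats::ks.test(snpMap(panel)$maf, "punif", 0.05, 0.45))
  expect_gt(ks$p.value, 0.01)
})

test_that("random mating creates relatedness visible in the GRM", {
  cfg <- simConfig(80, c(chr1 = 1e6), snpDensity = 300, ldDecay = 0.3,
                   seed = 51, mating = "random", nFounders = 15L)
  panel <- simulateGenotypes(cfg)
  A <- grm(buildGrms(buildModelMatrices(panel, components = "add")), "add")
  offDiag <- A[upper.tri(A)]
  cfgI <- simConfig(80, c(chr1 = 1e6), snpDensity = 300, ldDecay = 0.3,
                    seed = 51, mating = "independent")
  Ai <- grm(buildGrms(buildModelMatrices(simulateGenotypes(cfgI),
                                         components = "add")), "add")
  # shared founder haplotypes push some relationships far above the
  # independent-panel background
  expect_gt(max(offDiag), max(Ai[upper.tri(Ai)]) + 0.1)
})

test_that("annotation intervals honor count, size and class fractions", {
  expect_length(simulateAnnotations(c(chr1 = 1e6), 0, seed = 1), 0)
  gr <- simulateAnnotations(c(chr1 = 5e6), 200,
                            sizeDistribution = list(type = "fixed",
                                                    size = 5e4),
                            seed = 2)
  expect_true(all(IRanges::width(gr) == 50000L))
  expect_true(all(GenomicRanges::end(gr) <= 5e6))
  frac <- c(coding = 0.6, noncoding = 0.3, chipseq = 0.1)
  gr2 <- simulateAnnotations(c(chr1 = 1e7), 1000, classFractions = frac,
                             seed = 3)
  counts <- table(factor(gr2$class, names(frac)))
  for (cl in names(frac)) {
    lo <- qbinom(0.005, 1000, frac[[cl]])
    hi <- qbinom(0.995, 1000, frac[[cl]])
    expect_gte(counts[[cl]], lo)
    expect_lte(counts[[cl]], hi)
  }
  expect_error(simulateAnnotations(data.frame(), 5, seed = 1), "non-empty")
})

test_that("phenotype components realize their requested variance fractions", {
  sb <- simPanelBlocks(400, c(chr1 = 1e6), density = 300, seed = 61)
  fr <- c(add = 0.4, dom = 0.1, epi = 0.15)
  sim <- simulatePhenotypes(sb$panel, sb$blocks, fractions = fr, seed = 62)
  comp <- sim$truth$components
  # component-variance oracle: directly measure each stored vector
  expect_lt(abs(var(comp$a) - 0.4), 0.01)
  expect_lt(abs(var(comp$d) - 0.1), 0.01)
  expect_lt(abs(var(comp$epi) - 0.15), 0.01)
  expect_lt(abs(var(comp$e) - 0.35), 0.01)
  expect_identical(sim$truth$fractions[["residual"]], 1 - sum(fr))
})

test_that("phenotype component vectors are close to uncorrelated", {
  sb <- simPanelBlocks(1000, c(chr1 = 1e6), density = 300, seed = 71)
  sim <- simulatePhenotypes(sb$panel, sb$blocks,
                            fractions = c(add = 0.3, dom = 0.15, epi = 0.15),
                            seed = 72)
  comp <- sim$truth$components
  expect_lt(abs(cor(comp$a, comp$d)), 0.1)
  expect_lt(abs(cor(comp$a, comp$epi)), 0.1)
  expect_lt(abs(cor(comp$d, comp$epi)), 0.1)
})

test_that("inverse Box-Cox skew at lambda = 1 is an affine shift", {
  sb <- simPanelBlocks(100, seed = 81)
  fr <- c(add = 0.3, dom = 0, epi = 0)
  plain <- simulatePhenotypes(sb$panel, sb$blocks, fractions = fr, seed = 82)
  skew1 <- simulatePhenotypes(sb$panel, sb$blocks, fractions = fr, seed = 82,
                              boxcoxLambdaInverse = 1)
  expect_equal(skew1$pheno$y, plain$pheno$y, tolerance = 1e-12)
  skew <- simulatePhenotypes(sb$panel, sb$blocks, fractions = fr, seed = 82,
                             boxcoxLambdaInverse = 0.3)
  expect_gt(abs(1 - boxcoxFit(skew$pheno$y)$lambda), 0.3)  # visibly skewed
})

test_that("phenotype simulation rejects invalid variance requests", {
  sb <- simPanelBlocks(50, seed = 91)
  expect_error(simulatePhenotypes(sb$panel, sb$blocks,
                                  fractions = c(add = 0.7, dom = 0.3,
                                                epi = 0.2), seed = 1),
               "sum")
  expect_error(simulatePhenotypes(sb$panel, NULL,
                                  fractions = c(add = 0.2, dom = 0,
                                                epi = 0.1), seed = 1),
               "block")
})

test_that("missing phenotypes are generated at the requested rate", {
  sb <- simPanelBlocks(500, seed = 101)
  sim <- simulatePhenotypes(sb$panel, sb$blocks,
                            fractions = c(add = 0.3, dom = 0, epi = 0),
                            seed = 102, missingRate = 0.2)
  expect_gt(mean(is.na(sim$pheno$y)), 0.12)
  expect_lt(mean(is.na(sim$pheno$y)), 0.28)
})

test_that("null simulation yields near-zero GREML heritability", {
  # all genetic fractions zero: phenotype is fixed effects + noise
  panel <- simulateGenotypes(simConfig(1000, c(chr1 = 2e6), snpDensity = 250,
                                       ldDecay = 0.3, seed = 111))
  sim <- simulatePhenotypes(panel, NULL,
                            fractions = c(add = 0, dom = 0, epi = 0),
                            seed = 112)
  X <- buildDesign(sim$pheno, "y", "sex", "age")
  grms <- buildGrms(buildModelMatrices(panel, components = "add"))@grms
  fit <- gremlFit(sim$pheno$y, X, grms, model = 6L)
  expect_lt(heritability(fit)[["add"]], 0.05)
})
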