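#' Simulation configuration
#'
#' Defines the study conditions for a simulated phased SNP panel:
#' multi-chromosome genome, SNP density, minor-allele-frequency spectrum,
#' and local linkage disequilibrium generated by a first-order Markov chain
#' along each founder haplotype. \code{ldDecay} is the target allelic
#' correlation between adjacent SNPs; it is exactly attainable only when
#' neighboring allele frequencies are similar (the conditional allele
#' probability is clamped to [0, 1] otherwise).
#'
#' @param nIndividuals number of diploid individuals (>= 2).
#' @param chromosomes data.frame with columns \code{name} and \code{length}
#'   (bp), or a named numeric vector of lengths.
#' @param snpDensity SNPs per Mb.
#' @param mafRange length-2 numeric; minor-allele frequencies are drawn
#'   uniformly on this interval (within (0, 0.5]).
#' @param ldDecay adjacent-SNP allelic correlation target in [0, 1).
#' @param seed integer seed; all generator randomness derives from it.
#' @param mating \code{"independent"} draws 2n founder haplotypes directly;
#'   \code{"random"} adds one generation of random mating over
#'   \code{nFounders} founder individuals, creating relatedness (non-trivial
#'   GRM off-diagonals).
#' @param nFounders number of founder individuals for \code{mating =
#'   "random"} (default \code{max(20, nIndividuals / 5)}).
#' @return A validated configuration list of class \code{"SimConfig"}.
#' @examples
#' cfg <- simConfig(50, c(chr1 = 1e6), snpDensity = 100, seed = 1)
#' @export
simConfig <- function(nIndividuals, chromosomes, snpDensity = 100,
                      mafRange = c(0.05, 0.45), ldDecay = 0.5, seed = 1,
                      mating = c("independent", "random"),
                      nFounders = NULL) {
  mating <- match.arg(mating)
  if (is.numeric(chromosomes) && !is.null(names(chromosomes)))
    chromosomes <- data.frame(name = names(chromosomes),
                              length = as.numeric(chromosomes))
  .stopIfNot(is.data.frame(chromosomes) &&
               all(c("name", "length") %in% names(chromosomes)),
             "chromosomes must be a named vector or data.frame(name, length)")
  .stopIfNot(nrow(chromosomes) >= 1L, "at least one chromosome is required")
  .stopIfNot(all(chromosomes$length > 0), "all chromosome lengths must be > 0")
  .stopIfNot(nIndividuals >= 2, "nIndividuals must be >= 2")
  .stopIfNot(ldDecay >= 0 && ldDecay < 1, "ldDecay must be in [0, 1)")
  .stopIfNot(length(mafRange) == 2L && mafRange[1] > 0 &&
               mafRange[2] <= 0.5 && mafRange[1] <= mafRange[2],
             "mafRange must be within (0, 0.5]")
  .stopIfNot(snpDensity > 0, "snpDensity must be > 0")
  if (is.null(nFounders)) nFounders <- max(20L, ceiling(nIndividuals / 5))
  structure(list(nIndividuals = as.integer(nIndividuals),
                 chromosomes = chromosomes, snpDensity = snpDensity,
                 mafRange = mafRange, ldDecay = ldDecay,
                 seed = as.integer(seed), mating = mating,
                 nFounders = as.integer(nFounders)),
            class = "SimConfig")
}

# Markov-chain founder haplotypes for one chromosome.
# freqs: allele-1 frequencies per SNP; r: target adjacent correlation.
.markovHaplotypes <- function(nHap, freqs, r) {
  m <- length(freqs)
  H <- matrix(0L, nHap, m)
  H[, 1L] <- rbinom(nHap, 1L, freqs[1L])
  if (m > 1L) for (j in 2:m) {
    p0 <- freqs[j - 1L]; p1 <- freqs[j]
    pr <- p1 + r * sqrt(p1 * (1 - p1) / (p0 * (1 - p0))) * (H[, j - 1L] - p0)
    H[, j] <- rbinom(nHap, 1L, pmin(pmax(pr, 0), 1))
  }
  H
}

#' Simulate a phased genotype panel
#'
#' Generates founder haplotypes per chromosome by a first-order Markov
#' chain so adjacent SNPs have allelic correlation close to
#' \code{ldDecay}, with per-SNP allele frequencies drawn from the MAF
#' spectrum. Under \code{mating = "independent"} the 2n haplotypes are the
#' individuals' chromosomes directly; under \code{mating = "random"} one
#' generation of random mating over the founders produces the panel, so
#' some individuals share parental haplotypes.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return A \linkS4class{GenotypePanel}. Deterministic for a fixed seed.
#' @examples
#' panel <- simulateGenotypes(simConfig(20, c(chr1 = 5e5), seed = 7))
#' nIndividuals(panel)
#' @export
simulateGenotypes <- function(config) {
  .stopIfNot(inherits(config, "SimConfig"), "config must come from simConfig()")
  set.seed(config$seed)
  n <- config$nIndividuals
  nHapOut <- 2L * n
  nHapFounder <- if (config$mating == "random") 2L * config$nFounders else nHapOut

  mapList <- list()
  hapList <- list()
  for (i in seq_len(nrow(config$chromosomes))) {
    chromName <- config$chromosomes$name[i]
    chromLen <- config$chromosomes$length[i]
    nSnp <- round(chromLen / 1e6 * config$snpDensity)
    if (nSnp < 1L)
      stop("configuration yields zero SNPs on chromosome ", chromName,
           call. = FALSE)
    pos <- sort(sample.int(chromLen, nSnp))
    freqs <- runif(nSnp, config$mafRange[1], config$mafRange[2])
    hapList[[i]] <- .markovHaplotypes(nHapFounder, freqs, config$ldDecay)
    mapList[[i]] <- data.frame(chrom = chromName, pos = pos,
                               ref = "A", alt = "B",
                               stringsAsFactors = FALSE)
  }
  H <- do.call(cbind, hapList)
  map <- do.call(rbind, mapList)

  if (config$mating == "random") {
    # one generation: each offspring receives one random haplotype from each
    # of two distinct founder parents, transmitted per chromosome
    nF <- config$nFounders
    chromCols <- split(seq_len(nrow(map)), map$chrom)[unique(map$chrom)]
    Hoff <- matrix(0L, nHapOut, nrow(map))
    for (ind in seq_len(n)) {
      parents <- sample.int(nF, 2L)
      for (cols in chromCols) {
        fromP1 <- 2L * parents[1L] - 2L + sample.int(2L, 1L)
        fromP2 <- 2L * parents[2L] - 2L + sample.int(2L, 1L)
        Hoff[2L * ind - 1L, cols] <- H[fromP1, cols]
        Hoff[2L * ind, cols] <- H[fromP2, cols]
      }
    }
    H <- Hoff
  }

  altFreq <- colMeans(H)
  map$maf <- pmin(altFreq, 1 - altFreq)
  map$index <- seq_len(nrow(map))
  methods::new("GenotypePanel", haplotypes = H, map = map,
               sampleIds = sprintf("ind_%04d", seq_len(n)))
}

#' Simulate annotation intervals
#'
#' Emits gene/ChIP-seq-like intervals, each labeled
#' \code{coding}, \code{noncoding} or \code{chipseq}. Chromosomes are
#' sampled proportionally to length; interval lengths come from
#' \code{sizeDistribution}; intervals of a class may overlap. Returned as a
#' \link[GenomicRanges]{GRanges} (1-based); \code{\link{writeBedIntervals}}
#' converts to BED's 0-based half-open convention on output.
#'
#' @param chromosomes data.frame(name, length) or named numeric lengths.
#' @param nIntervals number of intervals to draw.
#' @param sizeDistribution either \code{list(type = "fixed", size = bp)} or
#'   \code{list(type = "uniform", min = bp, max = bp)}.
#' @param classFractions named numeric over
#'   \code{c("coding","noncoding","chipseq")}, summing to 1.
#' @param seed integer seed.
#' @return \code{GRanges} with metadata columns \code{name} and
#'   \code{class}.
#' @export
simulateAnnotations <- function(chromosomes, nIntervals,
                                sizeDistribution = list(type = "uniform",
                                                        min = 5e3, max = 1e5),
                                classFractions = c(coding = 0.5,
                                                   noncoding = 0.3,
                                                   chipseq = 0.2),
                                seed = 1) {
  if (is.numeric(chromosomes) && !is.null(names(chromosomes)))
    chromosomes <- data.frame(name = names(chromosomes),
                              length = as.numeric(chromosomes))
  .stopIfNot(is.data.frame(chromosomes) && nrow(chromosomes) >= 1L,
             "chromosomes must be non-empty")
  .stopIfNot(all(sort(names(classFractions)) ==
                   sort(c("coding", "noncoding", "chipseq"))) &&
               abs(sum(classFractions) - 1) < 1e-8,
             "classFractions must be named coding/noncoding/chipseq and sum to 1")
  set.seed(seed)
  if (nIntervals == 0L)
    return(GenomicRanges::GRanges())
  sizes <- switch(sizeDistribution$type,
    fixed = rep(as.integer(sizeDistribution$size), nIntervals),
    uniform = as.integer(round(runif(nIntervals, sizeDistribution$min,
                                     sizeDistribution$max))),
    stop("unknown sizeDistribution type", call. = FALSE))
  .stopIfNot(all(sizes <= max(chromosomes$length)),
             "interval sizes must fit within chromosome lengths")
  cls <- sample(names(classFractions), nIntervals, replace = TRUE,
                prob = classFractions)
  chromIdx <- sample.int(nrow(chromosomes), nIntervals, replace = TRUE,
                         prob = chromosomes$length)
  # redraw chromosomes too short for their interval
  for (r in which(sizes > chromosomes$length[chromIdx])) {
    ok <- which(chromosomes$length >= sizes[r])
    chromIdx[r] <- ok[sample.int(length(ok), 1L)]
  }
  start0 <- vapply(seq_len(nIntervals), function(r) {
    L <- chromosomes$length[chromIdx[r]]
    sample.int(L - sizes[r] + 1L, 1L) - 1L  # 0-based start
  }, numeric(1))
  GenomicRanges::GRanges(
    seqnames = chromosomes$name[chromIdx],
    ranges = IRanges::IRanges(start = start0 + 1L, width = sizes),
    name = sprintf("iv_%05d", seq_len(nIntervals)),
    class = cls)
}

# inverse Box-Cox: maps a normal variable to a skewed one; identity (up to
# an affine shift) at lambda = 1
.invBoxcox <- function(z, lambda) {
  if (abs(lambda) < 1e-12) return(exp(z))
  base <- lambda * z + 1
  .stopIfNot(all(base > 0),
             "inverse Box-Cox undefined: lambda * y + 1 must stay positive")
  base^(1 / lambda)
}

#' Simulate phenotypes with known variance architecture
#'
#' Builds phenotypes as fixed effects + SNP additive values + SNP dominance
#' values + within-block additive-by-additive epistasis values + residual
#' noise. Additive and dominance values use the same genetic-partition SNP
#' codings as the model matrices. Epistasis acts within each haplotype
#' copy: for every sampled SNP pair inside a block, each of the
#' individual's two chromosomes contributes (centered allele code i x
#' centered allele code j x interaction effect), so the epistasis value is
#' an additive function of the individual's two haplotype alleles --- the
#' within-haplotype interaction a haplotype-additive model is hypothesized
#' to absorb (a SNP-additive model cannot). Each component is rescaled so
#' its realized sample variance equals the requested fraction of the
#' target phenotypic variance (set to 1) exactly; the residual absorbs the
#' remaining fraction. Optional skew is applied as the inverse Box-Cox
#' transform.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param blocks a \linkS4class{HaplotypeBlockSet} built from the panel
#'   (may be NULL when \code{fractions["epi"]} is 0).
#' @param fractions named numeric: \code{add}, \code{dom}, \code{epi}
#'   variance fractions, non-negative, summing to <= 1.
#' @param fixedEffects list with \code{sexEffect} and \code{ageEffect}
#'   coefficients (a two-level sex-like factor and a centered age-like
#'   covariate are generated).
#' @param seed integer seed.
#' @param epiPairsPerBlock SNP pairs sampled uniformly within each block.
#' @param missingRate phenotypes set missing completely at random.
#' @param boxcoxLambdaInverse skew parameter; \code{NULL} or 1 leaves the
#'   phenotype normal (1 shifts by a constant only).
#' @return list with \code{pheno} (data.frame id, y, sex, age) and
#'   \code{truth} (fractions, effect vectors, the stored component vectors
#'   \code{a}, \code{d}, \code{epi}, \code{e}, \code{xb}, the sampled
#'   epistasis pairs, and the skew lambda).
#' @export
simulatePhenotypes <- function(panel, blocks = NULL,
                               fractions = c(add = 0.4, dom = 0.1, epi = 0.1),
                               fixedEffects = list(sexEffect = 0.5,
                                                   ageEffect = 0.02),
                               seed = 1, epiPairsPerBlock = 2L,
                               missingRate = 0, boxcoxLambdaInverse = NULL) {
  .stopIfNot(all(c("add", "dom", "epi") %in% names(fractions)),
             "fractions must be named add/dom/epi")
  fractions <- fractions[c("add", "dom", "epi")]
  .stopIfNot(all(fractions >= 0), "variance fractions must be non-negative")
  .stopIfNot(sum(fractions) <= 1, "variance fractions must sum to <= 1")
  if (fractions[["epi"]] > 0)
    .stopIfNot(!is.null(blocks) && nBlocks(blocks) > 0,
               "epistasis fraction > 0 requires a non-empty block set")
  set.seed(seed)
  n <- nIndividuals(panel)
  dose <- genotypeDosage(panel)
  freqs <- colMeans(dose) / 2
  poly <- freqs > 0 & freqs < 1
  Wa <- snpAdditiveCoding(dose[, poly, drop = FALSE], freqs[poly])
  Wd <- snpDominanceCoding(dose[, poly, drop = FALSE], freqs[poly])

  scaleTo <- function(v, frac) {
    if (frac == 0) return(numeric(n))
    s <- .sampleVar(v)
    .stopIfNot(s > 0, "degenerate component: zero variance before rescaling")
    v * sqrt(frac / s)
  }

  alpha <- rnorm(ncol(Wa))
  a <- scaleTo(drop(Wa %*% alpha), fractions[["add"]])
  delta <- rnorm(ncol(Wd))
  d <- scaleTo(drop(Wd %*% delta), fractions[["dom"]])

  epiPairs <- NULL
  epi <- numeric(n)
  if (fractions[["epi"]] > 0) {
    polyIdx <- snpMap(panel)$index[poly]
    pairList <- list()
    for (b in seq_len(nBlocks(blocks))) {
      snps <- intersect(blockSnpIndices(blocks)[[b]], polyIdx)
      if (length(snps) < 2L) next
      prs <- utils::combn(snps, 2L)
      take <- sample.int(ncol(prs), min(epiPairsPerBlock, ncol(prs)))
      pairList[[length(pairList) + 1L]] <-
        data.frame(block = b, i = prs[1L, take], j = prs[2L, take])
    }
    .stopIfNot(length(pairList) > 0,
               "no usable SNP pairs within blocks for epistasis")
    epiPairs <- do.call(rbind, pairList)
    epiPairs$effect <- rnorm(nrow(epiPairs))
    # per-haplotype interaction: centered allele codes multiplied on the
    # same chromosome copy, then summed over the individual's two copies
    H <- haplotypeMatrix(panel)
    hapFreq <- colMeans(H)
    odd <- seq(1L, 2L * n, by = 2L)
    even <- odd + 1L
    raw <- numeric(n)
    for (r in seq_len(nrow(epiPairs))) {
      i <- epiPairs$i[r]; j <- epiPairs$j[r]
      ci <- H[, i] - hapFreq[i]
      cj <- H[, j] - hapFreq[j]
      perHap <- ci * cj
      raw <- raw + (perHap[odd] + perHap[even]) * epiPairs$effect[r]
    }
    epi <- scaleTo(raw, fractions[["epi"]])
  }

  residFrac <- 1 - sum(fractions)
  e <- if (residFrac > 0) scaleTo(rnorm(n), residFrac) else numeric(n)

  sex <- factor(sample(c("F", "M"), n, replace = TRUE))
  age <- runif(n, 30, 70)
  xb <- fixedEffects$sexEffect * (as.integer(sex) - 1L) +
        fixedEffects$ageEffect * (age - mean(age))
  mu <- 10
  y <- mu + xb + a + d + epi + e

  lambda <- boxcoxLambdaInverse
  if (!is.null(lambda) && lambda != 1) y <- .invBoxcox(y, lambda)

  if (missingRate > 0) y[runif(n) < missingRate] <- NA_real_

  list(pheno = data.frame(id = sampleIds(panel), y = y, sex = sex, age = age,
                          stringsAsFactors = FALSE),
       truth = list(fractions = c(fractions, residual = residFrac),
                    alpha = alpha, delta = delta, epiPairs = epiPairs,
                    components = list(a = a, d = d, epi = epi, e = e, xb = xb),
                    fixedEffects = fixedEffects,
                    boxcoxLambdaInverse = if (is.null(lambda)) 1 else lambda))
}
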