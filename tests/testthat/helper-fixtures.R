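# shared fixture builders; everything is generated in code at test time

# panel from an explicit (2n x m) 0/1 haplotype matrix
makePanel <- function(H, pos = NULL, chrom = "chr1") {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  m <- ncol(H)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  altFreq <- colMeans(H)
  map <- data.frame(chrom = rep(chrom, length.out = m), pos = as.integer(pos),
                    ref = "A", alt = "B", maf = pmin(altFreq, 1 - altFreq),
                    index = seq_len(m), stringsAsFactors = FALSE)
  methods::new("GenotypePanel", haplotypes = H, map = map,
               sampleIds = sprintf("s%03d", seq_len(nrow(H) %/% 2L)))
}

# SNP map without a panel, for blocking tests
makeMap <- function(pos, chrom = "chr1", maf = 0.3) {
  data.frame(chrom = rep(chrom, length.out = length(pos)),
             pos = as.integer(pos), ref = "A", alt = "B",
             maf = rep(maf, length.out = length(pos)),
             index = seq_along(pos), stringsAsFactors = FALSE)
}

# quick simulated panel + blocks for model-level tests
simPanelBlocks <- function(n, chromLengths = c(chr1 = 1e6), density = 200,
                           ld = 0.6, s = 5L, seed = 1) {
  panel <- simulateGenotypes(simConfig(n, chromLengths, snpDensity = density,
                                       ldDecay = ld, seed = seed))
  blocks <- enumerateHaplotypes(blocksFixedCount(snpMap(panel), s), panel)
  list(panel = panel, blocks = blocks)
}

# independent interval-union width oracle (sort + sweep, no IRanges)
unionWidthOracle <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0; curS <- start[1]; curE <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= curE + 1) curE <- max(curE, end[i])
    else { total <- total + curE - curS + 1; curS <- start[i]; curE <- end[i] }
  }
  total + curE - curS + 1
}

# independent restricted log-likelihood (V-form, generic X), for oracles
remlLogLikOracle <- function(sigG, sigE, y, X, G) {
  n <- length(y)
  V <- sigG * G + diag(sigE, n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (determinant(V, log = TRUE)$modulus +
            determinant(XtViX, log = TRUE)$modulus +
            drop(t(y) %*% P %*% y))
}
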