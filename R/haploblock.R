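# assemble a HaplotypeBlockSet from per-block descriptors
.newBlockSet <- function(chrom, snpIdx, spanBp, startBp, endBp, firstBp,
                         lastBp, source) {
  nb <- length(snpIdx)
  snpIdx <- lapply(unname(snpIdx), unname)
  blocks <- data.frame(
    block_id = if (nb) sprintf("%s_%s_%05d", source, chrom, seq_len(nb))
               else character(),
    chrom = chrom,
    n_snps = if (nb) lengths(snpIdx) else integer(),
    span_bp = spanBp, start_bp = startBp, end_bp = endBp,
    first_bp = firstBp, last_bp = lastBp,
    source = if (nb) rep(source, nb) else character(),
    stringsAsFactors = FALSE)
  methods::new("HaplotypeBlockSet", blocks = blocks, snpIndices = snpIdx,
               alleles = list(), nChromosomes = 0L)
}

.rbindBlockSets <- function(sets) {
  sets <- Filter(function(s) nrow(s@blocks) > 0, sets)
  if (!length(sets))
    return(methods::new("HaplotypeBlockSet",
                        blocks = data.frame(), snpIndices = list(),
                        alleles = list(), nChromosomes = 0L))
  methods::new("HaplotypeBlockSet",
               blocks = do.call(rbind, lapply(sets, function(s) s@blocks)),
               snpIndices = unname(do.call(c, lapply(sets,
                                                     function(s) s@snpIndices))),
               alleles = list(), nChromosomes = 0L)
}

#' Filter a SNP map by minor allele frequency, optionally thinning
#'
#' Removes SNPs with MAF below \code{mafMin} (boundary inclusive: a SNP at
#' exactly \code{mafMin} is kept). When \code{targetCount} is given the
#' survivors are thinned to that count by a uniform index stride, so
#' successive kept SNPs are (near-)equally spaced in index order. The
#' \code{index} column (panel column positions) is preserved.
#'
#' @param map SNP map data.frame with columns \code{chrom}, \code{pos},
#'   \code{maf}, \code{index}.
#' @param mafMin minimum MAF in [0, 0.5).
#' @param targetCount optional number of SNPs to keep after filtering.
#' @return the filtered (and possibly thinned) map, order preserved.
#' @export
subsetSnps <- function(map, mafMin, targetCount = NULL) {
  .stopIfNot(mafMin >= 0 && mafMin < 0.5, "mafMin must be in [0, 0.5)")
  .stopIfNot("maf" %in% names(map), "map must carry a maf column")
  out <- map[map$maf >= mafMin, , drop = FALSE]
  if (!is.null(targetCount)) {
    .stopIfNot(targetCount <= nrow(out),
               "targetCount exceeds the number of surviving SNPs")
    keep <- unique(round(seq(1L, nrow(out), length.out = targetCount)))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Haplotype blocks by fixed chromosome distance
#'
#' Partitions each chromosome into consecutive non-overlapping windows of
#' \code{windowKb} kilobases on absolute coordinates (window k covers
#' positions (k*w, (k+1)*w]), and assigns SNPs to windows by position.
#' Windows holding fewer than 2 SNPs yield no block; their SNPs remain
#' available to SNP-level model components. The span of every emitted
#' block is the window size.
#'
#' @param map SNP map data.frame (chrom, pos, index).
#' @param windowKb window size in Kb (> 0).
#' @return a \linkS4class{HaplotypeBlockSet} with source
#'   \code{"dist<windowKb>kb"}.
#' @export
blocksFixedDistance <- function(map, windowKb) {
  .stopIfNot(windowKb > 0, "windowKb must be > 0")
  .stopIfNot(nrow(map) > 0, "empty SNP map")
  w <- windowKb * 1000
  src <- sprintf("dist%gkb", windowKb)
  sets <- lapply(split(map, map$chrom), function(cm) {
    cm <- cm[order(cm$pos), , drop = FALSE]
    win <- cm$pos %/% w  # half-open windows [k*w, (k+1)*w)
    groups <- split(seq_len(nrow(cm)), win)
    groups <- groups[lengths(groups) >= 2L]
    if (!length(groups))
      return(.newBlockSet(character(), list(), numeric(), numeric(),
                          numeric(), numeric(), numeric(), src))
    winId <- as.numeric(names(groups))
    startBp <- pmax(winId * w, 1)
    .newBlockSet(chrom = cm$chrom[1L],
                 snpIdx = lapply(groups, function(g) cm$index[g]),
                 spanBp = rep(w, length(groups)),
                 startBp = startBp, endBp = (winId + 1) * w - 1,
                 firstBp = vapply(groups, function(g) cm$pos[g[1L]], 0),
                 lastBp = vapply(groups, function(g) cm$pos[g[length(g)]], 0),
                 source = src)
  })
  .rbindBlockSets(sets)
}

#' Haplotype blocks by fixed SNP count
#'
#' Groups each chromosome's SNPs into consecutive disjoint blocks of
#' exactly \code{s} SNPs. When the chromosome's SNP count is not divisible
#' by \code{s}, the final block consists of the chromosome's last \code{s}
#' SNPs and may overlap the penultimate block, so every block has exactly
#' \code{s} SNPs and each chromosome yields \code{ceiling(m_c / s)} blocks.
#' Chromosomes with fewer than \code{s} SNPs are skipped with a warning.
#'
#' @param map SNP map data.frame (chrom, pos, index).
#' @param s SNPs per block (>= 2).
#' @return a \linkS4class{HaplotypeBlockSet} with source
#'   \code{"count<s>snp"}.
#' @export
blocksFixedCount <- function(map, s) {
  .stopIfNot(s >= 2, "s must be >= 2")
  .stopIfNot(nrow(map) > 0, "empty SNP map")
  s <- as.integer(s)
  src <- sprintf("count%dsnp", s)
  sets <- lapply(split(map, map$chrom), function(cm) {
    cm <- cm[order(cm$pos), , drop = FALSE]
    mC <- nrow(cm)
    if (mC < s) {
      warning("chromosome ", cm$chrom[1L], " has fewer than ", s,
              " SNPs; skipped")
      return(.newBlockSet(character(), list(), numeric(), numeric(),
                          numeric(), numeric(), numeric(), src))
    }
    nFull <- mC %/% s
    starts <- seq(1L, by = s, length.out = nFull)
    if (mC %% s != 0L) starts <- c(starts, mC - s + 1L)
    groups <- lapply(starts, function(st) st:(st + s - 1L))
    firstBp <- vapply(groups, function(g) cm$pos[g[1L]], 0)
    lastBp <- vapply(groups, function(g) cm$pos[g[s]], 0)
    .newBlockSet(chrom = cm$chrom[1L],
                 snpIdx = lapply(groups, function(g) cm$index[g]),
                 spanBp = lastBp - firstBp,
                 startBp = firstBp, endBp = lastBp,
                 firstBp = firstBp, lastBp = lastBp, source = src)
  })
  .rbindBlockSets(sets)
}

#' Haplotype blocks from annotation intervals
#'
#' Builds blocks from gene or ChIP-seq-like intervals: each interval is
#' extended by \code{flankKb} on both ends (clipped at position 1),
#' overlapping extended intervals of the same class are merged, merged
#' intervals longer than \code{splitKb} are cut into consecutive chunks of
#' at most \code{splitKb}, and SNPs are assigned to chunks by position.
#' Chunks with fewer than 2 SNPs are dropped. The recorded span is the
#' distance between the first and last SNP in the block.
#'
#' @param map SNP map data.frame (chrom, pos, index).
#' @param intervals \code{GRanges} (1-based) with a \code{class} metadata
#'   column (\code{coding}, \code{noncoding}, \code{chipseq}, or any other
#'   label such as \code{gene}); classes are merged and blocked separately.
#' @param flankKb flank added to each end, in Kb (default 2).
#' @param splitKb maximum chunk length in Kb (default 150).
#' @return a \linkS4class{HaplotypeBlockSet}; block source is the interval
#'   class.
#' @export
blocksFromIntervals <- function(map, intervals, flankKb = 2, splitKb = 150) {
  .stopIfNot(nrow(map) > 0, "empty SNP map")
  .stopIfNot(methods::is(intervals, "GRanges"), "intervals must be a GRanges")
  .stopIfNot(all(IRanges::width(intervals) > 0),
             "malformed intervals: end must exceed start")
  cls <- as.character(intervals$class)
  if (is.null(cls) || !length(cls)) cls <- rep("gene", length(intervals))
  flank <- flankKb * 1000
  splitLen <- splitKb * 1000
  mapByChrom <- split(map[order(map$chrom, map$pos), , drop = FALSE],
                      map$chrom[order(map$chrom, map$pos)])
  sets <- list()
  for (cl in unique(cls)) {
    gr <- intervals[cls == cl]
    for (ch in unique(as.character(GenomicRanges::seqnames(gr)))) {
      g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
      ext <- IRanges::reduce(IRanges::IRanges(
        start = pmax(1, GenomicRanges::start(g) - flank),
        end = GenomicRanges::end(g) + flank))
      cm <- mapByChrom[[ch]]
      if (is.null(cm)) next
      chunkStart <- numeric(); chunkEnd <- numeric()
      for (k in seq_along(ext)) {
        st <- IRanges::start(ext)[k]; en <- IRanges::end(ext)[k]
        cuts <- seq(st, en, by = splitLen)
        chunkStart <- c(chunkStart, cuts)
        chunkEnd <- c(chunkEnd, pmin(cuts + splitLen - 1, en))
      }
      groups <- list(); gs <- numeric(); ge <- numeric()
      for (k in seq_along(chunkStart)) {
        inChunk <- which(cm$pos >= chunkStart[k] & cm$pos <= chunkEnd[k])
        if (length(inChunk) >= 2L) {
          groups[[length(groups) + 1L]] <- cm$index[inChunk]
          gs <- c(gs, chunkStart[k]); ge <- c(ge, chunkEnd[k])
        }
      }
      if (!length(groups)) next
      firstBp <- vapply(groups, function(ix) cm$pos[match(ix[1L], cm$index)], 0)
      lastBp <- vapply(groups,
                       function(ix) cm$pos[match(ix[length(ix)], cm$index)], 0)
      sets[[length(sets) + 1L]] <-
        .newBlockSet(chrom = ch, snpIdx = groups, spanBp = lastBp - firstBp,
                     startBp = gs, endBp = ge, firstBp = firstBp,
                     lastBp = lastBp, source = cl)
    }
  }
  .rbindBlockSets(sets)
}

#' Enumerate block haplotype alleles
#'
#' For each block, the distinct phased allele strings over the block's
#' SNPs across all 2n chromosomes form the allele catalog; frequencies are
#' count / 2n. Rare haplotypes are retained: frequency filtering is
#' SNP-level only, so the multi-allelic locus keeps every observed allele.
#'
#' @param blockset a \linkS4class{HaplotypeBlockSet}.
#' @param panel the \linkS4class{GenotypePanel} the blocks were built from.
#' @return the block set with the allele catalog filled and an
#'   \code{n_alleles} column added to \code{blockInfo}.
#' @export
enumerateHaplotypes <- function(blockset, panel) {
  .stopIfNot(methods::is(panel, "GenotypePanel"), "panel must be a GenotypePanel")
  H <- haplotypeMatrix(panel)
  nChrom <- nrow(H)
  maxIdx <- ncol(H)
  alleles <- vector("list", nBlocks(blockset))
  nAll <- integer(nBlocks(blockset))
  for (b in seq_len(nBlocks(blockset))) {
    idx <- blockset@snpIndices[[b]]
    .stopIfNot(all(idx >= 1L & idx <= maxIdx), "block SNP index out of range")
    sub <- H[, idx, drop = FALSE]
    key <- do.call(paste0, as.data.frame(sub))
    uk <- unique(key)
    codes <- match(key, uk)
    count <- tabulate(codes, nbins = length(uk))
    alleles[[b]] <- list(codes = codes, count = count,
                         freq = count / nChrom, strings = uk)
    nAll[b] <- length(uk)
  }
  blockset@alleles <- alleles
  blockset@nChromosomes <- as.integer(nChrom)
  blockset@blocks$n_alleles <- nAll
  methods::validObject(blockset)
  blockset
}

#' Summary statistics of a haplotype block set
#'
#' Emits the descriptive fields used to characterize a blocking scheme:
#' total number of distinct haplotypes (summed over blocks), number of
#' blocks, average haplotypes per block, min/max/average SNPs per block,
#' min/max/average span (Kb), genome coverage by the union of SNP spans
#' (Mb and percent), and coverage by the union of block regions extended
#' by \code{flankKb} (for annotation-derived blocks the regions already
#' include their construction flanks).
#'
#' @param blockset an allele-enumerated \linkS4class{HaplotypeBlockSet}.
#' @param genomeLength total genome length in bp; defaults to the sum over
#'   chromosomes of the largest block end coordinate.
#' @param flankKb extra flank applied to block regions for the extended
#'   coverage figure (default 0).
#' @return one-row data.frame of statistics.
#' @export
blockStatistics <- function(blockset, genomeLength = NULL, flankKb = 0) {
  b <- blockInfo(blockset)
  .stopIfNot(nrow(b) > 0, "empty block set")
  .stopIfNot(!is.null(b$n_alleles), "alleles must be enumerated first")
  if (is.null(genomeLength))
    genomeLength <- sum(vapply(split(b$end_bp, b$chrom), max, 0))
  spanCov <- .intervalUnionWidth(b$chrom, b$first_bp, b$last_bp)
  extCov <- .intervalUnionWidth(b$chrom, pmax(1, b$start_bp - flankKb * 1000),
                                b$end_bp + flankKb * 1000)
  data.frame(
    total_haplotypes = sum(b$n_alleles),
    n_blocks = nrow(b),
    avg_haplotypes_per_block = sum(b$n_alleles) / nrow(b),
    min_snps = min(b$n_snps), max_snps = max(b$n_snps),
    avg_snps = mean(b$n_snps),
    min_span_kb = min(b$span_bp) / 1000,
    max_span_kb = max(b$span_bp) / 1000,
    avg_span_kb = mean(b$span_bp) / 1000,
    coverage_mb = spanCov / 1e6,
    coverage_pct = 100 * spanCov / genomeLength,
    extended_coverage_mb = extCov / 1e6,
    extended_coverage_pct = 100 * extCov / genomeLength)
}
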