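test_that("MAF filtering is boundary-inclusive and thinning is even-strided", {
  map <- makeMap(c(1000, 2000, 3000))
  map$maf <- c(0.01, 0.05, 0.3)
  expect_identical(nrow(subsetSnps(map, 0.05)), 2L)
  expect_identical(subsetSnps(map, 0), map)
  big <- makeMap(seq_len(10000) * 100)
  thin <- subsetSnps(big, 0, targetCount = 1000)
  expect_identical(nrow(thin), 1000L)
  gaps <- diff(thin$index)
  expect_lte(max(gaps) - min(gaps), 1L)  # stride arithmetic oracle
  expect_error(subsetSnps(map, 0.05, targetCount = 5), "targetCount")
})

test_that("fixed-distance blocking assigns SNPs to first-SNP-anchored windows", {
  map <- makeMap(c(1000, 3000, 6000, 12000, 20000))
  bs <- blocksFixedDistance(map, 10)
  # hand enumeration: window [1000, 11000) holds 1/3/6 kb; 12 kb and 20 kb
  # fall in singleton windows and form no block
  expect_identical(nBlocks(bs), 1L)
  expect_identical(blockSnpIndices(bs)[[1]], 1:3)
  expect_identical(blockInfo(bs)$span_bp, 10000)
  # window larger than the chromosome span: one block with every SNP
  bsAll <- blocksFixedDistance(map, 1000)
  expect_identical(nBlocks(bsAll), 1L)
  expect_identical(blockSnpIndices(bsAll)[[1]], 1:5)
  expect_error(blocksFixedDistance(map[0, ], 10), "empty")
})

test_that("doubling the window never strands previously blocked SNPs", {
  # block count itself is not monotone in the window size (two singleton
  # windows can merge into one 2-SNP window), but the set of SNPs left
  # outside any block can only shrink when windows coarsen by doubling
  set.seed(11)
  for (rep in 1:20) {
    map <- makeMap(sort(sample.int(5e5, 60)))
    for (w in c(5, 10, 20, 40)) {
      fine <- unlist(blockSnpIndices(blocksFixedDistance(map, w)))
      coarse <- unlist(blockSnpIndices(blocksFixedDistance(map, 2 * w)))
      unblockedFine <- setdiff(map$index, fine)
      unblockedCoarse <- setdiff(map$index, coarse)
      expect_true(all(unblockedCoarse %in% unblockedFine))
    }
  }
})

test_that("distance and interval blocks never share SNPs; count blocks only at the tail", {
  set.seed(12)
  map <- makeMap(sort(sample.int(1e6, 150)))
  idx <- unlist(blockSnpIndices(blocksFixedDistance(map, 25)))
  expect_identical(anyDuplicated(idx), 0L)
  bs <- blocksFixedCount(map, 7L)
  counts <- table(unlist(blockSnpIndices(bs)))
  expect_lte(max(counts), 2L)  # only the trailing overlap duplicates
})

test_that("fixed-count blocking uses the trailing-overlap rule", {
  map <- makeMap(seq_len(7) * 1000)
  bs <- blocksFixedCount(map, 3L)
  expect_identical(nBlocks(bs), 3L)  # ceil(7/3)
  expect_identical(blockSnpIndices(bs), list(1:3, 4:6, 5:7))
  expect_true(all(blockInfo(bs)$n_snps == 3L))
  # divisible case: disjoint blocks
  bs2 <- blocksFixedCount(makeMap(seq_len(9) * 1000), 3L)
  expect_identical(nBlocks(bs2), 3L)
  expect_identical(anyDuplicated(unlist(blockSnpIndices(bs2))), 0L)
})

test_that("every fixed-count block has exactly s SNPs on random maps", {
  set.seed(13)
  for (rep in 1:10) {
    nPer <- sample(10:80, 2)
    map <- rbind(makeMap(sort(sample.int(1e6, nPer[1])), chrom = "chr1"),
                 makeMap(sort(sample.int(1e6, nPer[2])), chrom = "chr2"))
    map$index <- seq_len(nrow(map))
    s <- sample(2:9, 1)
    bs <- suppressWarnings(blocksFixedCount(map, s))
    expect_true(all(blockInfo(bs)$n_snps == s))
    expected <- sum(vapply(nPer, function(mc)
      if (mc >= s) ceiling(mc / s) else 0, numeric(1)))
    expect_identical(nBlocks(bs), as.integer(expected))
  }
})

test_that("a chromosome with fewer than s SNPs is skipped with a warning", {
  map <- rbind(makeMap(seq_len(10) * 1000, chrom = "chr1"),
               makeMap(seq_len(3) * 1000, chrom = "chr2"))
  map$index <- seq_len(nrow(map))
  expect_warning(bs <- blocksFixedCount(map, 5L), "fewer than")
  expect_true(all(blockInfo(bs)$chrom == "chr1"))
})

test_that("interval blocking flanks, merges, splits and drops thin chunks", {
  # 400-kb interval, 2-kb flanks -> 404 kb merged, split into 150/150/104
  map <- makeMap(seq(1e5, 6e5, by = 4000))
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(start = 150001, width = 4e5),
                               name = "gene1", class = "gene")
  bs <- blocksFromIntervals(map, gr, flankKb = 2, splitKb = 150)
  expect_identical(nBlocks(bs), 3L)
  expect_true(all(blockInfo(bs)$span_bp <= 150000))
  chunkLens <- blockInfo(bs)$end_bp - blockInfo(bs)$start_bp + 1
  expect_equal(sort(chunkLens), c(104000, 150000, 150000))
  # interval holding a single SNP emits no block
  sparse <- makeMap(c(100000, 500000))
  grS <- GenomicRanges::GRanges("chr1", IRanges::IRanges(95001, 105000),
                                name = "g", class = "gene")
  expect_identical(nBlocks(blocksFromIntervals(sparse, grS)), 0L)
})

test_that("overlapping intervals of one class merge; coverage matches a union oracle", {
  map <- makeMap(seq(1000, 99000, by = 1000))
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(10001, 25001), end = c(30000, 45000)),
    name = c("a", "b"), class = c("gene", "gene"))
  bs <- blocksFromIntervals(map, gr, flankKb = 2, splitKb = 150)
  expect_identical(nBlocks(bs), 1L)  # merged before chunking
  b <- blockInfo(bs)
  expect_equal(b$end_bp - b$start_bp + 1,
               unionWidthOracle(c(10001, 25001) - 2000,
                               c(30000, 45000) + 2000))
})

test_that("haplotype enumeration counts phased allele strings", {
  # 2-SNP block over 4 chromosomes: "00", "01", "01", "11"
  H <- rbind(c(0L, 0L), c(0L, 1L), c(0L, 1L), c(1L, 1L))
  panel <- makePanel(H)
  bs <- blocksFixedCount(snpMap(panel), 2L)
  bs <- enumerateHaplotypes(bs, panel)
  al <- blockAlleles(bs)[[1]]
  expect_identical(sort(al$freq), c(0.25, 0.25, 0.5))
  expect_identical(sum(al$count), 4L)
  # monomorphic block: one allele at frequency 1
  Hm <- matrix(c(1L, 0L), 6, 2, byrow = TRUE)
  bm <- enumerateHaplotypes(blocksFixedCount(snpMap(makePanel(Hm)), 2L),
                            makePanel(Hm))
  expect_identical(blockAlleles(bm)[[1]]$freq, 1)
})

test_that("allele counts agree with an independent string-hashing recount", {
  sb <- simPanelBlocks(60, density = 300, ld = 0.7, s = 4L, seed = 14)
  H <- haplotypeMatrix(sb$panel)
  for (b in seq_len(nBlocks(sb$blocks))) {
    idx <- blockSnpIndices(sb$blocks)[[b]]
    keys <- apply(H[, idx, drop = FALSE], 1L, paste, collapse = "-")
    oracle <- sort(as.integer(table(keys)))
    expect_identical(sort(blockAlleles(sb$blocks)[[b]]$count), oracle)
    expect_lt(abs(sum(blockAlleles(sb$blocks)[[b]]$freq) - 1), 1e-12)
  }
})

test_that("a fully linked 2-SNP block has exactly 2 alleles", {
  set.seed(15)
  hap <- rbinom(80, 1, 0.4)
  H <- cbind(hap, hap)  # LD = 1: second SNP copies the first
  panel <- makePanel(H)
  bs <- enumerateHaplotypes(blocksFixedCount(snpMap(panel), 2L), panel)
  expect_identical(blockInfo(bs)$n_alleles, 2L)
})

test_that("block statistics are internally consistent and match the union oracle", {
  sb <- simPanelBlocks(40, c(chr1 = 5e5), density = 400, s = 5L, seed = 16)
  stats <- blockStatistics(sb$blocks, genomeLength = 5e5)
  b <- blockInfo(sb$blocks)
  expect_equal(stats$avg_haplotypes_per_block,
               stats$total_haplotypes / stats$n_blocks, tolerance = 1e-9)
  expect_equal(stats$avg_snps, sum(b$n_snps) / nrow(b), tolerance = 1e-9)
  expect_equal(stats$coverage_pct,
               100 * unionWidthOracle(b$first_bp, b$last_bp) / 5e5,
               tolerance = 1e-9)
  # toy: 2 blocks with 3 and 5 alleles -> 8 total, average 4
  toy <- sb$blocks
  toy@blocks <- toy@blocks[1:2, ]
  toy@snpIndices <- toy@snpIndices[1:2]
  toy@alleles <- toy@alleles[1:2]
  toy@blocks$n_alleles <- c(3L, 5L)
  st <- blockStatistics(toy, genomeLength = 5e5)
  expect_identical(st$total_haplotypes, 8L)
  expect_identical(st$avg_haplotypes_per_block, 4)
})
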