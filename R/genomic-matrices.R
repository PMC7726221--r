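#' SNP additive coding
#'
#' Centered allele counts: a genotype with x copies of the counted allele
#' at sample frequency p is coded x - 2p, giving codes {2-2p, 1-2p, -2p}.
#' Columns have mean zero when p is the sample frequency.
#'
#' @param genotypes n x m dosage matrix (0/1/2 copies of the counted
#'   allele).
#' @param freqs length-m sample frequencies of the counted allele.
#' @return n x m numeric matrix of additive codes.
#' @export
snpAdditiveCoding <- function(genotypes, freqs) {
  .stopIfNot(ncol(genotypes) == length(freqs),
             "freqs must have one entry per SNP column")
  if (any(freqs <= 0 | freqs >= 1))
    stop("monomorphic SNP encountered (frequency 0 or 1); ",
         "apply a MAF filter first", call. = FALSE)
  sweep(genotypes, 2L, 2 * freqs)
}

#' SNP dominance coding
#'
#' Genetic-partition dominance codes: genotypes with {2, 1, 0} copies of
#' the counted allele (frequency p, q = 1 - p) are coded
#' {-2q^2, 2pq, -2p^2}. Under Hardy-Weinberg proportions the codes have
#' expectation zero and are orthogonal to the additive codes.
#'
#' @inheritParams snpAdditiveCoding
#' @return n x m numeric matrix of dominance codes.
#' @export
snpDominanceCoding <- function(genotypes, freqs) {
  .stopIfNot(ncol(genotypes) == length(freqs),
             "freqs must have one entry per SNP column")
  if (any(freqs <= 0 | freqs >= 1))
    stop("monomorphic SNP encountered (frequency 0 or 1); ",
         "apply a MAF filter first", call. = FALSE)
  W <- matrix(0, nrow(genotypes), ncol(genotypes))
  for (code in c(0L, 1L, 2L)) {
    vals <- switch(as.character(code),
                   "0" = -2 * freqs^2,
                   "1" = 2 * freqs * (1 - freqs),
                   "2" = -2 * (1 - freqs)^2)
    hit <- genotypes == code
    W[hit] <- rep(vals, each = nrow(genotypes))[hit]
  }
  dimnames(W) <- dimnames(genotypes)
  W
}

#' Haplotype additive coding
#'
#' Multi-allelic centered allele counts: one column per block allele l
#' with frequency p_l; an individual carrying c_l in {0, 1, 2} copies is
#' coded c_l - 2 p_l. Within each block the columns sum to zero for every
#' individual (sum of copies is 2 and frequencies sum to 1), so each block
#' contributes at most (alleles - 1) to the rank.
#'
#' @param blockset an allele-enumerated \linkS4class{HaplotypeBlockSet}.
#' @param panel the \linkS4class{GenotypePanel} used for enumeration.
#' @return list with \code{W} (n x total alleles), \code{blockCols}
#'   (columns per block), and \code{alleleInfo} data.frame (block_id,
#'   allele, freq).
#' @export
haplotypeAdditiveCoding <- function(blockset, panel) {
  .stopIfNot(length(blockAlleles(blockset)) > 0,
             "alleles must be enumerated first (enumerateHaplotypes)")
  n <- nIndividuals(panel)
  .stopIfNot(blockset@nChromosomes == 2L * n,
             "block set was enumerated on a different panel")
  cols <- list(); blockCols <- list(); info <- list()
  colAt <- 0L
  b <- blockInfo(blockset)
  for (bi in seq_len(nBlocks(blockset))) {
    al <- blockAlleles(blockset)[[bi]]
    .stopIfNot(abs(sum(al$freq) - 1) < 1e-9, "allele frequencies must sum to 1")
    nAl <- length(al$freq)
    # copies per individual: codes of its two chromosomes
    c1 <- al$codes[seq(1L, 2L * n, by = 2L)]
    c2 <- al$codes[seq(2L, 2L * n, by = 2L)]
    Wb <- matrix(0, n, nAl)
    Wb[cbind(seq_len(n), c1)] <- Wb[cbind(seq_len(n), c1)] + 1
    Wb[cbind(seq_len(n), c2)] <- Wb[cbind(seq_len(n), c2)] + 1
    Wb <- sweep(Wb, 2L, 2 * al$freq)
    cols[[bi]] <- Wb
    blockCols[[bi]] <- colAt + seq_len(nAl)
    colAt <- colAt + nAl
    info[[bi]] <- data.frame(block_id = b$block_id[bi], allele = seq_len(nAl),
                             freq = al$freq, stringsAsFactors = FALSE)
  }
  list(W = do.call(cbind, cols), blockCols = blockCols,
       alleleInfo = do.call(rbind, info))
}

#' Build the mixed-model matrices
#'
#' Assembles the requested subset of W_additive, W_dominance (SNP-level)
#' and W_haplotype (block-allele-level) model matrices on a common
#' individual ordering, with trace normalizers k = tr(WW')/n. SNP
#' frequencies are sample frequencies over all genotyped individuals
#' (computed after MAF filtering, before any cross-validation masking).
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param blockset allele-enumerated \linkS4class{HaplotypeBlockSet};
#'   required when \code{"hap"} is among components.
#' @param components subset of \code{c("add", "dom", "hap")}.
#' @param snpSubset optional integer vector of panel column indices to
#'   restrict the SNP matrices to (e.g. the SNPs inside a functional
#'   region's blocks); defaults to all polymorphic SNPs.
#' @return a \linkS4class{ModelMatrices}.
#' @export
buildModelMatrices <- function(panel, blockset = NULL,
                               components = c("add", "dom", "hap"),
                               snpSubset = NULL) {
  components <- match.arg(components, several.ok = TRUE)
  n <- nIndividuals(panel)
  dose <- genotypeDosage(panel)
  freqs <- colMeans(dose) / 2
  if (is.null(snpSubset)) snpSubset <- which(freqs > 0 & freqs < 1)
  .stopIfNot(all(freqs[snpSubset] > 0 & freqs[snpSubset] < 1),
             "snpSubset contains monomorphic SNPs")
  empty <- matrix(0, n, 0)
  Wa <- Wd <- Wah <- empty
  k <- numeric()
  blockCols <- list()
  blockI <- data.frame()
  if ("add" %in% components) {
    Wa <- snpAdditiveCoding(dose[, snpSubset, drop = FALSE], freqs[snpSubset])
    k["add"] <- sum(Wa^2) / n
  }
  if ("dom" %in% components) {
    Wd <- snpDominanceCoding(dose[, snpSubset, drop = FALSE], freqs[snpSubset])
    k["dom"] <- sum(Wd^2) / n
  }
  if ("hap" %in% components) {
    .stopIfNot(!is.null(blockset), "components 'hap' requires a blockset")
    hc <- haplotypeAdditiveCoding(blockset, panel)
    Wah <- hc$W
    k["hap"] <- sum(Wah^2) / n
    blockCols <- hc$blockCols
    blockI <- blockInfo(blockset)
  }
  snpI <- snpMap(panel)[snpSubset, c("chrom", "pos", "index"), drop = FALSE]
  methods::new("ModelMatrices", Wa = Wa, Wd = Wd, Wah = Wah, k = k,
               blockCols = blockCols, snpInfo = snpI, blockInfo = blockI)
}

#' Build genomic relationship matrices
#'
#' A = W W' / k per component with k = tr(WW')/n, so every relationship
#' matrix is symmetric positive semidefinite with mean diagonal exactly 1.
#' Scaling any W by a constant leaves its GRM unchanged (k absorbs the
#' scale), and duplicating columns leaves it unchanged too.
#'
#' @param mm a \linkS4class{ModelMatrices}.
#' @return a \linkS4class{GRMSet} with matrices named \code{add},
#'   \code{dom}, \code{hap} as available.
#' @export
buildGrms <- function(mm) {
  n <- nrow(if (ncol(mm@Wa)) mm@Wa else if (ncol(mm@Wd)) mm@Wd else mm@Wah)
  grms <- list()
  for (nm in names(mm@k)) {
    W <- switch(nm, add = mm@Wa, dom = mm@Wd, hap = mm@Wah)
    .stopIfNot(mm@k[[nm]] > 0, paste0("zero trace for component ", nm))
    G <- tcrossprod(W) / mm@k[[nm]]
    grms[[nm]] <- (G + t(G)) / 2
  }
  methods::new("GRMSet", grms = grms, k = mm@k, n = as.integer(n))
}

#' Write / read a GRM as text (lower triangle) or binary
#'
#' The text format has one line per (i, j) pair of the lower triangle
#' including the diagonal: \code{id_i id_j value}. The binary format
#' writes the full matrix as doubles with an \code{.ids} sidecar carrying
#' the individual identifiers; ids round-trip in both formats.
#'
#' @param G symmetric numeric matrix with rownames as individual ids (or
#'   ids supplied via \code{ids}).
#' @param path output path.
#' @param ids individual identifiers; defaults to rownames or 1..n.
#' @return \code{writeGrm*} the path, invisibly; \code{readGrm*} the
#'   matrix with dimnames set to ids.
#' @name grm-io
#' @export
writeGrmText <- function(G, path, ids = NULL) {
  if (is.null(ids)) ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  lt <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(id1 = ids[lt[, 1L]], id2 = ids[lt[, 2L]],
                   value = G[lt], stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grm-io
#' @export
readGrmText <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ids <- unique(c(df$id1, df$id2))
  n <- length(ids)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(df$id1, ids); j <- match(df$id2, ids)
  G[cbind(i, j)] <- df$value
  G[cbind(j, i)] <- df$value
  G
}

#' @rdname grm-io
#' @export
writeGrmBinary <- function(G, path, ids = NULL) {
  if (is.null(ids)) ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  con <- file(path, "wb")
  writeBin(as.numeric(G), con)
  close(con)
  writeLines(ids, paste0(path, ".ids"))
  invisible(path)
}

#' @rdname grm-io
#' @export
readGrmBinary <- function(path) {
  ids <- readLines(paste0(path, ".ids"))
  n <- length(ids)
  con <- file(path, "rb")
  vals <- readBin(con, "numeric", n = n * n)
  close(con)
  matrix(vals, n, n, dimnames = list(ids, ids))
}
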