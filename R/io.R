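#' Read a phased VCF into a genotype panel
#'
#' Parses a VCF with phased GT ("0|1" style) via \pkg{vcfR}. Only
#' biallelic SNP records are kept; multiallelic sites are always dropped
#' (with a message). Records with unphased ("/") or half-missing
#' genotypes are an error in strict mode and are dropped per-site (with a
#' message) in lenient mode; retained records have identical values in
#' both modes. Positions are 1-based per VCF. Duplicated chrom+pos records
#' are an error.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param strict reject unphased/half-missing records (default TRUE).
#' @return a \linkS4class{GenotypePanel}.
#' @export
readPhasedVcf <- function(path, strict = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm)))  # single-record VCF drops to a named vector
    fixm <- matrix(fixm, nrow = 1L, dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  keep <- rep(TRUE, nrow(fix))
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi)) {
    message(sum(multi), " multiallelic/non-SNP record(s) skipped")
    keep <- keep & !multi
  }
  bad <- apply(gt, 1L, function(g) any(grepl("/", g, fixed = TRUE)) ||
                 anyNA(g) || any(grepl(".", g, fixed = TRUE)))
  if (any(bad & keep)) {
    if (strict)
      stop("unphased or missing genotypes present (strict mode); ",
           sum(bad & keep), " record(s)", call. = FALSE)
    message(sum(bad & keep), " unphased/missing record(s) dropped")
    keep <- keep & !bad
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (anyDuplicated(paste(fix$CHROM, fix$POS)))
    stop("duplicated positions in VCF", call. = FALSE)
  samples <- colnames(gt)
  n <- length(samples)
  m <- nrow(fix)
  H <- matrix(0L, 2L * n, m)
  for (s in seq_len(n)) {
    parts <- strsplit(gt[, s], "|", fixed = TRUE)
    H[2L * s - 1L, ] <- as.integer(vapply(parts, `[`, "", 1L))
    H[2L * s, ] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  ord <- order(fix$CHROM, as.integer(fix$POS))
  fix <- fix[ord, , drop = FALSE]
  H <- H[, ord, drop = FALSE]
  altFreq <- colMeans(H)
  map <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    maf = pmin(altFreq, 1 - altFreq),
                    index = seq_len(m), stringsAsFactors = FALSE)
  methods::new("GenotypePanel", haplotypes = H, map = map,
               sampleIds = samples)
}

#' Write a genotype panel as a phased VCF
#'
#' Emits a minimal VCF 4.2 with GT-only FORMAT and "0|1"-style phased
#' genotypes; a read-back with \code{\link{readPhasedVcf}} recovers every
#' haplotype string.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePhasedVcf <- function(panel, path) {
  map <- snpMap(panel)
  H <- haplotypeMatrix(panel)
  n <- nIndividuals(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=hapblup_%s",
                       utils::packageVersion("hapblup")),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleIds(panel)), collapse = "\t")),
             con)
  gtCols <- vapply(seq_len(n), function(s)
    paste0(H[2L * s - 1L, ], "|", H[2L * s, ]), character(ncol(H)))
  if (is.null(dim(gtCols))) gtCols <- matrix(gtCols, nrow = ncol(H))
  lines <- paste(map$chrom, map$pos, sprintf("snp_%06d", seq_len(nrow(map))),
                 map$ref, map$alt, ".", "PASS", ".", "GT",
                 apply(gtCols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read / write a plain haplotype table
#'
#' TSV with columns chrom, pos, ref, alt and two 0/1 columns per
#' individual (\code{<id>_1}, \code{<id>_2}), one row per SNP.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param path file path.
#' @return \code{writeHaplotypeTsv}: the path invisibly;
#'   \code{readHaplotypeTsv}: a \linkS4class{GenotypePanel}.
#' @name haplotype-tsv
#' @export
writeHaplotypeTsv <- function(panel, path) {
  map <- snpMap(panel)
  H <- haplotypeMatrix(panel)
  ids <- sampleIds(panel)
  hapNames <- as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2")))
  df <- cbind(map[, c("chrom", "pos", "ref", "alt")],
              as.data.frame(t(H), check.names = FALSE))
  names(df)[-(1:4)] <- hapNames
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname haplotype-tsv
#' @export
readHaplotypeTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  hapCols <- setdiff(names(df), c("chrom", "pos", "ref", "alt"))
  ids <- unique(sub("_[12]$", "", hapCols))
  H <- t(as.matrix(df[, hapCols, drop = FALSE]))
  storage.mode(H) <- "integer"
  altFreq <- colMeans(H)
  map <- data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref,
                    alt = df$alt, maf = pmin(altFreq, 1 - altFreq),
                    index = seq_len(nrow(df)), stringsAsFactors = FALSE)
  dimnames(H) <- NULL
  methods::new("GenotypePanel", haplotypes = H, map = map, sampleIds = ids)
}

#' Read / write annotation intervals as BED
#'
#' Five-column BED: chrom, start (0-based), end (half-open), name, class.
#' Coordinates are converted to 1-based inclusive at this boundary; all
#' internal interval arithmetic is 1-based.
#'
#' @param path BED file path.
#' @param gr a \code{GRanges} with \code{name} and \code{class} metadata
#'   columns.
#' @return \code{readBedIntervals}: a \code{GRanges};
#'   \code{writeBedIntervals}: the path invisibly.
#' @name bed-io
#' @export
readBedIntervals <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  .stopIfNot(ncol(df) >= 3L, "BED needs at least chrom, start, end")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (any(df$end <= df$start))
    stop("malformed intervals: end must exceed start", call. = FALSE)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    name = if (ncol(df) >= 4L) df[[4L]] else sprintf("iv_%d", seq_len(nrow(df))),
    class = if (ncol(df) >= 5L) df[[5L]] else "gene")
}

#' @rdname bed-io
#' @export
writeBedIntervals <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = if (!is.null(gr$name)) gr$name
                          else sprintf("iv_%d", seq_along(gr)),
                   class = if (!is.null(gr$class)) gr$class else "gene")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract gene intervals from a GTF into BED-style ranges
#'
#' Minimal convenience reader: keeps \code{gene} feature rows, labels them
#' \code{coding} when the attributes contain
#' \code{gene_(bio)type "protein_coding"} and \code{noncoding} otherwise.
#' Full GTF semantics are out of scope.
#'
#' @param path GTF file path.
#' @return \code{GRanges} with \code{name} (gene id if present) and
#'   \code{class} columns.
#' @export
gtfGeneIntervals <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  df <- df[df[[3L]] == "gene", , drop = FALSE]
  .stopIfNot(nrow(df) > 0, "no gene features in GTF")
  attrs <- df[[9L]]
  coding <- grepl('gene_(bio)?type[ =]"?protein_coding', attrs)
  geneId <- sub('.*gene_id[ =]"?([^";]+).*', "\\1", attrs)
  GenomicRanges::GRanges(
    seqnames = df[[1L]],
    ranges = IRanges::IRanges(start = df[[4L]], end = df[[5L]]),
    name = geneId,
    class = ifelse(coding, "coding", "noncoding"))
}
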