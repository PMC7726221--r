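#' @import methods
#' @importFrom stats var cor sd rnorm runif rbinom optimize setNames
#' @importFrom utils head tail read.table write.table
NULL

#' Phased diploid genotype panel
#'
#' Container for phased haplotypes of \code{n} individuals over \code{m}
#' mapped biallelic SNPs. Haplotypes are stored as a \code{2n x m} 0/1
#' integer matrix; rows \code{2i-1} and \code{2i} are the two phased
#' chromosomes of individual \code{i}. The SNP map records chromosome,
#' 1-based bp position and alleles for every column, plus an \code{index}
#' column giving the column position in the haplotype matrix (kept stable
#' under SNP subsetting so haplotype blocks can always be resolved against
#' the panel).
#'
#' @slot haplotypes integer matrix (2n x m) of 0/1 allele codes.
#' @slot map data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{maf}, \code{index}.
#' @slot sampleIds character vector of n individual identifiers.
#'
#' @aliases GenotypePanel-class
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  slots = c(haplotypes = "matrix", map = "data.frame",
            sampleIds = "character"))

setValidity("GenotypePanel", function(object) {
  h <- object@haplotypes
  m <- object@map
  msgs <- character()
  if (nrow(h) %% 2L != 0L) msgs <- c(msgs, "haplotype rows must be 2 per individual")
  if (nrow(h) != 2L * length(object@sampleIds))
    msgs <- c(msgs, "haplotype rows must equal 2 * length(sampleIds)")
  if (ncol(h) != nrow(m)) msgs <- c(msgs, "map rows must match haplotype columns")
  if (length(h) && !all(h %in% c(0L, 1L)))
    msgs <- c(msgs, "haplotype entries must be 0/1")
  need <- c("chrom", "pos", "index")
  if (!all(need %in% names(m)))
    msgs <- c(msgs, "map must have columns chrom, pos, index")
  if (all(need %in% names(m)) && nrow(m) > 1L) {
    bad <- vapply(split(m$pos, m$chrom), function(p) any(diff(p) <= 0), logical(1))
    if (any(bad)) msgs <- c(msgs, "positions must be strictly increasing within chromosome")
  }
  if (length(msgs)) msgs else TRUE
})

#' Haplotype block set
#'
#' Blocks of consecutive SNPs, each treated as one multi-allelic locus.
#' After \code{\link{enumerateHaplotypes}} the per-block allele catalog is
#' filled: every distinct phased allele string observed across the 2n
#' chromosomes is one allele, with its count and frequency, and each
#' chromosome carries an integer allele code.
#'
#' @slot blocks data.frame with one row per block: \code{block_id},
#'   \code{chrom}, \code{n_snps}, \code{span_bp}, \code{start_bp},
#'   \code{end_bp}, \code{source}, and (after enumeration)
#'   \code{n_alleles}.
#' @slot snpIndices list of integer vectors; panel column indices per block.
#' @slot alleles list (one element per block) of
#'   \code{list(codes = integer(2n), freq = numeric, count = integer)};
#'   empty until enumerated.
#' @slot nChromosomes integer; 2n used for enumeration (0 before).
#'
#' @aliases HaplotypeBlockSet-class
#' @exportClass HaplotypeBlockSet
setClass("HaplotypeBlockSet",
  slots = c(blocks = "data.frame", snpIndices = "list", alleles = "list",
            nChromosomes = "integer"),
  prototype = prototype(alleles = list(), nChromosomes = 0L))

setValidity("HaplotypeBlockSet", function(object) {
  msgs <- character()
  if (length(object@snpIndices) != nrow(object@blocks))
    msgs <- c(msgs, "snpIndices must have one element per block row")
  if (nrow(object@blocks) && any(object@blocks$n_snps < 2L))
    msgs <- c(msgs, "every block must contain at least 2 SNPs")
  if (length(object@alleles)) {
    if (length(object@alleles) != nrow(object@blocks))
      msgs <- c(msgs, "alleles must have one element per block")
    sums <- vapply(object@alleles, function(a) sum(a$freq), numeric(1))
    if (any(abs(sums - 1) > 1e-12))
      msgs <- c(msgs, "allele frequencies of every block must sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Model matrices for the multi-allelic mixed model
#'
#' Holds the SNP additive matrix (centered allele counts), the SNP dominance
#' matrix (genetic-partition codes) and the haplotype additive matrix (one
#' centered column per block allele, grouped by block), together with the
#' trace normalizers k = tr(WW')/n used to scale cross-products into
#' relationship matrices with mean diagonal 1.
#'
#' @slot Wa numeric matrix n x m (0 columns when not built).
#' @slot Wd numeric matrix n x m (0 columns when not built).
#' @slot Wah numeric matrix n x n_alleles (0 columns when not built).
#' @slot k named numeric normalizers (subset of add, dom, hap).
#' @slot blockCols list of integer vectors; columns of Wah per block.
#' @slot snpInfo data.frame describing Wa/Wd columns (chrom, pos, index).
#' @slot blockInfo data.frame describing blocks behind Wah.
#'
#' @aliases ModelMatrices-class
#' @exportClass ModelMatrices
setClass("ModelMatrices",
  slots = c(Wa = "matrix", Wd = "matrix", Wah = "matrix", k = "numeric",
            blockCols = "list", snpInfo = "data.frame",
            blockInfo = "data.frame"))

#' Genomic relationship matrices
#'
#' Named list of n x n symmetric relationship matrices (subset of
#' \code{add}, \code{dom}, \code{hap}), each W W'/k with k = tr(WW')/n so
#' the mean diagonal is exactly 1.
#'
#' @slot grms named list of matrices.
#' @slot k named numeric trace normalizers.
#' @slot n integer number of individuals.
#'
#' @aliases GRMSet-class
#' @exportClass GRMSet
setClass("GRMSet",
  slots = c(grms = "list", k = "numeric", n = "integer"))

setValidity("GRMSet", function(object) {
  msgs <- character()
  for (nm in names(object@grms)) {
    G <- object@grms[[nm]]
    if (nrow(G) != object@n || ncol(G) != object@n)
      msgs <- c(msgs, sprintf("GRM '%s' must be n x n", nm))
    else if (max(abs(G - t(G))) > 1e-8)
      msgs <- c(msgs, sprintf("GRM '%s' must be symmetric", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' GREML fit
#'
#' Result of restricted maximum-likelihood estimation of the mixed model
#' y ~ N(Xb, sum_i sigma_i^2 G_i + sigma_e^2 I). Heritability of component
#' i is sigma_i^2 divided by the sum of all estimated variance components
#' (the phenotypic variance under the model).
#'
#' @slot varcomp named numeric variance components, including
#'   \code{residual}.
#' @slot heritability named numeric; per-component fractions plus
#'   \code{residual}; sums to 1.
#' @slot beta numeric fixed-effect solutions.
#' @slot logLik numeric restricted log-likelihood (constants dropped).
#' @slot trajectory numeric log-likelihood at each accepted iteration.
#' @slot converged logical.
#' @slot iterations integer.
#' @slot n integer number of fitted records.
#' @slot model integer model id (1-6) or NA when fitted outside the grid.
#'
#' @aliases GremlFit-class
#' @exportClass GremlFit
setClass("GremlFit",
  slots = c(varcomp = "numeric", heritability = "numeric", beta = "numeric",
            logLik = "numeric", trajectory = "numeric", converged = "logical",
            iterations = "integer", n = "integer", model = "integer"))

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel: %d individuals, %d SNPs, %d chromosome(s)\n",
              length(object@sampleIds), nrow(object@map),
              length(unique(object@map$chrom))))
})

setMethod("show", "HaplotypeBlockSet", function(object) {
  cat(sprintf("HaplotypeBlockSet: %d blocks (%s)%s\n",
              nrow(object@blocks),
              paste(unique(object@blocks$source), collapse = ", "),
              if (length(object@alleles)) ", alleles enumerated" else ""))
})

setMethod("show", "GRMSet", function(object) {
  cat(sprintf("GRMSet: n = %d, matrices: %s\n", object@n,
              paste(names(object@grms), collapse = ", ")))
})

setMethod("show", "GremlFit", function(object) {
  cat(sprintf("GremlFit (%s, %d iterations, n = %d)\n",
              if (object@converged) "converged" else "NOT converged",
              object@iterations, object@n))
  v <- rbind(variance = object@varcomp,
             heritability = object@heritability[names(object@varcomp)])
  print(round(v, 5))
  cat(sprintf("restricted logLik: %.4f\n", object@logLik))
})
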