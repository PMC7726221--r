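#' Accessors for hapblup classes
#'
#' Standard accessor generics: number of individuals/SNPs/blocks, the SNP
#' map, the raw haplotype matrix, genotype dosages, sample identifiers,
#' block descriptions and allele catalogs, and the relationship matrices
#' of a \linkS4class{GRMSet}.
#'
#' @param x a \linkS4class{GenotypePanel}, \linkS4class{HaplotypeBlockSet}
#'   or \linkS4class{GRMSet}.
#' @return See the individual methods: counts, data.frames, matrices or
#'   lists as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname accessors
#' @export
setGeneric("haplotypeMatrix", function(x) standardGeneric("haplotypeMatrix"))

#' @rdname accessors
#' @export
setGeneric("genotypeDosage", function(x) standardGeneric("genotypeDosage"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))

#' @rdname accessors
#' @export
setGeneric("blockInfo", function(x) standardGeneric("blockInfo"))

#' @rdname accessors
#' @export
setGeneric("blockSnpIndices", function(x) standardGeneric("blockSnpIndices"))

#' @rdname accessors
#' @export
setGeneric("blockAlleles", function(x) standardGeneric("blockAlleles"))

#' @rdname accessors
#' @export
setGeneric("grm", function(x, name) standardGeneric("grm"))

#' @rdname accessors
#' @export
setMethod("nIndividuals", "GenotypePanel", function(x) length(x@sampleIds))

#' @rdname accessors
#' @export
setMethod("nSnps", "GenotypePanel", function(x) nrow(x@map))

#' @rdname accessors
#' @export
setMethod("snpMap", "GenotypePanel", function(x) x@map)

#' @rdname accessors
#' @export
setMethod("haplotypeMatrix", "GenotypePanel", function(x) x@haplotypes)

#' @rdname accessors
#' @export
setMethod("genotypeDosage", "GenotypePanel", function(x) {
  h <- x@haplotypes
  n <- nrow(h) %/% 2L
  d <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(d) <- x@sampleIds
  d
})

#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypePanel", function(x) x@sampleIds)

#' @rdname accessors
#' @export
setMethod("nBlocks", "HaplotypeBlockSet", function(x) nrow(x@blocks))

#' @rdname accessors
#' @export
setMethod("blockInfo", "HaplotypeBlockSet", function(x) x@blocks)

#' @rdname accessors
#' @export
setMethod("blockSnpIndices", "HaplotypeBlockSet", function(x) x@snpIndices)

#' @rdname accessors
#' @export
setMethod("blockAlleles", "HaplotypeBlockSet", function(x) x@alleles)

#' @rdname accessors
#' @export
setMethod("grm", "GRMSet", function(x, name) {
  if (!name %in% names(x@grms))
    stop("no GRM named '", name, "' in this set", call. = FALSE)
  x@grms[[name]]
})

#' Variance components, heritabilities and fixed effects of a fit
#'
#' @param x a \linkS4class{GremlFit}.
#' @return Named numeric vectors.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
varComp <- function(x) x@varcomp

#' @rdname fit-accessors
#' @export
heritability <- function(x) x@heritability

#' @rdname fit-accessors
#' @export
fixedEffects <- function(x) x@beta
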