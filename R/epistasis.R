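#' Total heritability of a prediction model
#'
#' Sums exactly the component heritabilities a model prescribes:
#' Model 4 uses the haplotype additive heritability alone; Model 2 adds
#' the SNP additive heritability; Model 1 adds SNP additive and dominance;
#' Model 3 adds SNP dominance; Model 6 is the SNP additive heritability
#' alone; Model 5 is SNP additive plus dominance. A component set
#' inconsistent with the model id is rejected, naming the absent term.
#'
#' @param h named numeric of component heritabilities over
#'   \code{c("add", "dom", "hap")} (a \code{residual} entry, if present,
#'   is ignored), or a \linkS4class{GremlFit}.
#' @param model model id 1..6.
#' @return the total genotypic (Models 1-4) or SNP (Models 5-6)
#'   heritability.
#' @examples
#' totalHeritability(c(add = 0.070, dom = 0.094, hap = 0.394), model = 1)
#' @export
totalHeritability <- function(h, model) {
  if (methods::is(h, "GremlFit")) h <- heritability(h)
  h <- h[setdiff(names(h), "residual")]
  need <- modelComponents(model)
  missing <- setdiff(need, names(h))
  if (length(missing))
    stop("model ", model, " requires component(s) missing from the fit: ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(h), need)
  if (length(extra))
    stop("component(s) ", paste(extra, collapse = ", "),
         " are not part of model ", model, call. = FALSE)
  sum(h[need])
}

# haplotype model -> required SNP baseline model
.snpBaselineFor <- function(hapModel) if (hapModel %in% c(2, 4)) 6L else 5L

#' Haplotype epistasis heritability (heritability-based method)
#'
#' The excess of a haplotype model's total heritability over the
#' corresponding SNP model's total heritability: haplotype Models 2 and 4
#' are differenced against Model 6 (SNP additive only) and Models 1 and 3
#' against Model 5 (SNP additive + dominance). A negative value indicates
#' haplotype loss (the haplotype model captured less SNP additive signal
#' than the SNP baseline) and is reported, not clamped.
#'
#' @param hG2 total heritability of the haplotype model
#'   (\code{\link{totalHeritability}} with the haplotype model id).
#' @param hS2 total heritability of the SNP baseline model.
#' @param hapModel haplotype model id in 1..4.
#' @param snpModel SNP baseline id (5 or 6); must match the pairing rule.
#' @return numeric \code{hG2 - hS2} with attribute
#'   \code{"haplotypeLoss"} (TRUE when negative).
#' @examples
#' epistasisHeritability(0.616, 0.469, hapModel = 4, snpModel = 6)  # 0.147
#' @export
epistasisHeritability <- function(hG2, hS2, hapModel, snpModel) {
  .stopIfNot(hapModel %in% 1:4, "hapModel must be in 1..4")
  .stopIfNot(snpModel %in% 5:6, "snpModel must be 5 or 6")
  expected <- .snpBaselineFor(hapModel)
  if (snpModel != expected)
    stop("haplotype model ", hapModel, " must be differenced against model ",
         expected, ", not model ", snpModel, call. = FALSE)
  hE2 <- hG2 - hS2
  attr(hE2, "haplotypeLoss") <- hE2 < 0
  hE2
}

#' Relative haplotype epistasis heritability
#'
#' The ratio of the haplotype epistasis heritability to the SNP additive
#' heritability: against the Model 6 additive heritability for haplotype
#' Models 2 and 4, and against the Model 5 additive heritability for
#' Models 1 and 3. Reported as a fraction; output writers multiply by 100.
#'
#' @param hE2 haplotype epistasis heritability.
#' @param baselineAdditive the appropriate SNP additive heritability
#'   (> 0).
#' @param hapModel haplotype model id in 1..4 (determines which baseline
#'   is meant; recorded for the report).
#' @return the ratio hE2 / baselineAdditive.
#' @examples
#' relativeEpistasisHeritability(0.147, 0.469, 4)  # 0.313
#' @export
relativeEpistasisHeritability <- function(hE2, baselineAdditive, hapModel) {
  .stopIfNot(hapModel %in% 1:4, "hapModel must be in 1..4")
  if (baselineAdditive <= 0)
    stop("baseline additive heritability must be > 0", call. = FALSE)
  as.numeric(hE2) / baselineAdditive
}

#' Epistasis estimate from a pair of fitted models
#'
#' Convenience wrapper: takes the haplotype-model fit and the SNP-baseline
#' fit, applies the model-specific total-heritability sums, and returns
#' the epistasis heritability and its relative form.
#'
#' @param hapFit \linkS4class{GremlFit} of a haplotype model (1..4).
#' @param snpFit \linkS4class{GremlFit} of the matching SNP model (5..6).
#' @param hapModel,snpModel model ids; default to the ids recorded on the
#'   fits.
#' @return list with \code{h_g2}, \code{h_s2}, \code{h_E2},
#'   \code{h_Er2}, \code{haplotypeLoss}, \code{hapModel}, \code{snpModel}.
#' @export
epistasisEstimate <- function(hapFit, snpFit, hapModel = hapFit@model,
                              snpModel = snpFit@model) {
  hG2 <- totalHeritability(hapFit, hapModel)
  hS2 <- totalHeritability(snpFit, snpModel)
  hE2 <- epistasisHeritability(hG2, hS2, hapModel, snpModel)
  baseAdd <- heritability(snpFit)[["add"]]
  list(h_g2 = hG2, h_s2 = hS2, h_E2 = as.numeric(hE2),
       h_Er2 = relativeEpistasisHeritability(hE2, baseAdd, hapModel),
       haplotypeLoss = attr(hE2, "haplotypeLoss"),
       hapModel = hapModel, snpModel = snpModel)
}
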