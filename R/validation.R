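#' Ten-fold validation plan
#'
#' Randomly assigns phenotyped individuals to k folds. With n not
#' divisible by k, the first k-1 folds get ceiling(n/k) individuals each
#' and the last fold the remainder, so the last fold is generally the
#' smallest; with n divisible by k all folds are equal. When the
#' ceiling rule is infeasible (it would exhaust n before the last fold), a
#' most-even split is used with a warning.
#'
#' @param ids identifiers (or indices) of phenotyped individuals.
#' @param k number of folds (default 10).
#' @param seed integer seed for the permutation.
#' @return list with \code{fold} (integer per id, in input order),
#'   \code{ids}, \code{k}, \code{seed}.
#' @examples
#' table(makeFolds(1:103, seed = 1)$fold)  # nine 11s and one 4
#' @export
makeFolds <- function(ids, k = 10L, seed = 1L) {
  n <- length(ids)
  .stopIfNot(n >= k, "need at least k individuals")
  set.seed(seed)
  perm <- sample.int(n)
  if (n %% k == 0L) {
    sizes <- rep(n %/% k, k)
  } else {
    big <- ceiling(n / k)
    if ((k - 1L) * big < n) {
      sizes <- c(rep(big, k - 1L), n - (k - 1L) * big)
    } else {
      warning("ceiling-size rule infeasible; using a most-even split")
      sizes <- rep(n %/% k, k)
      extra <- n - sum(sizes)
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    }
  }
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  list(fold = fold, ids = ids, k = as.integer(k), seed = as.integer(seed))
}

#' Cross-validated prediction accuracy of one model
#'
#' For each fold, the validation individuals' phenotypes are omitted from
#' the fit (variance components and fixed effects estimated on the
#' training records only, or variance components reused from a full-data
#' fit when \code{reuseComponents} is given), the relationship matrices
#' retain all individuals, and accuracy is the Pearson correlation between
#' the validation individuals' phenotypic values and their predicted total
#' genetic values. Folds with fewer than 3 validation phenotypes are
#' skipped with a warning.
#'
#' @param y response for all individuals (NA allowed; NA records are never
#'   used for training or scoring).
#' @param X design matrix for all individuals.
#' @param grms named list of full relationship matrices.
#' @param model model id 1..6 selecting the components used.
#' @param plan a \code{\link{makeFolds}} plan over the phenotyped
#'   individuals (indices into \code{y}).
#' @param reuseComponents \code{NULL} (default: re-estimate per training
#'   fold) or a \linkS4class{GremlFit} / named variance-component vector
#'   estimated once on all data.
#' @param adjustFixed score accuracy on fixed-effect-adjusted phenotypes
#'   (y - Xb) instead of raw phenotypes (default FALSE, the primary
#'   definition).
#' @param tol,maxIter passed to \code{\link{gremlFit}}.
#' @return list with \code{perFold} accuracies, \code{mean}, \code{sd}
#'   (across folds, n-1 denominator), \code{model}, \code{skipped}.
#' @export
crossValidate <- function(y, X, grms, model, plan, reuseComponents = NULL,
                          adjustFixed = FALSE, tol = 1e-8, maxIter = 200L) {
  comps <- modelComponents(model)
  .stopIfNot(all(comps %in% names(grms)),
             paste("grms must provide:", paste(comps, collapse = ", ")))
  grms <- grms[comps]
  phenoIdx <- if (is.numeric(plan$ids)) plan$ids else match(plan$ids, names(y))
  X <- as.matrix(X)
  acc <- rep(NA_real_, plan$k)
  skipped <- integer()
  eig <- if (length(grms) == 1L && !is.null(reuseComponents))
    eigen(grms[[1L]], symmetric = TRUE) else NULL
  for (f in seq_len(plan$k)) {
    val <- phenoIdx[plan$fold == f]
    val <- val[!is.na(y[val])]
    train <- phenoIdx[plan$fold != f]
    train <- train[!is.na(y[train])]
    if (length(val) < 3L) {
      warning("fold ", f, " has fewer than 3 validation phenotypes; skipped")
      skipped <- c(skipped, f)
      next
    }
    vc <- if (is.null(reuseComponents)) {
      gt <- lapply(grms, function(G) G[train, train])
      varComp(gremlFit(y[train], X[train, , drop = FALSE], gt, tol = tol,
                       maxIter = maxIter, model = model))
    } else if (methods::is(reuseComponents, "GremlFit")) {
      varComp(reuseComponents)
    } else reuseComponents
    pred <- gblupPredict(vc, y, X, grms, train = train)
    target <- if (adjustFixed)
      y[val] - drop(X[val, , drop = FALSE] %*% pred$beta) else y[val]
    acc[f] <- cor(target, pred$total[val])
  }
  ok <- !is.na(acc)
  list(perFold = acc, mean = mean(acc[ok]), sd = sd(acc[ok]),
       model = model, skipped = skipped)
}

#' Percent accuracy gain over a reference
#'
#' \code{100 * (acc - ref) / ref}: the relative accuracy increase of a
#' haplotype model over the best SNP model (or of any accuracy over a
#' reference accuracy).
#'
#' @param acc accuracy of the model of interest.
#' @param ref reference accuracy (> 0 for a meaningful percentage).
#' @return percent gain (negative for a loss).
#' @examples
#' accuracyGain(0.253, 0.234)  # 8.12
#' @export
accuracyGain <- function(acc, ref) 100 * (acc - ref) / ref

#' Cross-validation grid over blocking schemes and models
#'
#' Runs every (blocking, model) combination through
#' \code{\link{crossValidate}} and summarizes mean and SD accuracy, the
#' percent gain of each haplotype model (1-4) over the best SNP model
#' (5 or 6) present in the grid, and the best cell. SNP-only models are
#' fitted once and shared across blockings.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param y,X response and design for all individuals.
#' @param blockings named list of allele-enumerated
#'   \linkS4class{HaplotypeBlockSet}s.
#' @param models subset of 1..6.
#' @param plan a \code{\link{makeFolds}} plan.
#' @param ... passed to \code{\link{crossValidate}}.
#' @return list with \code{summary} data.frame (blocking, model, mean, sd,
#'   gain_pct, best) and \code{folds} data.frame (blocking, model, fold,
#'   accuracy).
#' @export
modelGrid <- function(panel, y, X, blockings, models, plan, ...) {
  .stopIfNot(length(blockings) >= 1L || all(models %in% 5:6),
             "at least one blocking is required for haplotype models")
  snpModels <- intersect(models, 5:6)
  hapModels <- intersect(models, 1:4)
  needSnp <- length(snpModels) > 0 || any(hapModels %in% c(1, 2, 3))
  mmSnp <- if (needSnp)
    buildModelMatrices(panel, components = c("add", "dom")) else NULL
  grmSnp <- if (needSnp) buildGrms(mmSnp)@grms else list()
  rows <- list(); folds <- list()
  addRow <- function(blocking, model, cv) {
    rows[[length(rows) + 1L]] <<- data.frame(
      blocking = blocking, model = model, mean = cv$mean, sd = cv$sd,
      stringsAsFactors = FALSE)
    folds[[length(folds) + 1L]] <<- data.frame(
      blocking = blocking, model = model,
      fold = seq_along(cv$perFold), accuracy = cv$perFold,
      stringsAsFactors = FALSE)
  }
  for (m in snpModels)
    addRow("snp", m, crossValidate(y, X, grmSnp, m, plan, ...))
  for (bl in names(blockings)) {
    grmHap <- buildGrms(buildModelMatrices(
      panel, blockings[[bl]], components = "hap"))@grms
    grmsAll <- c(grmSnp, grmHap)
    for (m in hapModels)
      addRow(bl, m, crossValidate(y, X, grmsAll, m, plan, ...))
  }
  summary <- do.call(rbind, rows)
  bestSnp <- if (length(snpModels))
    max(summary$mean[summary$model %in% 5:6]) else NA_real_
  summary$gain_pct <- ifelse(summary$model %in% 1:4 & !is.na(bestSnp),
                             accuracyGain(summary$mean, bestSnp), NA_real_)
  summary$best <- summary$mean == max(summary$mean)
  list(summary = summary, folds = do.call(rbind, folds),
       bestSnpAccuracy = bestSnp)
}
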