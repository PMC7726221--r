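#' Run the full analysis pipeline
#'
#' Executes phenotype preparation, haplotype blocking, model-matrix and
#' GRM construction, the cross-validation model grid, epistasis
#' heritability estimation, and per-locus heritability profiles, writing
#' every report as TSV with a provenance header (package version, seed,
#' config hash). Inputs are either simulated (config \code{$simulate}) or
#' loaded from files (config \code{$input}: phased VCF or haplotype TSV,
#' phenotype TSV, optional BED). Any stage failure halts with a
#' stage-tagged message.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{seed}{integer; drives folds and (if used) the simulator.}
#'     \item{simulate}{list(nIndividuals, chromosomes, snpDensity,
#'       mafRange, ldDecay, mating, fractions, missingRate,
#'       lambdaInverse); mutually exclusive with \code{input}.}
#'     \item{input}{list(vcf or haplotypeTsv, phenotype, bed).}
#'     \item{trait}{list(response, classVars, covars, boxcox,
#'       outlierSd).}
#'     \item{mafMin}{SNP MAF filter (default 0.05).}
#'     \item{blockings}{named list; each entry
#'       list(method = "distance"|"count"|"intervals", windowKb, s,
#'       flankKb, splitKb).}
#'     \item{models}{subset of 1..6.}
#'     \item{cv}{list(k, reuseComponents, adjustFixed).}
#'     \item{outputDir}{directory for report files.}
#'   }
#' @return invisibly, a list with the panel, phenotype table, design,
#'   block sets, grid results, epistasis table, profile table and paths of
#'   the written reports.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .stopIfNot(is.list(config), "config must be a list or a YAML path")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  hash <- .configHash(config)
  outDir <- if (is.null(config$outputDir)) "." else config$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  emit <- function(df, file) {
    .writeTsv(df, file.path(outDir, file), seed = seed, hash = hash)
    file
  }
  written <- character()

  ## --- load or simulate -------------------------------------------------
  truth <- NULL
  bundle <- stage("load", {
    if (!is.null(config$simulate)) {
      sc <- config$simulate
      cfg <- simConfig(
        nIndividuals = sc$nIndividuals,
        chromosomes = unlist(sc$chromosomes),
        snpDensity = if (is.null(sc$snpDensity)) 100 else sc$snpDensity,
        mafRange = if (is.null(sc$mafRange)) c(0.05, 0.45)
                   else unlist(sc$mafRange),
        ldDecay = if (is.null(sc$ldDecay)) 0.5 else sc$ldDecay,
        seed = seed,
        mating = if (is.null(sc$mating)) "independent" else sc$mating)
      panel <- simulateGenotypes(cfg)
      simBlocks <- enumerateHaplotypes(
        blocksFixedCount(snpMap(panel), if (is.null(sc$blockSnps)) 5L
                                        else sc$blockSnps), panel)
      fr <- if (is.null(sc$fractions)) c(add = 0.4, dom = 0.1, epi = 0.1)
            else unlist(sc$fractions)
      sim <- simulatePhenotypes(
        panel, simBlocks, fractions = fr, seed = seed + 1L,
        missingRate = if (is.null(sc$missingRate)) 0 else sc$missingRate,
        boxcoxLambdaInverse = sc$lambdaInverse)
      truth <- sim$truth
      list(panel = panel, pheno = sim$pheno, truth = sim$truth)
    } else {
      inp <- config$input
      .stopIfNot(!is.null(inp), "config needs either $simulate or $input")
      panel <- if (!is.null(inp$vcf)) readPhasedVcf(inp$vcf)
               else readHaplotypeTsv(inp$haplotypeTsv)
      ph <- .readTsv(inp$phenotype)
      intervals <- if (!is.null(inp$bed)) readBedIntervals(inp$bed) else NULL
      list(panel = panel, pheno = ph, intervals = intervals)
    }
  })
  panel <- bundle$panel

  ## --- phenotype preparation --------------------------------------------
  tr <- config$trait
  if (is.null(tr)) tr <- list()
  response <- if (is.null(tr$response)) "y" else tr$response
  classVars <- if (is.null(tr$classVars)) intersect("sex", names(bundle$pheno))
               else tr$classVars
  covars <- if (is.null(tr$covars)) intersect("age", names(bundle$pheno))
            else tr$covars
  prep <- stage("prep", {
    ph <- bundle$pheno
    outlierSd <- if (is.null(tr$outlierSd)) 10 else tr$outlierSd
    rem <- removeOutliers(ph[[response]], outlierSd)
    ph[[response]] <- rem$kept
    lambda <- NA_real_
    if (isTRUE(tr$boxcox)) {
      bc <- boxcoxFit(ph[[response]])
      ph[[response]] <- bc$transformed
      lambda <- bc$lambda
    }
    X <- buildDesign(ph, response, classVars, covars)
    list(pheno = ph, X = X, rows = attr(X, "rows"),
         report = data.frame(trait = response, lambda = lambda,
                             n_removed = nrow(rem$removed),
                             removal_distances =
                               paste(round(rem$removed$sdDistance, 2),
                                     collapse = ",")))
  })
  written <- c(written, emit(prep$report, "transform_report.tsv"))

  ## --- MAF filter: restrict the panel once, before blocking ---------------
  mafMin <- if (is.null(config$mafMin)) 0.05 else config$mafMin
  mapKeep <- subsetSnps(snpMap(panel), mafMin)
  mapF <- mapKeep
  mapF$index <- seq_len(nrow(mapF))
  panelF <- methods::new("GenotypePanel",
                         haplotypes = haplotypeMatrix(panel)[, mapKeep$index,
                                                             drop = FALSE],
                         map = mapF, sampleIds = sampleIds(panel))
  map <- snpMap(panelF)

  ## --- blocking ----------------------------------------------------------
  blockCfgs <- config$blockings
  if (is.null(blockCfgs))
    blockCfgs <- list(dist50kb = list(method = "distance", windowKb = 50))
  blockSets <- stage("blocks", {
    out <- list()
    for (nm in names(blockCfgs)) {
      bc <- blockCfgs[[nm]]
      bs <- switch(bc$method,
        distance = blocksFixedDistance(map, bc$windowKb),
        count = blocksFixedCount(map, bc$s),
        intervals = blocksFromIntervals(
          map, bundle$intervals,
          flankKb = if (is.null(bc$flankKb)) 2 else bc$flankKb,
          splitKb = if (is.null(bc$splitKb)) 150 else bc$splitKb),
        stop("unknown blocking method '", bc$method, "'"))
      out[[nm]] <- enumerateHaplotypes(bs, panelF)
    }
    out
  })
  blockTables <- lapply(names(blockSets), function(nm) {
    b <- blockInfo(blockSets[[nm]])
    cbind(blocking = nm, b[, c("block_id", "chrom", "n_snps", "span_bp",
                               "source", "n_alleles")])
  })
  written <- c(written, emit(do.call(rbind, blockTables), "blocks.tsv"))
  statTable <- do.call(rbind, lapply(names(blockSets), function(nm)
    cbind(blocking = nm, blockStatistics(blockSets[[nm]]))))
  written <- c(written, emit(statTable, "block_statistics.tsv"))

  ## --- cross-validation grid ---------------------------------------------
  models <- if (is.null(config$models)) c(4L, 6L) else as.integer(config$models)
  cvCfg <- if (is.null(config$cv)) list() else config$cv
  k <- if (is.null(cvCfg$k)) 10L else as.integer(cvCfg$k)
  rows <- prep$rows
  yFit <- prep$pheno[[response]]
  Xall <- matrix(0, nIndividuals(panel), ncol(prep$X),
                 dimnames = list(NULL, colnames(prep$X)))
  Xall[rows, ] <- prep$X
  Xall[, 1L] <- 1  # intercept defined for unphenotyped individuals too
  plan <- makeFolds(rows, k = k, seed = seed)
  grid <- stage("cv", modelGrid(panelF, yFit, Xall, blockSets, models, plan,
                                reuseComponents = cvCfg$reuseComponents,
                                adjustFixed = isTRUE(cvCfg$adjustFixed)))
  written <- c(written, emit(grid$folds, "cv_folds.tsv"),
               emit(grid$summary, "cv_summary.tsv"))

  ## --- full-data fits, epistasis, profiles --------------------------------
  mmSnp <- buildModelMatrices(panelF, components = c("add", "dom"))
  grmSnp <- buildGrms(mmSnp)@grms
  fitOn <- rows[!is.na(yFit[rows])]
  fitModel <- function(m, grmsAll, mm) {
    comps <- modelComponents(m)
    gremlFit(yFit[fitOn], Xall[fitOn, , drop = FALSE],
             lapply(grmsAll[comps], function(G) G[fitOn, fitOn]), model = m)
  }
  epiRows <- list(); fitRows <- list(); profRows <- list()
  stage("epistasis", {
    snpFits <- list()
    for (m in intersect(models, 5:6))
      snpFits[[as.character(m)]] <- fitModel(m, grmSnp, mmSnp)
    for (nm in names(blockSets)) {
      mmHap <- buildModelMatrices(panelF, blockSets[[nm]],
                                  components = c("add", "dom", "hap"))
      grmsAll <- buildGrms(mmHap)@grms
      for (m in intersect(models, 1:4)) {
        hapFit <- fitModel(m, grmsAll, mmHap)
        fitRows[[paste(nm, m)]] <- data.frame(
          blocking = nm, model = m,
          component = names(varComp(hapFit)),
          variance = as.numeric(varComp(hapFit)),
          heritability = as.numeric(heritability(hapFit)),
          logL = hapFit@logLik, iterations = hapFit@iterations)
        base <- .snpBaselineFor(m)
        if (as.character(base) %in% names(snpFits)) {
          est <- epistasisEstimate(hapFit, snpFits[[as.character(base)]],
                                   hapModel = m, snpModel = base)
          epiRows[[paste(nm, m)]] <- data.frame(
            trait = response, model = m, blocking = nm,
            h_g2 = est$h_g2, h_s2 = est$h_s2, h_E2 = est$h_E2,
            h_Er2_pct = 100 * est$h_Er2, loss_flag = est$haplotypeLoss)
        }
        if (m == min(intersect(models, 1:4))) {
          prof <- perLocusHeritability(
            hapFit, mmHap, yFit[fitOn], Xall[fitOn, , drop = FALSE],
            lapply(grmsAll[modelComponents(m)],
                   function(G) G[fitOn, fitOn]))
          profRows[[nm]] <- cbind(blocking = nm, prof)
        }
      }
    }
    for (m in names(snpFits)) {
      f <- snpFits[[m]]
      fitRows[[paste("snp", m)]] <- data.frame(
        blocking = "snp", model = as.integer(m),
        component = names(varComp(f)), variance = as.numeric(varComp(f)),
        heritability = as.numeric(heritability(f)), logL = f@logLik,
        iterations = f@iterations)
    }
  })
  if (length(fitRows))
    written <- c(written, emit(do.call(rbind, fitRows), "fit_report.tsv"))
  if (length(epiRows))
    written <- c(written, emit(do.call(rbind, epiRows), "epistasis.tsv"))
  if (length(profRows))
    written <- c(written, emit(do.call(rbind, profRows), "heritability_profile.tsv"))

  if (!is.null(bundle$truth)) {
    tj <- bundle$truth
    tj$epiPairs <- NULL
    tj$components <- lapply(tj$components, unname)
    jsonlite::write_json(tj, file.path(outDir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, "truth.json")
  }

  invisible(list(panel = panel, pheno = prep$pheno, X = prep$X,
                 blockSets = blockSets, grid = grid,
                 epistasis = if (length(epiRows)) do.call(rbind, epiRows),
                 profiles = if (length(profRows)) do.call(rbind, profRows),
                 truth = bundle$truth, seed = seed, hash = hash,
                 outputDir = outDir, files = written))
}
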