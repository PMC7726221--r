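#' Components included in each prediction model
#'
#' Model 1: SNP additive + SNP dominance + haplotype additive;
#' Model 2: SNP additive + haplotype additive;
#' Model 3: SNP dominance + haplotype additive;
#' Model 4: haplotype additive only;
#' Model 5: SNP additive + SNP dominance;
#' Model 6: SNP additive only.
#'
#' @param model integer in 1..6.
#' @return character vector over \code{c("add", "dom", "hap")}.
#' @export
modelComponents <- function(model) {
  .stopIfNot(length(model) == 1L && model %in% 1:6, "model must be in 1..6")
  switch(model,
         c("add", "dom", "hap"),  # 1
         c("add", "hap"),         # 2
         c("dom", "hap"),         # 3
         "hap",                   # 4
         c("add", "dom"),         # 5
         "add")                   # 6
}

# Error-contrast representation: K spans null(X') so the restricted
# likelihood is an ordinary Gaussian likelihood of K'y with covariance
# K'VK. Numerically robust when a GRM's null space overlaps col(X) (the
# centered-coding null vector 1 and the intercept), where the V-form
# projection formula cancels catastrophically as the residual variance
# approaches zero.
.gremlPrep <- function(y, X, grms) {
  qrX <- qr(X)
  n <- length(y)
  p <- qrX$rank
  Q <- qr.Q(qrX, complete = TRUE)
  K <- Q[, (p + 1L):n, drop = FALSE]
  list(yk = drop(crossprod(K, y)),
       GK = lapply(grms, function(G) crossprod(K, G %*% K)),
       K = K, n = n, p = p,
       logdetXtX = as.numeric(determinant(crossprod(X), log = TRUE)$modulus))
}

# shared state at a given set of variance components (contrast space)
.gremlState <- function(theta, prep) {
  q <- length(prep$GK)
  nk <- length(prep$yk)
  Vk <- diag(theta[q + 1L], nk)
  for (i in seq_len(q)) Vk <- Vk + theta[i] * prep$GK[[i]]
  cV <- chol(Vk)
  dc <- diag(cV)
  if ((min(dc) / max(dc))^2 < 1e-12)
    stop("V numerically singular at these variance components")
  Vki <- chol2inv(cV)
  Pyk <- drop(Vki %*% prep$yk)
  logL <- -0.5 * (2 * sum(log(dc)) + sum(prep$yk * Pyk))
  list(Vki = Vki, Pyk = Pyk, logL = logL)
}

# scores and average-information matrix at the current state
.gremlDerivs <- function(st, prep) {
  q <- length(prep$GK)
  nk <- length(st$Pyk)
  Tm <- matrix(0, nk, q + 1L)
  trPG <- numeric(q + 1L)
  for (i in seq_len(q)) {
    Tm[, i] <- prep$GK[[i]] %*% st$Pyk
    trPG[i] <- sum(st$Vki * prep$GK[[i]])  # tr((K'VK)^-1 K'G K)
  }
  Tm[, q + 1L] <- st$Pyk
  trPG[q + 1L] <- sum(diag(st$Vki))
  yPGPy <- colSums(Tm * st$Pyk)
  score <- -0.5 * (trPG - yPGPy)
  AI <- 0.5 * crossprod(Tm, st$Vki %*% Tm)
  list(score = score, AI = AI, yPGPy = yPGPy, trPG = trPG)
}

# GLS fixed effects at final variance components (ridge on failure)
.glsBeta <- function(theta, y, X, grms) {
  n <- length(y); q <- length(grms)
  V <- diag(theta[q + 1L], n)
  for (i in seq_len(q)) V <- V + theta[i] * grms[[i]]
  cV <- tryCatch(chol(V), error = function(e)
    chol(V + diag(1e-8 * mean(diag(V)), n)))
  Vinv <- chol2inv(cV)
  drop(solve(crossprod(X, Vinv %*% X), crossprod(X, Vinv %*% y)))
}

#' GREML estimation of variance components
#'
#' Maximizes the restricted log-likelihood of
#' \code{y ~ N(Xb, sum_i sigma_i^2 G_i + sigma_e^2 I)} and reports
#' variance components, per-component heritabilities (component variance
#' over the sum of all estimated components), fixed-effect solutions and
#' the restricted log-likelihood (additive constants dropped). One record
#' per individual is assumed (incidence Z = I).
#'
#' Two algorithms are provided. \code{"ai"}: expectation-maximization REML
#' steps for the first iterations, then average-information updates with
#' step-halving and an EM fallback; negative updates are truncated at
#' 1e-8 of the phenotypic variance; accepted iterations never decrease the
#' restricted likelihood. \code{"eigen"}: for a single genetic component,
#' the model is rotated through the eigendecomposition of its relationship
#' matrix and the likelihood profiled over the variance ratio (Brent
#' search); a precomputed decomposition can be supplied so repeated fits
#' against the same matrix (cross-validation folds, simulation replicates)
#' reuse it. \code{"auto"} picks \code{"eigen"} when exactly one genetic
#' component is present.
#'
#' @param y numeric response (complete on fitted individuals).
#' @param X design matrix (full column rank).
#' @param grms named list of relationship matrices (subset of
#'   \code{add}, \code{dom}, \code{hap}, aligned with \code{y}).
#' @param tol relative log-likelihood convergence tolerance (default
#'   1e-8; parameters must also stabilize to 1e-6 relative).
#' @param maxIter iteration cap; non-convergence is flagged on the result,
#'   not an error.
#' @param method \code{"auto"}, \code{"ai"} or \code{"eigen"}.
#' @param eigenCache optional \code{eigen()} result of the single GRM for
#'   \code{method = "eigen"}.
#' @param model optional model id (1..6) recorded on the fit.
#' @return a \linkS4class{GremlFit}.
#' @export
gremlFit <- function(y, X, grms, tol = 1e-8, maxIter = 200L,
                     method = c("auto", "ai", "eigen"), eigenCache = NULL,
                     model = NA_integer_) {
  method <- match.arg(method)
  .stopIfNot(is.list(grms) && length(grms) >= 1L && !is.null(names(grms)),
             "grms must be a non-empty named list")
  .stopIfNot(!anyNA(y), "y must be complete on fitted individuals")
  X <- as.matrix(X)
  .stopIfNot(nrow(X) == length(y), "X rows must match y")
  if (qr(X)$rank < ncol(X)) stop("singular X: design not full rank",
                                 call. = FALSE)
  if (method == "auto")
    method <- if (length(grms) == 1L) "eigen" else "ai"
  if (method == "eigen") {
    .stopIfNot(length(grms) == 1L,
               "method 'eigen' requires exactly one genetic component")
    return(.gremlFitEigen(y, X, grms, eigenCache = eigenCache, model = model))
  }
  .gremlFitAi(y, X, grms, tol = tol, maxIter = as.integer(maxIter),
              model = model)
}

.finishFit <- function(theta, grms, beta, logL, trajectory, converged,
                       iterations, n, model) {
  vc <- stats::setNames(theta, c(names(grms), "residual"))
  methods::new("GremlFit", varcomp = vc, heritability = vc / sum(vc),
               beta = as.numeric(beta), logLik = logL,
               trajectory = trajectory, converged = converged,
               iterations = as.integer(iterations), n = as.integer(n),
               model = as.integer(model))
}

.gremlFitAi <- function(y, X, grms, tol, maxIter, model) {
  n <- length(y); q <- length(grms)
  vP <- .sampleVar(y)
  bound <- 1e-8 * vP
  prep <- .gremlPrep(y, X, grms)
  theta <- rep(vP / (q + 1L), q + 1L)
  st <- .gremlState(theta, prep)
  trajectory <- st$logL
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    dv <- .gremlDerivs(st, prep)
    # boundary fixation: a component at the lower bound with negative score
    # would leave the parameter space; drop it from the update system until
    # its score turns positive again
    free <- !(theta <= bound * 1.001 & dv$score < 0)
    emStep <- function(th) {
      out <- pmax(th + th^2 / n * (dv$yPGPy - dv$trPG), bound)
      out[!free] <- th[!free]
      out
    }
    candidate <- NULL
    if (iter > 2L && any(free)) {
      delta <- numeric(q + 1L)
      sol <- tryCatch(solve(dv$AI[free, free, drop = FALSE], dv$score[free]),
                      error = function(e) NULL)
      if (!is.null(sol)) {
        delta[free] <- sol
        step <- 1
        for (h in 1:15) {
          cand <- pmax(theta + step * delta, bound)
          stCand <- tryCatch(.gremlState(cand, prep),
                             error = function(e) NULL)
          if (!is.null(stCand) && stCand$logL >= st$logL - 1e-10) {
            candidate <- list(theta = cand, st = stCand)
            break
          }
          step <- step / 2
        }
      }
    }
    if (is.null(candidate)) {
      cand <- emStep(theta)
      stCand <- tryCatch(.gremlState(cand, prep),
                         error = function(e) NULL)
      if (is.null(stCand)) {
        # EM walked into a numerically singular V: stay at current estimates
        converged <- TRUE
        break
      }
      if (stCand$logL < st$logL - 1e-10) {
        # EM failed to ascend numerically: accept stationarity
        converged <- TRUE
        break
      }
      candidate <- list(theta = cand, st = stCand)
    }
    relL <- (candidate$st$logL - st$logL) / (abs(st$logL) + 1)
    relP <- if (any(free))
      max(abs(candidate$theta[free] - theta[free]) / (theta[free] + 1e-12))
    else 0
    theta <- candidate$theta
    st <- candidate$st
    trajectory <- c(trajectory, st$logL)
    if (iter > 3L && relL < tol && relP < 1e-6) {
      converged <- TRUE
      break
    }
  }
  .finishFit(theta, grms, .glsBeta(theta, y, X, grms), st$logL, trajectory,
             converged, iter, n, model)
}

# single-genetic-component REML in the eigenbasis of the GRM; profile over
# gamma = sigma_g^2 / sigma_e^2
.gremlFitEigen <- function(y, X, grms, eigenCache = NULL, model) {
  G <- grms[[1L]]
  n <- length(y); p <- ncol(X)
  if (is.null(eigenCache)) eigenCache <- eigen(G, symmetric = TRUE)
  lam <- pmax(eigenCache$values, 0)
  U <- eigenCache$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  prof <- function(lg) {
    g <- exp(lg)
    dvec <- g * lam + 1
    XtViX <- crossprod(Xs / dvec, Xs)
    cX <- chol(XtViX)
    beta <- drop(chol2inv(cX) %*% crossprod(Xs, ys / dvec))
    r <- ys - drop(Xs %*% beta)
    rss <- sum(r^2 / dvec)
    sigE <- rss / (n - p)
    logL <- -0.5 * ((n - p) * log(sigE) + sum(log(dvec)) +
                      2 * sum(log(diag(cX))) + (n - p))
    list(logL = logL, sigE = sigE, sigG = g * sigE, beta = beta)
  }
  # analytic d logL / d log(gamma): beta and sigma_e are profiled out, so
  # the envelope theorem leaves only the explicit dependence on gamma
  grad <- function(lg) {
    g <- exp(lg)
    dvec <- g * lam + 1
    XtViX <- crossprod(Xs / dvec, Xs)
    beta <- drop(solve(XtViX, crossprod(Xs, ys / dvec)))
    r <- ys - drop(Xs %*% beta)
    rss <- sum(r^2 / dvec)
    drss <- -sum(r^2 * lam / dvec^2)
    dlogdetX <- -sum(solve(XtViX) * crossprod(Xs * (lam / dvec^2), Xs))
    -0.5 * ((n - p) * drss / rss + sum(lam / dvec) + dlogdetX) * g
  }
  opt <- optimize(function(lg) prof(lg)$logL, interval = c(-30, 15),
                  maximum = TRUE, tol = 1e-10)
  lgHat <- opt$maximum
  # Brent localizes only to ~sqrt(machine eps); polish with a gradient root
  # so repeated-SNP invariance holds to ~1e-12
  gl <- grad(lgHat - 0.05); gu <- grad(lgHat + 0.05)
  if (is.finite(gl) && is.finite(gu) && gl > 0 && gu < 0)
    lgHat <- stats::uniroot(grad, c(lgHat - 0.05, lgHat + 0.05),
                            tol = 1e-12)$root
  at <- prof(lgHat)
  lo <- prof(-30)
  if (lo$logL > at$logL) at <- lo  # boundary: no genetic variance
  theta <- c(at$sigG, at$sigE)
  # report on the same scale as the error-contrast formula of the AI path
  logL <- at$logL + 0.5 * as.numeric(
    determinant(crossprod(X), log = TRUE)$modulus)
  .finishFit(theta, grms, at$beta, logL, trajectory = logL,
             converged = TRUE, iterations = 1L, n = n, model = model)
}

#' GBLUP prediction of genetic values
#'
#' Solves the mixed-model equations on the training records and predicts
#' component genetic values for all individuals, including those whose
#' phenotypes were masked: \code{b = (X'V^-1X)^-1 X'V^-1 y} on training
#' records and \code{u_i = sigma_i^2 G_i[, train] V^-1 (y - Xb)}. The total
#' genetic value is the sum of the included components. A component with
#' zero variance yields exactly zero predictions.
#'
#' @param fit a \linkS4class{GremlFit}, or a named numeric vector of
#'   variance components including \code{residual}.
#' @param y full response vector (may contain NA outside \code{train}).
#' @param X full design matrix (all individuals).
#' @param grms named list of full n x n relationship matrices matching the
#'   fit's genetic components.
#' @param train integer indices of training records; defaults to all
#'   non-missing \code{y}.
#' @return list with \code{beta}, \code{u} (n x components matrix),
#'   \code{total} (length-n total genetic value) and \code{train}.
#' @export
gblupPredict <- function(fit, y, X, grms, train = NULL) {
  vc <- if (methods::is(fit, "GremlFit")) varComp(fit) else fit
  .stopIfNot("residual" %in% names(vc), "variance components need 'residual'")
  comps <- setdiff(names(vc), "residual")
  .stopIfNot(all(comps %in% names(grms)),
             "grms must cover every genetic component of the fit")
  if (is.null(train)) train <- which(!is.na(y))
  X <- as.matrix(X)
  n <- nrow(X)
  Vt <- diag(vc[["residual"]], length(train))
  for (cc in comps) Vt <- Vt + vc[[cc]] * grms[[cc]][train, train]
  cV <- tryCatch(chol(Vt), error = function(e) {
    warning("V not invertible; adding ridge 1e-8 * mean diagonal")
    chol(Vt + diag(1e-8 * mean(diag(Vt)), nrow(Vt)))
  })
  Vinv <- chol2inv(cV)
  Xt <- X[train, , drop = FALSE]
  yt <- y[train]
  XtViX <- crossprod(Xt, Vinv %*% Xt)
  beta <- drop(solve(XtViX, crossprod(Xt, Vinv %*% yt)))
  r <- drop(Vinv %*% (yt - drop(Xt %*% beta)))
  u <- matrix(0, n, length(comps), dimnames = list(NULL, comps))
  for (cc in comps)
    u[, cc] <- vc[[cc]] * drop(grms[[cc]][, train, drop = FALSE] %*% r)
  list(beta = beta, u = u, total = rowSums(u), train = train)
}

#' Per-locus heritability profiles
#'
#' Back-solves locus effects from a converged fit,
#' \code{alpha = (sigma^2 / k) W' V^-1 (y - Xb)}, and reports the
#' heritability of SNP j as (sample variance of W column j) * alpha_j^2
#' divided by the phenotypic variance (sum of all estimated variance
#' components), and the heritability of a haplotype block as the sample
#' variance of the block's fitted genetic-value vector over the phenotypic
#' variance. Rows are keyed by chromosome and position for Manhattan-style
#' plotting.
#'
#' @param fit a converged \linkS4class{GremlFit}.
#' @param mm the \linkS4class{ModelMatrices} behind the fit's GRMs.
#' @param y,X the data the model was fitted on.
#' @param grms the named GRM list used for the fit.
#' @return data.frame with columns \code{component}, \code{locus_id},
#'   \code{chrom}, \code{pos_start}, \code{pos_end}, \code{heritability}.
#' @export
perLocusHeritability <- function(fit, mm, y, X, grms) {
  vc <- varComp(fit)
  comps <- setdiff(names(vc), "residual")
  sigP2 <- sum(vc)
  n <- length(y)
  V <- diag(vc[["residual"]], n)
  for (cc in comps) V <- V + vc[[cc]] * grms[[cc]]
  Vinv <- chol2inv(chol(V))
  X <- as.matrix(X)
  XtViX <- crossprod(X, Vinv %*% X)
  beta <- drop(solve(XtViX, crossprod(X, Vinv %*% y)))
  r <- drop(Vinv %*% (y - drop(X %*% beta)))
  out <- list()
  snpProfile <- function(W, cc) {
    eff <- drop(crossprod(W, r)) * vc[[cc]] / mm@k[[cc]]
    colVar <- apply(W, 2L, .sampleVar)
    data.frame(component = cc,
               locus_id = sprintf("%s_%d", mm@snpInfo$chrom, mm@snpInfo$pos),
               chrom = mm@snpInfo$chrom,
               pos_start = mm@snpInfo$pos, pos_end = mm@snpInfo$pos,
               heritability = colVar * eff^2 / sigP2,
               stringsAsFactors = FALSE)
  }
  if ("add" %in% comps) out$add <- snpProfile(mm@Wa, "add")
  if ("dom" %in% comps) out$dom <- snpProfile(mm@Wd, "dom")
  if ("hap" %in% comps) {
    eff <- drop(crossprod(mm@Wah, r)) * vc[["hap"]] / mm@k[["hap"]]
    hB <- vapply(mm@blockCols, function(cols)
      .sampleVar(mm@Wah[, cols, drop = FALSE] %*% eff[cols]), numeric(1))
    bi <- mm@blockInfo
    out$hap <- data.frame(component = "hap", locus_id = bi$block_id,
                          chrom = bi$chrom, pos_start = bi$first_bp,
                          pos_end = bi$last_bp, heritability = hB / sigP2,
                          stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
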