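# small shared fixture: panel, GRMs and a phenotype with known architecture
gremlFixture <- function(n = 120, density = 250, fr = c(add = 0.4, dom = 0.1,
                                                        epi = 0),
                         seed = 31) {
  sb <- simPanelBlocks(n, density = density, seed = seed)
  sim <- simulatePhenotypes(sb$panel, sb$blocks, fractions = fr,
                            seed = seed + 1)
  X <- buildDesign(sim$pheno, "y", "sex", "age")
  gs <- buildGrms(buildModelMatrices(sb$panel, sb$blocks))
  list(y = sim$pheno$y, X = X, grms = gs@grms, panel = sb$panel,
       blocks = sb$blocks, truth = sim$truth)
}

test_that("REML optimum matches a brute-force restricted-likelihood grid (n = 30)", {
  set.seed(32)
  fx <- gremlFixture(n = 30, density = 150, fr = c(add = 0.5, dom = 0,
                                                   epi = 0), seed = 33)
  fit <- gremlFit(fx$y, fx$X, fx$grms["add"], model = 6L)
  vc <- varComp(fit)
  # independent 2-D grid of the restricted likelihood around the optimum
  gGrid <- seq(max(vc[["add"]] - 0.4, 0.01), vc[["add"]] + 0.4, length.out = 41)
  eGrid <- seq(max(vc[["residual"]] - 0.4, 0.01), vc[["residual"]] + 0.4,
               length.out = 41)
  ll <- outer(gGrid, eGrid, Vectorize(function(sg, se)
    remlLogLikOracle(sg, se, fx$y, fx$X, fx$grms[["add"]])))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  # primary: the fitted point beats every grid point by the oracle's own
  # likelihood (both formulas differ from the fit's by the same constant)
  llAtFit <- remlLogLikOracle(vc[["add"]], vc[["residual"]], fx$y, fx$X,
                              fx$grms[["add"]])
  expect_gte(llAtFit, max(ll) - 1e-6)
  # location: within the 2-D grid's resolution (joint-grid coupling makes
  # the marginal argmax up to ~2 cells wide)
  resG <- diff(gGrid)[1]; resE <- diff(eGrid)[1]
  expect_lt(abs(gGrid[best[1]] - vc[["add"]]), 2 * resG + 1e-9)
  expect_lt(abs(eGrid[best[2]] - vc[["residual"]]), 2 * resE + 1e-9)
})

test_that("AI and eigen paths agree; cached eigendecomposition changes nothing", {
  fx <- gremlFixture(n = 100, seed = 34)
  fAi <- gremlFit(fx$y, fx$X, fx$grms["add"], method = "ai", model = 6L)
  fEig <- gremlFit(fx$y, fx$X, fx$grms["add"], method = "eigen", model = 6L)
  expect_lt(max(abs(varComp(fAi) - varComp(fEig))), 1e-6)
  expect_lt(abs(fAi@logLik - fEig@logLik), 1e-8)
  eig <- eigen(fx$grms[["add"]], symmetric = TRUE)
  fCached <- gremlFit(fx$y, fx$X, fx$grms["add"], method = "eigen",
                      eigenCache = eig, model = 6L)
  expect_identical(varComp(fCached), varComp(fEig))
})

test_that("pure-noise phenotypes give near-zero heritability across replicates", {
  # modest marker count: the GREML sampling SE of h2 on unrelated panels
  # grows with sqrt(m)/n, so the null band is tightest at low density
  sb <- simPanelBlocks(500, c(chr1 = 1e6), density = 80, seed = 35)
  gs <- buildGrms(buildModelMatrices(sb$panel, components = "add"))
  G <- grm(gs, "add")
  eig <- eigen(G, symmetric = TRUE)
  n <- 500
  X <- matrix(1, n, 1)
  set.seed(36)
  h2 <- vapply(1:50, function(r) {
    y <- rnorm(n)
    heritability(gremlFit(y, X, list(add = G), method = "eigen",
                          eigenCache = eig))[["add"]]
  }, numeric(1))
  expect_gte(mean(h2 < 0.05), 0.95)
})

test_that("restricted likelihood ascends over accepted iterations", {
  fx <- gremlFixture(n = 150, fr = c(add = 0.35, dom = 0.15, epi = 0),
                     seed = 37)
  fit <- gremlFit(fx$y, fx$X, fx$grms[c("add", "dom")], method = "ai",
                  model = 5L)
  expect_true(all(diff(fit@trajectory) >= -1e-8))
  expect_true(fit@converged)
})

test_that("heritabilities plus residual fraction sum to one", {
  fx <- gremlFixture(n = 100, fr = c(add = 0.3, dom = 0.1, epi = 0.1),
                     seed = 38)
  for (m in c(1L, 2L, 5L, 6L)) {
    fit <- gremlFit(fx$y, fx$X, fx$grms[modelComponents(m)], model = m)
    expect_lt(abs(sum(heritability(fit)) - 1), 1e-10)
    expect_true(all(varComp(fit) >= 0))
  }
})

test_that("adding a component never decreases the maximized likelihood", {
  fx <- gremlFixture(n = 120, fr = c(add = 0.3, dom = 0.1, epi = 0.1),
                     seed = 39)
  l6 <- gremlFit(fx$y, fx$X, fx$grms["add"], model = 6L)@logLik
  l5 <- gremlFit(fx$y, fx$X, fx$grms[c("add", "dom")], model = 5L)@logLik
  l2 <- gremlFit(fx$y, fx$X, fx$grms[c("add", "hap")], model = 2L)@logLik
  l1 <- gremlFit(fx$y, fx$X, fx$grms, model = 1L)@logLik
  expect_gte(l5, l6 - 1e-6)
  expect_gte(l2, l6 - 1e-6)
  expect_gte(l1, l5 - 1e-6)
  expect_gte(l1, l2 - 1e-6)
})

test_that("singular designs and incomplete responses are rejected", {
  fx <- gremlFixture(n = 50, seed = 40)
  Xbad <- cbind(fx$X, fx$X[, 2])
  expect_error(gremlFit(fx$y, Xbad, fx$grms["add"]), "singular X")
  yNa <- fx$y; yNa[3] <- NA
  expect_error(gremlFit(yNa, fx$X, fx$grms["add"]), "complete")
})

test_that("GBLUP equals the Henderson mixed-model-equation ridge solution", {
  set.seed(41)
  sb <- simPanelBlocks(50, c(chr1 = 1e6), density = 200, seed = 42)
  sim <- simulatePhenotypes(sb$panel, sb$blocks,
                            fractions = c(add = 0.5, dom = 0, epi = 0),
                            seed = 43)
  y <- sim$pheno$y
  X <- buildDesign(sim$pheno, "y", "sex", "age")
  dose <- genotypeDosage(sb$panel)
  p <- colMeans(dose) / 2
  keep <- which(p > 0 & p < 1)[1:200]
  W <- snpAdditiveCoding(dose[, keep], p[keep])
  n <- nrow(W)
  k <- sum(W^2) / n
  A <- tcrossprod(W) / k
  sigG <- 0.5; sigE <- 0.4
  pred <- gblupPredict(c(add = sigG, residual = sigE), y, X,
                       list(add = A), train = seq_len(n))
  # independent oracle: Henderson MME for the equivalent marker model
  # y = Xb + W alpha + e, alpha ~ N(0, (sigG/k) I), lambda = sigE k / sigG
  lambda <- sigE * k / sigG
  m <- ncol(W)
  lhs <- rbind(cbind(crossprod(X), crossprod(X, W)),
               cbind(crossprod(W, X), crossprod(W) + diag(lambda, m)))
  rhs <- c(crossprod(X, y), crossprod(W, y))
  sol <- solve(lhs, rhs)
  betaMme <- sol[seq_len(ncol(X))]
  alphaMme <- sol[-seq_len(ncol(X))]
  expect_lt(max(abs(pred$beta - betaMme)), 1e-8)
  expect_lt(max(abs(pred$total - drop(W %*% alphaMme))), 1e-8)
})

test_that("zero genetic variance gives exactly zero predictions", {
  fx <- gremlFixture(n = 60, seed = 44)
  pred <- gblupPredict(c(add = 0, residual = 1), fx$y, fx$X, fx$grms["add"])
  expect_identical(unname(pred$total), rep(0, 60))
})

test_that("GBLUP is permutation-equivariant", {
  fx <- gremlFixture(n = 80, seed = 45)
  vc <- c(add = 0.5, residual = 0.5)
  pred <- gblupPredict(vc, fx$y, fx$X, fx$grms["add"])
  set.seed(46)
  perm <- sample.int(80)
  predP <- gblupPredict(vc, fx$y[perm], fx$X[perm, , drop = FALSE],
                        list(add = fx$grms[["add"]][perm, perm]))
  expect_equal(predP$total, pred$total[perm], tolerance = 1e-9)
})

test_that("masked individuals receive predictions without influencing the fit", {
  fx <- gremlFixture(n = 100, seed = 47)
  train <- 1:80
  vc <- c(add = 0.5, residual = 0.5)
  p1 <- gblupPredict(vc, fx$y, fx$X, fx$grms["add"], train = train)
  yMut <- fx$y
  yMut[81:100] <- rnorm(20, 100, 50)  # arbitrary values for masked records
  p2 <- gblupPredict(vc, yMut, fx$X, fx$grms["add"], train = train)
  expect_equal(p1$total, p2$total, tolerance = 1e-12)
  expect_length(p1$total, 100)
})

test_that("a single causal SNP tops the per-SNP heritability profile", {
  set.seed(48)
  panel <- simulateGenotypes(simConfig(1000, c(chr1 = 1e6), snpDensity = 300,
                                       ldDecay = 0.2, seed = 49))
  mm <- buildModelMatrices(panel, components = "add")
  gs <- buildGrms(mm)
  G <- grm(gs, "add")
  eig <- eigen(G, symmetric = TRUE)
  n <- 1000
  X <- matrix(1, n, 1)
  causal <- 150L
  wCausal <- mm@Wa[, causal]
  hits <- 0L
  for (r in 1:20) {
    gval <- wCausal * 1
    gval <- gval * sqrt(0.3 / var(gval))
    y <- gval + rnorm(n, sd = sqrt(0.7))
    fit <- gremlFit(y, X, list(add = G), method = "eigen", eigenCache = eig,
                    model = 6L)
    prof <- perLocusHeritability(fit, mm, y, X, list(add = G))
    if (which.max(prof$heritability) == causal) hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # >= 90% of replicates
})

test_that("per-SNP heritabilities respect the shrinkage bound and null case", {
  fx <- gremlFixture(n = 200, density = 200, fr = c(add = 0.5, dom = 0,
                                                    epi = 0), seed = 50)
  mm <- buildModelMatrices(fx$panel, components = "add")
  fit <- gremlFit(fx$y, fx$X, fx$grms["add"], model = 6L)
  prof <- perLocusHeritability(fit, mm, fx$y, fx$X, fx$grms["add"])
  expect_lte(sum(prof$heritability),
             heritability(fit)[["add"]] * 1.1)
  # no signal: every per-locus heritability is tiny
  set.seed(51)
  sb <- simPanelBlocks(500, density = 150, seed = 52)
  mm0 <- buildModelMatrices(sb$panel, components = "add")
  G0 <- grm(buildGrms(mm0), "add")
  y0 <- rnorm(500)
  X0 <- matrix(1, 500, 1)
  fit0 <- gremlFit(y0, X0, list(add = G0), model = 6L)
  prof0 <- perLocusHeritability(fit0, mm0, y0, X0, list(add = G0))
  expect_lt(max(prof0$heritability), 1e-3)
})
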